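# Distance-based phylogeny: p-distance over IUPAC consensus sequences,
# Saitou-Nei neighbor joining, column-resampling bootstrap, and a
# group-monophyly (bipartition) test. Trees are ape `phylo` objects so
# they plug into the wider R phylogenetics ecosystem; newick I/O goes
# through ape.

#' Pairwise p-distance matrix from a nucleotide alignment
#'
#' d(i, j) = mismatches / compared sites with pairwise deletion of columns
#' where either sequence has a gap or missing call. Three treatments of
#' IUPAC ambiguity codes are available:
#'
#' * `"overlap"` (default): codes match when their expansion sets share an
#'   allele, so a heterozygous S is compatible with a homozygous C;
#' * `"strict"`: codes must be identical (S vs C counts as a mismatch);
#' * `"missing"`: ambiguous calls are deleted pairwise, as distance-based
#'   phylogenetics software conventionally does; note that for data where
#'   heterozygosity itself is group-structured this discards signal.
#'
#' @param alignment nucleotide [as_alignment()] tibble.
#' @param strict compare codes for identity rather than expansion overlap
#'   (shorthand for `ambiguity = "strict"`, kept as an explicit flag).
#' @param ambiguity one of `"overlap"`, `"strict"`, `"missing"`.
#' @return `dist`-classed object labeled by record id.
#' @export
p_distance <- function(alignment, strict = FALSE,
                       ambiguity = c("overlap", "strict", "missing")) {
  ambiguity <- match.arg(ambiguity)
  if (strict) ambiguity <- "strict"
  alignment <- as_alignment(alignment)
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  missing <- m == "-" | m == .MISSING_CALL
  if (ambiguity == "missing") {
    missing <- missing | !(m %in% c("A", "C", "G", "T"))
  }
  d <- matrix(0, n, n, dimnames = list(alignment$id, alignment$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !(missing[i, ] | missing[j, ])
      if (!any(ok)) {
        abort(paste0("no comparable sites between ", sQuote(alignment$id[i]),
                     " and ", sQuote(alignment$id[j])))
      }
      a <- m[i, ok]; b <- m[j, ok]
      if (ambiguity == "overlap") {
        diff_idx <- which(a != b)
        mis <- sum(!vapply(diff_idx, function(k) iupac_overlap(a[k], b[k]), logical(1)))
      } else {
        mis <- sum(a != b)
      }
      d[i, j] <- d[j, i] <- mis / sum(ok)
    }
  }
  as.dist(d)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Agglomerates by the standard Q criterion; on additive distance matrices
#' the generating topology and branch lengths are recovered exactly.
#' Negative branch-length estimates are clamped to zero. Ties in Q are
#' broken deterministically by label order, so a fixed input yields a
#' bit-identical tree.
#'
#' @param dm a symmetric distance matrix or `dist` with labels.
#' @return unrooted `phylo` object.
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) abort("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  # node bookkeeping: tips 1..n, internal nodes appended as created
  node_of <- seq_len(n)          # tree node id of each active cluster
  next_node <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  active <- seq_len(n)
  Dw <- D
  repeat {
    r <- length(active)
    if (r == 2) break
    sub <- Dw[active, active, drop = FALSE]
    rs <- rowSums(sub)
    Q <- (r - 2) * sub - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # deterministic arg-min: first in row-major order over active indices
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[[1]]; j <- idx[[2]]
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]
    dij <- Dw[ai, aj]
    li <- 0.5 * dij + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- dij - li
    li <- max(li, 0); lj <- max(lj, 0)
    new <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(new, node_of[ai]), c(new, node_of[aj]))
    lens <- c(lens, li, lj)
    # distances from the new cluster
    others <- setdiff(active, c(ai, aj))
    newrow <- 0.5 * (Dw[ai, others] + Dw[aj, others] - dij)
    Dw <- rbind(cbind(Dw, 0), 0)
    k <- nrow(Dw)
    rownames(Dw)[k] <- colnames(Dw)[k] <- paste0("node", new)
    Dw[k, others] <- Dw[others, k] <- newrow
    node_of <- c(node_of, new)
    active <- c(others, k)
  }
  # join the last two clusters with a single edge
  ai <- active[1]; aj <- active[2]
  edges <- rbind(edges, c(node_of[aj], node_of[ai]))
  lens <- c(lens, max(Dw[ai, aj], 0))
  n_internal <- next_node - 1L - n
  # ape phylo: tips 1..n, root = n+1; our last-created node plays root.
  # Re-map internal ids so the joining node (highest degree-3 node) is fine
  # as-is: ape only needs internal ids in n+1..n+n_internal, root first.
  # Our internal ids are already n+1..next_node-1; the final edge connects
  # the last internal node down to an earlier one, so re-orient edges away
  # from the root.
  phy <- list(
    edge = edges, edge.length = lens, tip.label = labels,
    Nnode = as.integer(n_internal)
  )
  class(phy) <- "phylo"
  phy <- orient_phylo(phy, root = node_of[aj])
  ape::reorder.phylo(phy, "cladewise")
}

# re-orient an undirected edge list so every edge points away from `root`,
# and renumber internal nodes in ape's convention (root = ntip + 1)
orient_phylo <- function(phy, root) {
  edges <- phy$edge; lens <- phy$edge.length
  ntip <- length(phy$tip.label)
  adj <- list()
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[as.character(a)]] <- rbind(adj[[as.character(a)]], c(b, e))
    adj[[as.character(b)]] <- rbind(adj[[as.character(b)]], c(a, e))
  }
  new_edges <- matrix(0L, 0, 2); new_lens <- numeric(0)
  visited <- integer(0)
  stack <- root
  parent <- setNames(NA_integer_, as.character(root))
  order_nodes <- integer(0)
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    visited <- c(visited, v)
    order_nodes <- c(order_nodes, v)
    nb <- adj[[as.character(v)]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1]; e <- nb[k, 2]
      if (w %in% visited) next
      new_edges <- rbind(new_edges, c(v, w))
      new_lens <- c(new_lens, lens[e])
      stack <- c(stack, w)
    }
  }
  internal_old <- order_nodes[order_nodes > ntip]
  map <- setNames(seq_along(internal_old) + ntip, as.character(internal_old))
  remap <- function(x) ifelse(x > ntip, map[as.character(x)], x)
  out <- list(
    edge = cbind(as.integer(remap(new_edges[, 1])), as.integer(remap(new_edges[, 2]))),
    edge.length = new_lens,
    tip.label = phy$tip.label,
    Nnode = phy$Nnode
  )
  class(out) <- "phylo"
  out
}

# canonical string encoding of each internal (non-trivial) bipartition of
# an unrooted tree: the side not containing the first tip label, sorted.
# `min_edge` drops bipartitions whose internal edge has (near-)zero
# length — a clamped or zero-length edge is an unresolved polytomy, not a
# supported split.
tree_bipartitions <- function(tree, min_edge = 0) {
  ntip <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
    if (child <= ntip) next
    side <- desc[[child]]
    other <- setdiff(tree$tip.label, side)
    if (length(side) <= 1 || length(other) <= 1) next
    if (!is.null(tree$edge.length) && tree$edge.length[e] < min_edge) next
    canon <- if (tree$tip.label[1] %in% side) other else side
    out <- c(out, paste(sort(canon), collapse = "|"))
  }
  unique(out)
}

#' Test whether a set of leaves is monophyletic (unrooted sense)
#'
#' True when some edge of the tree bipartitions the leaves into exactly
#' `group_labels` versus the rest.
#'
#' @param tree a `phylo` object.
#' @param group_labels character vector of leaf labels.
#' @return list with `monophyletic` (logical) and `bipartition` (the
#'   canonical label set string when true, else `NA`).
#' @export
is_group_monophyletic <- function(tree, group_labels) {
  unknown <- setdiff(group_labels, tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("unknown leaf label(s): ", paste(unknown, collapse = ", ")))
  }
  other <- setdiff(tree$tip.label, group_labels)
  if (length(group_labels) <= 1 || length(other) == 0) {
    return(list(monophyletic = TRUE, bipartition = paste(sort(group_labels), collapse = "|")))
  }
  canon <- if (tree$tip.label[1] %in% group_labels) {
    paste(sort(other), collapse = "|")
  } else {
    paste(sort(group_labels), collapse = "|")
  }
  hit <- canon %in% tree_bipartitions(tree)
  list(monophyletic = hit,
       bipartition = if (hit) paste(sort(group_labels), collapse = "|") else NA_character_)
}

#' Neighbor-joining tree with column-resampling bootstrap support
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree for each replicate, and annotates each internal bipartition
#' of the full-data tree with the percentage of replicates containing it.
#'
#' @param alignment nucleotide [as_alignment()] tibble.
#' @param n_reps number of bootstrap replicates (the study-scale default in
#'   the field is 1000; 100 suffices for clear-cut splits).
#' @param seed RNG seed for reproducibility.
#' @param ambiguity ambiguity-code treatment passed to [p_distance()];
#'   defaults to `"strict"` for tree building: identical-code comparison
#'   retains the heterozygosity signal that separates the groups in
#'   consensus data (see the methods vignette for the comparison of the
#'   three treatments).
#' @return `phylo` with `node.label` holding integer support percentages
#'   (root label empty), plus attribute `support` (named vector keyed by
#'   canonical bipartition).
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1,
                              ambiguity = "strict") {
  stopifnot(n_reps >= 1)
  alignment <- as_alignment(alignment)
  L <- alignment_length(alignment)
  if (L < 2) abort("alignment must have at least 2 columns")
  m <- alignment_matrix(alignment)
  main <- neighbor_joining(p_distance(alignment, ambiguity = ambiguity))
  main_parts <- tree_bipartitions(main)
  counts <- setNames(numeric(length(main_parts)), main_parts)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- alignment
    rep_aln$residues <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    tr <- tryCatch(
      neighbor_joining(p_distance(as_alignment(rep_aln), ambiguity = ambiguity)),
      error = function(e) NULL
    )
    if (is.null(tr)) next
    hits <- intersect(tree_bipartitions(tr, min_edge = 1e-12), main_parts)
    counts[hits] <- counts[hits] + 1
  }
  support <- round(100 * counts / n_reps)
  attr(main, "support") <- support
  main <- annotate_support(main, support)
  main
}

# put supports on internal node labels of the main tree
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labs <- attr(ape::prop.part(tree), "labels")
  parts <- ape::prop.part(tree)
  node.label <- character(tree$Nnode)
  for (k in seq_along(parts)) {
    side <- labs[parts[[k]]]
    other <- setdiff(labs, side)
    if (length(side) <= 1 || length(other) <= 1) { node.label[k] <- ""; next }
    canon <- if (labs[1] %in% side) paste(sort(other), collapse = "|") else paste(sort(side), collapse = "|")
    node.label[k] <- if (canon %in% names(support)) as.character(support[[canon]]) else ""
  }
  tree$node.label <- node.label
  tree
}

#' Write a tree as a newick string or file
#'
#' @param tree `phylo` object.
#' @param path optional file path; when `NULL` the newick string is
#'   returned.
#' @return newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo") || length(tree$tip.label) == 0) {
    abort("not a valid tree")
  }
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a newick tree
#'
#' @param x newick string or file path.
#' @return `phylo` object.
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) abort("could not parse newick input")
  tr
}
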