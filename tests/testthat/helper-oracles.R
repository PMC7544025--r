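# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately written along a different code path than the
# package implementation it checks.

# IUPAC expansion sourced from Biostrings, not the package's own table
oracle_expand <- function(code) {
  if (code == ".") return(character(0))
  strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
}

# brute-force diagnostic marker enumeration over all (position, allele)
# pairs, with carrier/contrast logic written from scratch
oracle_markers <- function(matrix, target_group, theta, require_contrast_fixed) {
  tab <- as.data.frame(matrix)
  contrast_group <- setdiff(c("high", "low"), target_group)
  out <- list()
  for (pos in sort(unique(tab$position))) {
    at <- tab[tab$position == pos, ]
    tgt <- at$call[at$group == target_group & at$call != "."]
    ctr <- at$call[at$group == contrast_group & at$call != "."]
    if (length(tgt) == 0 || length(ctr) == 0) next
    if (require_contrast_fixed) {
      u <- unique(ctr)
      if (length(u) != 1 || !u %in% c("A", "C", "G", "T")) next
    }
    best <- NULL
    for (a in c("A", "C", "G", "T")) {
      ctr_carries <- any(vapply(ctr, function(cc) a %in% oracle_expand(cc), TRUE))
      if (ctr_carries) next
      carriers <- sum(vapply(tgt, function(cc) a %in% oracle_expand(cc), TRUE))
      pen <- carriers / length(tgt)
      if (pen < theta) next
      if (is.null(best) || pen > best$pen ||
          (pen == best$pen && a < best$allele)) {
        best <- list(pos = pos, allele = a, pen = pen)
      }
    }
    if (!is.null(best)) out[[length(out) + 1]] <- best
  }
  do.call(rbind, lapply(out, function(b) {
    data.frame(position = b$pos, allele = b$allele, penetrance = b$pen)
  }))
}

# random small allele matrix with both groups represented
random_matrix <- function(n_pos = 5, n_ind = 8, seed = 1) {
  set.seed(seed)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", ".")
  w <- c(rep(8, 4), rep(2, 6), 1)
  groups <- c("high", "low", sample(c("high", "low"), n_ind - 2, replace = TRUE))
  positions <- sort(sample(1:500, n_pos))
  tibble::tibble(
    position = rep(positions, each = n_ind),
    individual_id = rep(paste0("ind", seq_len(n_ind)), times = n_pos),
    species_code = rep("syn", n_pos * n_ind),
    group = rep(groups, times = n_pos),
    call = sample(codes, n_pos * n_ind, replace = TRUE, prob = w)
  ) |> allele_matrix()
}

# exhaustive affine-gap alignment score: enumerate every alignment path,
# scoring gap runs as open + (len - 1) * extend
oracle_align_score <- function(a, b, S, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < m) {
      rec(i + 1, j + 1, "M", acc + S[av[i + 1], bv[j + 1]])
    }
    if (i < n) {
      step <- if (last == "X") gap_extend else gap_open
      rec(i + 1, j, "X", acc + step)
    }
    if (j < m) {
      step <- if (last == "Y") gap_extend else gap_open
      rec(i, j + 1, "Y", acc + step)
    }
    invisible(NULL)
  }
  rec(0, 0, "start", 0)
  best
}

# independent top-down memoized formulation of the same affine problem
# (used where full enumeration is too large)
oracle_align_score_memo <- function(a, b, S, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(hash = TRUE)
  f <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == n && j == m) {
      0
    } else {
      cand <- -Inf
      if (i < n && j < m) {
        cand <- max(cand, S[av[i + 1], bv[j + 1]] + f(i + 1, j + 1, "M"))
      }
      if (i < n) {
        cand <- max(cand, (if (last == "X") gap_extend else gap_open) + f(i + 1, j, "X"))
      }
      if (j < m) {
        cand <- max(cand, (if (last == "Y") gap_extend else gap_open) + f(i, j + 1, "Y"))
      }
      cand
    }
    memo[[key]] <- res
    res
  }
  f(0, 0, "start")
}

# toy substitution matrix over a reduced alphabet
toy_matrix <- function(match = 2, mismatch = -1, alphabet = c("A", "C")) {
  S <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(S) <- match
  S
}

# map reference residue indices to alignment columns by linear scan
oracle_map_columns <- function(ref_row, positions) {
  chars <- strsplit(ref_row, "")[[1]]
  cols <- integer(length(positions))
  seen <- 0
  for (j in seq_along(chars)) {
    if (chars[j] != "-") {
      seen <- seen + 1
      hit <- which(positions == seen)
      if (length(hit)) cols[hit] <- j
    }
  }
  cols
}

# sequence tibble builder for small hand-made alignments
seq_tbl <- function(ids, residues, moltype = "dna",
                    group = rep("unassigned", length(ids)),
                    species = rep("", length(ids))) {
  tibble::tibble(id = ids, species_code = species, group = group,
                 moltype = moltype, residues = residues)
}

fixture_matrix <- function() {
  read_allele_matrix(mesa_example("table2_sabp2.tsv"))
}
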