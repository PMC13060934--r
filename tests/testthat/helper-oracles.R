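# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / direct dynamic programming, not by
# calling the package's own code paths.

# IUPAC monoisotopic masses, written out independently of the package
# constants, for hand-sum mass checks.
ORACLE_MASS <- c(C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462,
                 S = 31.97207069, P = 30.97376151)

hand_mass <- function(counts) sum(ORACLE_MASS[names(counts)] * counts)

# --- Smith-Waterman oracle (affine gaps, BLOSUM62) -------------------------
# Full Gotoh DP over all cells, plus enumeration of every co-optimal local
# alignment by traceback branching. Returns the optimal score and the set of
# (identity, coverage) values realized by co-optimal alignments.
sw_oracle <- function(query, subject, open = 11, ext = 1, max_paths = 500) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q)
  m <- length(s)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in subject (consumes query residue)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in query (consumes subject residue)
  for (i in 1:n) {
    for (j in 1:m) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Iy[i + 1, j] - ext)
      sub <- B[q[i], s[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + sub)
    }
  }
  best <- max(M)
  if (best == 0) return(list(score = 0, stats = data.frame(identity = 0, coverage = 0)))
  paths <- list()
  # traceback: each state emits its column, then branches to all optimal
  # predecessors; a path ends when the M chain reaches value 0
  walk <- function(i, j, state, cols) {
    if (length(paths) >= max_paths) return()
    if (state == "M") {
      sub <- B[q[i - 1], s[j - 1]]
      v <- M[i, j] - sub
      cols <- c(list(c(q[i - 1], s[j - 1], j - 1)), cols)
      if (abs(v) < 1e-9 &&
          (M[i - 1, j - 1] >= 0)) {
        paths[[length(paths) + 1]] <<- cols
      }
      if (v > 1e-9) {
        if (abs(M[i - 1, j - 1] - v) < 1e-9) walk(i - 1, j - 1, "M", cols)
        if (abs(Ix[i - 1, j - 1] - v) < 1e-9) walk(i - 1, j - 1, "Ix", cols)
        if (abs(Iy[i - 1, j - 1] - v) < 1e-9) walk(i - 1, j - 1, "Iy", cols)
      }
    } else if (state == "Ix") {
      cols <- c(list(c(q[i - 1], "-", NA)), cols)
      if (abs(M[i - 1, j] - (open + ext) - Ix[i, j]) < 1e-9) walk(i - 1, j, "M", cols)
      if (abs(Ix[i - 1, j] - ext - Ix[i, j]) < 1e-9) walk(i - 1, j, "Ix", cols)
    } else {
      cols <- c(list(c("-", s[j - 1], j - 1)), cols)
      if (abs(M[i, j - 1] - (open + ext) - Iy[i, j]) < 1e-9) walk(i, j - 1, "M", cols)
      if (abs(Iy[i, j - 1] - ext - Iy[i, j]) < 1e-9) walk(i, j - 1, "Iy", cols)
    }
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      if (abs(M[i, j] - best) < 1e-9) walk(i, j, "M", list())
    }
  }
  stats <- unique(do.call(rbind, lapply(paths, function(cols) {
    qc <- vapply(cols, `[`, character(1), 1)
    sc <- vapply(cols, `[`, character(1), 2)
    sj <- suppressWarnings(as.integer(vapply(cols, `[`, character(1), 3)))
    matches <- sum(qc == sc & qc != "-" & qc != "X")
    data.frame(identity = matches / length(cols) * 100,
               coverage = (max(sj, na.rm = TRUE) - min(sj, na.rm = TRUE) + 1) / m)
  })))
  list(score = best, stats = stats)
}

# Score a gapped alignment directly from its columns: BLOSUM62 on residue
# pairs, affine cost open + ext * L per gap run.
score_alignment <- function(query_aligned, subject_aligned, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  qc <- strsplit(query_aligned, "")[[1]]
  sc <- strsplit(subject_aligned, "")[[1]]
  total <- 0
  in_gap <- FALSE
  for (i in seq_along(qc)) {
    if (qc[i] == "-" || sc[i] == "-") {
      total <- total - ext - if (in_gap) 0 else open
      in_gap <- TRUE
    } else {
      total <- total + B[qc[i], sc[i]]
      in_gap <- FALSE
    }
  }
  total
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- Mann-Whitney enumeration oracle ---------------------------------------
# Exact two-sided p by enumerating all C(n+m, n) group labelings of the
# pooled values; U from definition (pairwise comparisons), two-sided p
# doubles the smaller tail.
mwu_oracle <- function(x, y) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n <- length(x)
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(length(pooled), n)
  u_all <- apply(labelings, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  list(U = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# --- Hypergeometric enumeration oracle -------------------------------------
# P(X >= k) by enumerating all C(N, n) draws of an urn with K successes.
hypergeom_oracle <- function(N, K, n, k) {
  urn <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(idx) sum(urn[idx]))
  mean(hits >= k)
}

# Back-translate a protein with the first codon of each amino acid
# (deterministic; independent of the package's random back-translation).
codon_encode <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) names(gc)[gc == a][1], character(1)),
        collapse = "")
}
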