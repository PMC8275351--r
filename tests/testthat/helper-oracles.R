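# Independent brute-force oracles used to validate the package's exact
# solvers.  These deliberately share no code with the implementation: plain
# recursive enumeration over integer compositions.

# all nonnegative integer vectors of length t summing to total (rows)
compositions <- function(total, t) {
  if (t == 1L) return(matrix(total, 1L, 1L))
  out <- vector("list", total + 1L)
  for (v in 0:total) {
    rest <- compositions(total - v, t - 1L)
    out[[v + 1L]] <- cbind(v, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

# brute-force solution set of B n = c, sum(n) = total (B is L x t)
brute_solutions <- function(B, cvec, total) {
  comp <- compositions(total, ncol(B))
  keep <- rep(TRUE, nrow(comp))
  for (j in seq_len(nrow(B)))
    keep <- keep & (comp %*% B[j, ] == cvec[j])
  m <- comp[keep, , drop = FALSE]
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# exact multinomial event probability by exhaustive composition sums;
# event: list(lo, hi) count bounds plus optional beacon consistency given a
# block's pattern matrix and a present/absent vector
exact_event_probability <- function(freqs, two_N, lo, hi,
                                    patterns = NULL, present = NULL) {
  t_n <- length(freqs)
  comp <- compositions(two_N, t_n)
  ok <- rep(TRUE, nrow(comp))
  for (i in seq_len(t_n))
    ok <- ok & comp[, i] >= lo[i] & comp[, i] <= hi[i]
  if (!is.null(present)) {
    M <- comp %*% patterns            # row = per-site minor counts
    for (j in seq_along(present))
      ok <- ok & (if (present[j]) M[, j] >= 1 else M[, j] == 0)
  }
  rows <- which(ok)
  if (!length(rows)) return(0)
  sum(vapply(rows, function(r) stats::dmultinom(comp[r, ], prob = freqs),
             numeric(1L)))
}

# exhaustive novel-haplotype search for d = 1: smallest feasible count k
# (sweeping 1..2N), then minimum minor-allele z at that k, ties broken by
# lexicographically smallest pattern; z must differ from all known patterns
brute_novel_d1 <- function(B, cvec, two_N, known_patterns) {
  L <- nrow(B); t_n <- ncol(B)
  known_keys <- apply(known_patterns, 1L, paste0, collapse = "")
  zs <- as.matrix(expand.grid(rep(list(0:1), L)))[, L:1, drop = FALSE]
  for (k in seq_len(two_N)) {
    comp <- compositions(two_N - k, t_n)
    sums <- comp %*% t(B)             # rows = per-site known contributions
    best <- NULL
    for (q in seq_len(nrow(zs))) {
      z <- zs[q, ]
      if (paste0(z, collapse = "") %in% known_keys) next
      target <- cvec - k * z
      if (any(target < 0)) next
      hit <- rep(TRUE, nrow(comp))
      for (j in seq_len(L)) hit <- hit & (sums[, j] == target[j])
      if (!any(hit)) next
      cand <- list(k = k, z = z, obj = sum(z),
                   key = paste0(z, collapse = ""))
      if (is.null(best) || cand$obj < best$obj ||
          (cand$obj == best$obj && cand$key < best$key))
        best <- cand
    }
    if (!is.null(best)) return(best)
  }
  NULL
}

# small random block + frequency table fixtures for property tests
random_system <- function(t_max = 6L, two_N_max = 20L, L_max = 6L,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t_n <- sample(2:t_max, 1L)
  L_min <- max(2L, ceiling(log2(2 * t_n)))   # room for distinct patterns
  L <- sample(L_min:max(L_min, L_max), 1L)
  two_N <- 2L * sample(2:(two_N_max %/% 2L), 1L)
  repeat {
    B <- matrix(rbinom(L * t_n, 1L, 0.45), L, t_n)
    if (!anyDuplicated(apply(t(B), 1L, paste0, collapse = ""))) break
  }
  truth <- as.integer(rmultinom(1L, two_N, rep(1 / t_n, t_n)))
  cvec <- as.integer(B %*% truth)
  list(B = B, c = cvec, two_N = two_N, truth = truth)
}

# haploblock wrapper around an arbitrary pattern matrix
block_from_patterns <- function(patterns, freqs, block_id = "TB") {
  L <- ncol(patterns)
  rownames(patterns) <- paste0("h", seq_len(nrow(patterns)))
  maf <- pmin(0.5, as.numeric(crossprod(patterns, freqs)))
  sites <- data.frame(site_id = paste0("s", seq_len(L)),
                      position = seq_len(L) * 10L,
                      major_allele = "A", minor_allele = "G",
                      public_maf = maf)
  haploblock(block_id, sites, patterns, freqs)
}
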