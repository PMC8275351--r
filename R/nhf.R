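#' Formulate the novel-haplotype reconstruction problem
#'
#' When no assignment of known-haplotype counts reproduces the published
#' frequency table, one or more *novel* haplotypes (patterns unseen in the
#' public panel) must be present.  With `d` novel haplotypes of fixed counts
#' `k_1..k_d` and unknown 0/1 allele vectors `z_m`, the count-form
#' constraints are, per site j,
#' `sum_i b_ij n_i + sum_m k_m z_mj = c_j`, with
#' `sum_i n_i + sum_m k_m = 2N`, `n_i >= 0` integer, `z_mj` binary, and every
#' `z_m` distinct from all known patterns and from each other.  The objective
#' is to minimise the total number of minor alleles `sum_m sum_j z_mj` (a
#' novel haplotype should still be mostly major alleles).  This returns the
#' problem instance; [solve_novel_ilp] solves it exactly.
#'
#' @param block a [haploblock].
#' @param ft a [freq_table].
#' @param d number of novel haplotypes (>= 1).
#' @param k_vector their fixed database counts, `d` positive integers.
#' @return a list of class `novel_ilp` with the coefficient matrix, counts,
#'   totals and `k_vector`.
#' @export
formulate_ilp <- function(block, ft, d, k_vector) {
  if (d <= 0) stop("d must be a positive integer")
  k_vector <- as.integer(k_vector)
  if (length(k_vector) != d || any(k_vector < 1L))
    stop("k_vector must hold d positive counts")
  cs <- build_constraints(block, ft)
  if (sum(k_vector) > cs$two_N)
    stop("novel counts exceed database size 2N")
  structure(list(B = cs$B, c = cs$c, two_N = cs$two_N, d = as.integer(d),
                 k_vector = k_vector, block = block),
            class = "novel_ilp")
}

#' @export
print.novel_ilp <- function(x, ...) {
  cat("Novel-haplotype reconstruction instance: d =", x$d,
      "novel haplotype(s) with counts", paste(x$k_vector, collapse = ", "),
      "\n  minimise total minor alleles s.t.",
      nrow(x$B), "site constraints, 2N =", x$two_N, "\n")
  invisible(x)
}

# All ways to write residual value r as sum_m k_m z_m with binary z.
# Returns a list of 0/1 vectors of length d (possibly several when counts tie).
residual_decompositions <- function(r, k_vector) {
  d <- length(k_vector)
  out <- list()
  for (mask in 0:(2^d - 1L)) {
    z <- as.integer(intToBits(mask)[seq_len(d)])
    if (sum(k_vector * z) == r) out[[length(out) + 1L]] <- z
  }
  out
}

#' Exactly solve a novel-haplotype instance
#'
#' Exhaustively enumerates, by depth-first search with residual pruning, the
#' known-haplotype count vectors whose per-site residuals `c_j - B n` are
#' subset sums of the fixed novel counts, decodes each residual pattern into
#' novel allele vectors, enforces distinctness (novel patterns differ from
#' every known pattern and from each other), and returns a solution with the
#' minimum total minor-allele count.  Ties are broken by the
#' lexicographically smallest concatenated novel pattern.  This is an exact
#' combinatorial solver: its optimality is the enumeration itself.
#'
#' @param ilp a [formulate_ilp] instance.
#' @param max_solutions cap on the underlying count enumeration.
#' @return a list of class `novel_solution` (`feasible`, `z` d x L 0/1
#'   matrix, `counts` = k_vector, `n` known counts, `objective`), or
#'   `feasible = FALSE` when no admissible assignment exists.
#' @export
solve_novel_ilp <- function(ilp, max_solutions = 1e5) {
  k <- ilp$k_vector
  slack <- sort(unique(vapply(0:(2^ilp$d - 1L), function(mask)
    sum(k * as.integer(intToBits(mask)[seq_len(ilp$d)])), numeric(1L))))
  enum <- tryCatch(
    enumerate_counts(ilp$B, ilp$c, ilp$two_N - sum(k),
                     slack_set = as.integer(slack),
                     max_solutions = max_solutions),
    haplomember_capacity_error = function(e) {
      warning("search budget exhausted for counts ",
              paste(k, collapse = ","), "; treated as infeasible")
      NULL
    })
  if (is.null(enum) || nrow(enum$n) == 0L) return(infeasible_novel(ilp))
  known_keys <- pattern_strings(ilp$block$patterns)
  L <- nrow(ilp$B)
  best <- NULL
  for (s in seq_len(nrow(enum$n))) {
    r <- enum$resid[s, ]
    decs <- lapply(r, residual_decompositions, k_vector = k)
    # expand per-site decomposition choices (ties only arise for equal k_m)
    combos <- expand_decompositions(decs, cap = 4096L)
    for (zz in combos) {
      z <- matrix(zz, nrow = ilp$d, ncol = L)   # filled column-by-column
      keys <- apply(z, 1L, paste0, collapse = "")
      if (anyDuplicated(keys) || any(keys %in% known_keys)) next
      obj <- sum(z)
      cand <- list(z = z, n = enum$n[s, ], objective = obj,
                   key = paste(keys, collapse = "|"))
      if (is.null(best) || obj < best$objective ||
          (obj == best$objective && cand$key < best$key))
        best <- cand
    }
  }
  if (is.null(best)) return(infeasible_novel(ilp))
  structure(list(feasible = TRUE, d = ilp$d, z = best$z, counts = k,
                 n = best$n, objective = best$objective,
                 two_N = ilp$two_N, block_id = ilp$block$block_id,
                 haplotype_ids = rownames(ilp$block$patterns)),
            class = "novel_solution")
}

infeasible_novel <- function(ilp) {
  structure(list(feasible = FALSE, d = ilp$d, counts = ilp$k_vector,
                 two_N = ilp$two_N, block_id = ilp$block$block_id),
            class = "novel_solution")
}

# cartesian product of per-site decomposition lists, capped for safety
expand_decompositions <- function(decs, cap = 4096L) {
  sizes <- lengths(decs)
  if (any(sizes == 0L)) return(list())
  total <- prod(sizes)
  if (total > cap) {
    warning("ambiguous residual decompositions truncated at ", cap)
    total <- cap
  }
  out <- vector("list", total)
  idx <- rep(1L, length(decs))
  for (q in seq_len(total)) {
    out[[q]] <- unlist(lapply(seq_along(decs), function(j) decs[[j]][[idx[j]]]))
    # odometer increment
    j <- 1L
    while (j <= length(decs)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L; j <- j + 1L
    }
  }
  out
}

#' @export
print.novel_solution <- function(x, ...) {
  if (!x$feasible) {
    cat("Novel-haplotype reconstruction: infeasible for counts",
        paste(x$counts, collapse = ", "), "\n")
    return(invisible(x))
  }
  cat("Novel-haplotype reconstruction: d =", x$d, "\n")
  for (m in seq_len(x$d))
    cat(sprintf("  novel%d: %s  (count %d, frequency %.4g)\n",
        m, paste0(x$z[m, ], collapse = ""), x$counts[m],
        x$counts[m] / x$two_N))
  cat("  total minor alleles:", x$objective, "\n")
  invisible(x)
}

#' Reconstruct novel haplotypes from a frequency table (NHF)
#'
#' Sweeps the novel-haplotype counts in increasing total footprint -- for
#' d = 1, k = 1, 2, ..., 2N; for d = 2, nondecreasing pairs (k1 <= k2) in
#' increasing k1 + k2 then k1 -- and returns the first feasible exact
#' solution, i.e. the smallest-count novel explanation of the table.  The
#' outer loop raises d from 1 to `d_max` (default 2) when no single novel
#' haplotype explains the table.  Complexity grows as O((2N)^d), which is why
#' d is capped small.
#'
#' @param block a [haploblock].
#' @param ft a [freq_table].
#' @param d_max maximum number of distinct novel haplotypes to try.
#' @param max_k cap on each novel count sweep (default 2N).
#' @param max_solutions cap for the inner enumerations.
#' @return a `novel_solution`; `feasible = FALSE` signals not-found (no
#'   exception).
#' @examples
#' blk <- toy_block()
#' db <- genome_db(3, rbind(blk$patterns, novel = c(0L, 1L, 1L, 0L)),
#'                 c(2, 1, 1, 2))
#' ft <- summarize_database(db, blk)
#' reconstruct_novel(blk, ft)   # recovers the pattern 0110
#' @export
reconstruct_novel <- function(block, ft, d_max = 2, max_k = NULL,
                              max_solutions = 1e5) {
  two_N <- 2L * ft$n_genomes
  if (is.null(max_k)) max_k <- two_N
  for (d in seq_len(d_max)) {
    for (kv in k_sweep(d, min(max_k, two_N))) {
      if (sum(kv) > two_N) next
      sol <- solve_novel_ilp(formulate_ilp(block, ft, d, kv),
                             max_solutions = max_solutions)
      if (sol$feasible) return(sol)
    }
  }
  structure(list(feasible = FALSE, d = NA_integer_, counts = integer(),
                 two_N = two_N, block_id = block$block_id),
            class = "novel_solution")
}

# count-vector sweep order: increasing total, then increasing k1
k_sweep <- function(d, max_k) {
  if (d == 1L) return(lapply(seq_len(max_k), identity))
  if (d == 2L) {
    out <- list()
    for (tot in 2:(2L * max_k))
      for (k1 in seq_len(tot %/% 2L))
        if (k1 <= max_k && (tot - k1) <= max_k)
          out[[length(out) + 1L]] <- c(k1, tot - k1)
    return(out)
  }
  stop("d > 2 sweep not supported")
}

#' Validate reconstructed novel haplotypes by KHF membership testing
#'
#' Augments the block's known panel with the reconstructed pattern(s),
#' assigning each a small public frequency (one pseudo-observation in a
#' nominal public panel), then reruns [khf_test] on each novel pattern
#' against the same frequency table and empirical null.  A reconstructed
#' haplotype whose p-value falls below `alpha` is declared present.  Patterns
#' lying at Hamming distance 1 from a common known haplotype are flagged as
#' possible de novo mutations or sequencing artifacts.
#'
#' @param block a [haploblock] (the reduced panel used for reconstruction).
#' @param ft the [freq_table].
#' @param solution a feasible `novel_solution`.
#' @param null_dist a [null_dist] for p-values.
#' @param alpha significance level.
#' @param novel_frequency public frequency assigned to each reconstructed
#'   haplotype; default `1 / (2 * panel_genomes)`.
#' @param panel_genomes nominal size (genomes) of the public panel backing
#'   the default `novel_frequency`.
#' @param common_threshold frequency above which a known haplotype counts as
#'   "common" for the one-SNV artifact flag.
#' @return a list of class `novel_validation`: per-novel-haplotype
#'   `haplo_inference` results, `artifact_flags`, and the augmented block.
#' @export
validate_novel <- function(block, ft, solution, null_dist = NULL,
                           alpha = 0.05, novel_frequency = NULL,
                           panel_genomes = 1000L,
                           common_threshold = 0.05) {
  if (!isTRUE(solution$feasible))
    stop("cannot validate a not-found reconstruction")
  if (is.null(novel_frequency))
    novel_frequency <- 1 / (2 * panel_genomes)
  d <- solution$d
  aug_pats <- rbind(block$patterns, solution$z)
  rownames(aug_pats) <- c(rownames(block$patterns),
                          paste0("novel", seq_len(d)))
  f_aug <- c(block$frequencies * (1 - d * novel_frequency),
             rep(novel_frequency, d))
  aug <- haploblock(block$block_id, block$sites, aug_pats, f_aug)
  t_known <- n_haplotypes(block)
  cs <- build_constraints(aug, ft)
  ss <- enumerate_solutions(cs)
  if (ss$outcome == "none")
    stop("augmented system infeasible: reconstruction inconsistent ",
         "with the table")
  results <- lapply(seq_len(d), function(m)
    khf_test(aug, ft, t_known + m, null_dist = null_dist, alpha = alpha,
             solutions = ss))
  flags <- vapply(seq_len(d), function(m) {
    dist <- colSums(abs(t(block$patterns) - solution$z[m, ]))
    any(dist == 1L & block$frequencies >= common_threshold)
  }, logical(1L))
  structure(list(results = results, artifact_flags = flags,
                 augmented_block = aug, solution = solution, alpha = alpha),
            class = "novel_validation")
}

#' @export
print.novel_validation <- function(x, ...) {
  cat("Validation of", length(x$results), "reconstructed haplotype(s):\n")
  for (m in seq_along(x$results)) {
    r <- x$results[[m]]
    cat(sprintf("  %s: posterior %.4g, p = %s -> %s%s\n", r$target,
                r$posterior,
                if (is.na(r$p_value)) "NA" else format(r$p_value, digits = 3),
                if (isTRUE(r$decision)) "present" else "not confirmed",
                if (x$artifact_flags[m])
                  "  [1 SNV from a common haplotype: possible artifact]"
                else ""))
  }
  invisible(x)
}
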