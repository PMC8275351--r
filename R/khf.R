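#' Linear constraint system of a frequency table
#'
#' Each site j of the haploblock imposes one linear constraint on the unknown
#' database counts n_1..n_t of the known haplotypes:
#' `sum_i b_ij * n_i = c_j`, where `b_ij` is 1 iff haplotype i carries the
#' minor allele at site j and `c_j` is the published minor-allele count.  The
#' normalisation `sum_i n_i = 2N` (frequencies sum to one, in count form) is
#' carried as the system's total.
#'
#' @param block a [haploblock].
#' @param ft a [freq_table] over the same sites, in the same order.
#' @return an object of class `constraint_system` with elements `B` (L x t
#'   0/1 matrix), `c` (length-L integer right-hand side), `two_N`, and the
#'   originating `block`.
#' @examples
#' blk <- toy_block()
#' ft <- freq_table("toy", blk$sites$site_id, blk$sites$minor_allele,
#'                  c(3, 1, 2, 3), n_genomes = 2)
#' build_constraints(blk, ft)
#' @export
build_constraints <- function(block, ft) {
  if (!identical(as.character(ft$site_id), as.character(block$sites$site_id)))
    stop("frequency-table sites do not match block sites")
  structure(list(B = t(block$patterns),        # L x t, rows = sites
                 c = ft$counts,
                 two_N = 2L * ft$n_genomes,
                 block = block),
            class = "constraint_system")
}

#' @export
print.constraint_system <- function(x, ...) {
  t_n <- ncol(x$B)
  hap <- colnames(x$B)
  if (is.null(hap)) hap <- paste0("x", seq_len(t_n))
  for (j in seq_len(nrow(x$B))) {
    lhs <- paste0("n(", hap[x$B[j, ] == 1L], ")", collapse = " + ")
    if (lhs == "") lhs <- "0"
    cat(lhs, "=", x$c[j], "\n")
  }
  cat(paste0("n(", hap, ")", collapse = " + "), "=", x$two_N, "\n")
  invisible(x)
}

# Exact enumeration of nonnegative integer count vectors n with
#   B %*% n = c - slack_j,  slack_j in slack_set,  sum(n) = total.
# Exact routes, tried in order (slack {0} only for the first two):
#   * full column rank: the real solution of the linear system is unique, so
#     the only possible integer solution is its rounding -- verified exactly
#     in integer arithmetic (unique or none, no search);
#   * nullity 1: solutions lie on the line n0 + alpha v; walk the integer
#     values of one coordinate with the largest |v| entry, verify each
#     candidate exactly;
#   * otherwise depth-first search with constraint propagation (compiled),
#     under a node budget; exceeding the budget raises a capacity error, the
#     signal that the system is too underdetermined to enumerate completely.
# Returns list(n = m x t matrix, resid = m x L matrix of terminal residuals).
enumerate_counts <- function(B, cvec, total, slack_set = 0L,
                             max_solutions = 1e5, max_nodes = 2e7) {
  L <- nrow(B); t_n <- ncol(B)
  slack_set <- sort(unique(as.integer(slack_set)))
  if (identical(slack_set, 0L)) {
    A <- rbind(B, rep(1, t_n))
    b <- c(cvec, total)
    qa <- qr(A)
    none <- list(n = matrix(0L, 0L, t_n), resid = matrix(0L, 0L, L))
    if (qa$rank == t_n) {
      x <- qr.coef(qa, b)
      cand <- as.integer(round(x))
      ok <- all(abs(x - cand) < 1e-6) && all(cand >= 0L) &&
        all(as.integer(A %*% cand) == as.integer(b))
      return(if (ok)
        list(n = matrix(cand, 1L, t_n), resid = matrix(0L, 1L, L))
      else none)
    }
    if (qa$rank == t_n - 1L && t_n >= 2L) {
      x0 <- qr.coef(qa, b)           # one least-squares solution
      x0[is.na(x0)] <- 0
      if (max(abs(A %*% x0 - b)) > 1e-6) return(none)
      # null-space direction: last column of Q from the QR of t(A)
      v <- qr.Q(qr(t(A)), complete = TRUE)[, t_n]
      i0 <- which.max(abs(v))
      sols <- list()
      for (ni in 0:total) {
        alpha <- (ni - x0[i0]) / v[i0]
        nn <- x0 + alpha * v
        cand <- as.integer(round(nn))
        if (all(abs(nn - cand) < 1e-6) && all(cand >= 0L) &&
            all(as.integer(A %*% cand) == as.integer(b)))
          sols[[length(sols) + 1L]] <- cand
      }
      if (!length(sols)) return(none)
      n <- unique(do.call(rbind, sols))
      if (nrow(n) > max_solutions)
        stop(capacity_error(max_solutions))
      ord <- do.call(order, as.data.frame(n))
      return(list(n = n[ord, , drop = FALSE],
                  resid = matrix(0L, nrow(n), L)))
    }
  }
  storage.mode(B) <- "integer"
  out <- .cpp_enumerate_counts(B, as.integer(cvec), as.integer(total),
                               slack_set, max_solutions, max_nodes)
  if (isTRUE(out$overflow) || isTRUE(out$budget_exceeded))
    stop(capacity_error(max_solutions,
                        budget = isTRUE(out$budget_exceeded)))
  if (nrow(out$n) == 0L)
    return(list(n = matrix(0L, 0L, t_n), resid = matrix(0L, 0L, L)))
  ord <- do.call(order, as.data.frame(out$n))
  list(n = out$n[ord, , drop = FALSE], resid = out$resid[ord, , drop = FALSE])
}

capacity_error <- function(max_solutions, budget = FALSE) {
  structure(class = c("haplomember_capacity_error", "error", "condition"),
            list(message = if (budget)
              "enumeration search budget exceeded; system too underdetermined"
            else paste0("more than ", max_solutions,
                        " solutions; raise max_solutions"),
              call = NULL))
}

#' Enumerate all integer solutions of a constraint system
#'
#' Finds every nonnegative integer assignment of database counts to the known
#' haplotypes that reproduces the published per-site minor-allele counts and
#' sums to 2N, by depth-first search with per-site residual pruning and
#' constraint propagation.  The outcome classifies the block:
#' `"none"` (no assignment exists -- the signature of a novel haplotype in
#' the database), `"unique"`, or `"multiple"`.
#'
#' @param cs a [build_constraints] result.
#' @param max_solutions abort (capacity error) if more solutions than this
#'   exist; raise for pathological, highly underdetermined systems.
#' @return an object of class `solution_set`: `outcome`, `solutions` (an
#'   m x t integer matrix, rows in lexicographic order), `two_N`, and the
#'   haplotype ids.  An infeasible system returns outcome `"none"`, not an
#'   error.
#' @examples
#' blk <- toy_block()
#' ft <- freq_table("toy", blk$sites$site_id, blk$sites$minor_allele,
#'                  c(3, 1, 2, 3), n_genomes = 2)
#' enumerate_solutions(build_constraints(blk, ft))  # unique: n = (2, 1, 1)
#' @export
enumerate_solutions <- function(cs, max_solutions = 1e5) {
  out <- enumerate_counts(cs$B, cs$c, cs$two_N, slack_set = 0L,
                          max_solutions = max_solutions)
  m <- nrow(out$n)
  sols <- out$n
  colnames(sols) <- rownames(cs$block$patterns)
  structure(list(
    outcome = if (m == 0L) "none" else if (m == 1L) "unique" else "multiple",
    solutions = sols,
    two_N = cs$two_N,
    haplotype_ids = rownames(cs$block$patterns)),
    class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat("Solution set: outcome =", x$outcome,
      "(", nrow(x$solutions), "solutions, 2N =", x$two_N, ")\n")
  if (nrow(x$solutions) > 0L)
    print(utils::head(x$solutions, 10L))
  if (nrow(x$solutions) > 10L) cat("  ...\n")
  invisible(x)
}

#' Likelihood of the published table given target presence / absence
#'
#' With multiple feasible count assignments, the probability of observing the
#' frequency table given that target haplotype A is in the database is the
#' sum, over the solutions in which A has count `n_k > 0`, of the binomial
#' probability of drawing `n_k` copies in 2N trials at the solution's own
#' frequency `f_k(A) = n_k / 2N`; given absence it is the sum over A-free
#' solutions of `(1 - f_k(A))^(2N)`, each term equal to 1 since `f_k(A) = 0`
#' there.  These are the expressions as printed ("literal" mode); they do not
#' share a normaliser across solutions.  `freq_mode = "population"`
#' substitutes the public population frequency `f(A)` for `f_k(A)` in both.
#' With a unique solution the shortcut semantics apply: the likelihood pair
#' is (1, 0) if the solution contains A and (0, 1) otherwise.
#'
#' @param ss a [solution_set] with outcome `"unique"` or `"multiple"`.
#' @param target_index column index (or haplotype id) of the target.
#' @param freq_mode `"solution"` (default; `f_k(A) = n_k/2N` as printed) or
#'   `"population"` (use `f_pop`).
#' @param f_pop public population frequency of the target (required for
#'   `freq_mode = "population"`).
#' @return a nonnegative number (not normalised across the two hypotheses).
#' @export
likelihood_present <- function(ss, target_index, freq_mode = c("solution",
                               "population"), f_pop = NULL) {
  freq_mode <- match.arg(freq_mode)
  i <- resolve_target(ss, target_index)
  if (ss$outcome == "none")
    stop("no solutions: route to novel-haplotype reconstruction")
  nk <- ss$solutions[, i]
  if (ss$outcome == "unique") return(if (nk[1L] > 0L) 1 else 0)
  pos <- nk > 0L
  if (!any(pos)) return(0)
  fk <- if (freq_mode == "solution") nk[pos] / ss$two_N else {
    if (is.null(f_pop)) stop("f_pop required in population mode")
    rep(f_pop, sum(pos))
  }
  sum(stats::dbinom(nk[pos], ss$two_N, fk))
}

#' @rdname likelihood_present
#' @export
likelihood_absent <- function(ss, target_index, freq_mode = c("solution",
                              "population"), f_pop = NULL) {
  freq_mode <- match.arg(freq_mode)
  i <- resolve_target(ss, target_index)
  if (ss$outcome == "none")
    stop("no solutions: route to novel-haplotype reconstruction")
  nk <- ss$solutions[, i]
  if (ss$outcome == "unique") return(if (nk[1L] == 0L) 1 else 0)
  zero <- nk == 0L
  if (!any(zero)) return(0)
  fk <- if (freq_mode == "solution") 0 else {
    if (is.null(f_pop)) stop("f_pop required in population mode")
    f_pop
  }
  sum((1 - fk)^ss$two_N * rep(1, sum(zero)))
}

resolve_target <- function(ss, target) {
  if (is.character(target)) {
    i <- match(target, ss$haplotype_ids)
    if (is.na(i)) stop("unknown target haplotype '", target, "'")
    i
  } else as.integer(target)
}

#' Known-haplotype membership test on a frequency table (KHF)
#'
#' Tests H0 "the target haplotype is not in the database" against H1 "it is",
#' given the published per-site minor-allele counts.  The prior of presence is
#' `1 - (1 - f(A))^(2N)`; the likelihoods come from the enumerated solution
#' set ([likelihood_present], [likelihood_absent]); the posterior follows by
#' Bayes' rule and the test statistic is the posterior-odds ratio
#' `Lambda = P(A not in DB | Q) / P(A in DB | Q)` -- small values favour
#' presence.  The p-value is the left-tail rank of Lambda in an empirical
#' null distribution of truly-absent haplotypes.
#'
#' @param block a [haploblock]; the target must be one of its haplotypes.
#' @param ft a [freq_table].
#' @param target haplotype id (or index) of the target.
#' @param null_dist a [null_dist], or `NULL` to skip the p-value.
#' @param alpha significance level for the reported decision.
#' @param mode `"literal"` uses the likelihoods exactly as defined;
#'   `"normalized"` rescales the pair to sum to one before Bayes (identical
#'   posterior, recorded for comparison).
#' @param freq_mode passed to the likelihood functions.
#' @param max_solutions cap for [enumerate_solutions].
#' @param solutions optionally a precomputed [solution_set] for this block
#'   and table (enumeration is the expensive step; reuse it across targets).
#' @return an object of class `haplo_inference` with the prior, likelihoods,
#'   posterior, `lambda`, `p_value`, and `decision` (`p < alpha`).  When the
#'   solution set is empty the outcome `"none"` is returned with everything
#'   else `NA`: the table signals a novel haplotype and should be routed to
#'   [reconstruct_novel].
#' @examples
#' blk <- toy_block()
#' db <- genome_db(2, blk$patterns, c(2, 1, 1))
#' ft <- summarize_database(db, blk)
#' khf_test(blk, ft, "x1")   # unique solution containing x1: posterior 1
#' @export
khf_test <- function(block, ft, target, null_dist = NULL, alpha = 0.05,
                     mode = c("literal", "normalized"),
                     freq_mode = c("solution", "population"),
                     max_solutions = 1e5, solutions = NULL) {
  mode <- match.arg(mode)
  freq_mode <- match.arg(freq_mode)
  i <- if (is.character(target)) match(target, rownames(block$patterns))
       else as.integer(target)
  if (is.na(i) || i < 1L || i > n_haplotypes(block))
    stop("target must be one of the block's known haplotypes")
  ss <- if (is.null(solutions))
    enumerate_solutions(build_constraints(block, ft), max_solutions)
  else solutions
  tid <- rownames(block$patterns)[i]
  if (ss$outcome == "none")
    return(new_inference(target = tid, block_id = block$block_id,
                         engine = "khf", outcome = "none", mode = mode,
                         prior = prior_presence(block$frequencies[i],
                                                ft$n_genomes),
                         alpha = alpha))
  f_pop <- block$frequencies[i]
  prior <- prior_presence(f_pop, ft$n_genomes)
  lin <- likelihood_present(ss, i, freq_mode, f_pop = f_pop)
  lout <- likelihood_absent(ss, i, freq_mode, f_pop = f_pop)
  if (mode == "normalized" && (lin + lout) > 0) {
    s <- lin + lout
    lin <- lin / s; lout <- lout / s
  }
  finish_inference(tid, block$block_id, "khf", ss$outcome, mode,
                   prior, lin, lout, null_dist, alpha)
}

# shared Bayes + Lambda + p-value wrap-up for all engines
finish_inference <- function(target, block_id, engine, outcome, mode,
                             prior, lik_in, lik_out, null_dist, alpha,
                             smoothed = FALSE) {
  num <- lik_in * prior
  den <- num + lik_out * (1 - prior)
  posterior <- if (den > 0) num / den else NA_real_
  lambda <- if (is.na(posterior)) NA_real_
            else if (posterior == 0) Inf
            else (1 - posterior) / posterior
  p <- if (is.null(null_dist) || is.na(lambda)) NA_real_
       else if (is.infinite(lambda)) 1.0
       else p_value(lambda, null_dist)
  new_inference(target = target, block_id = block_id, engine = engine,
                outcome = outcome, mode = mode, prior = prior,
                lik_in = lik_in, lik_out = lik_out, posterior = posterior,
                lambda = lambda, p_value = p, alpha = alpha,
                smoothed = smoothed)
}

new_inference <- function(target, block_id, engine, outcome, mode, prior,
                          lik_in = NA_real_, lik_out = NA_real_,
                          posterior = NA_real_, lambda = NA_real_,
                          p_value = NA_real_, alpha = 0.05,
                          smoothed = FALSE) {
  structure(list(target = target, block_id = block_id, engine = engine,
                 outcome = outcome, mode = mode, prior = prior,
                 lik_in = lik_in, lik_out = lik_out, posterior = posterior,
                 lambda = lambda, p_value = p_value, alpha = alpha,
                 decision = isTRUE(p_value < alpha), smoothed = smoothed),
            class = "haplo_inference")
}

#' @export
print.haplo_inference <- function(x, ...) {
  cat("Haplotype membership inference (", toupper(x$engine), ")\n", sep = "")
  cat("  target:   ", x$target, "  [block ", x$block_id, "]\n", sep = "")
  if (identical(x$outcome, "none")) {
    cat("  outcome:   no feasible known-haplotype composition",
        "(novel haplotype signal)\n")
    return(invisible(x))
  }
  cat(sprintf("  prior P(A in DB)      = %.6g\n", x$prior))
  cat(sprintf("  posterior P(A in DB|Q)= %.6g\n", x$posterior))
  cat(sprintf("  Lambda                = %.6g%s\n", x$lambda,
              if (x$smoothed) "  (smoothed MC estimate)" else ""))
  if (!is.na(x$p_value))
    cat(sprintf("  p-value               = %.4g  -> %s at alpha = %g\n",
                x$p_value,
                if (x$decision) "declared PRESENT" else "not declared",
                x$alpha))
  invisible(x)
}

#' @export
as.data.frame.haplo_inference <- function(x, ...) {
  data.frame(target = x$target, block_id = x$block_id, engine = x$engine,
             outcome = x$outcome, mode = x$mode, prior = x$prior,
             lik_in = x$lik_in, lik_out = x$lik_out,
             posterior = x$posterior, lambda = x$lambda,
             p_value = x$p_value, decision = x$decision,
             smoothed = x$smoothed)
}
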