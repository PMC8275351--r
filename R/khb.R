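#' Logical constraints implied by a Beacon table
#'
#' A Beacon answer at site j constrains the haplotype panel: if the minor
#' allele is *absent*, every haplotype carrying it has database count 0
#' (`must_absent`); if it is *present*, at least one of its carriers has
#' count >= 1 -- and if, after removing must_absent haplotypes, only one
#' carrier survives, that haplotype is `must_present`.  The two rules are
#' applied to a fixed point, which is order-independent.  Sites whose carrier
#' set repeats an earlier site's add no constraint and are dropped from the
#' recorded disjunctions.
#'
#' @param block a [haploblock].
#' @param bt a [beacon_table] over the same sites in the same order.
#' @return an object of class `logical_constraints`: `status` (character
#'   vector per haplotype: `"must_present"`, `"must_absent"`,
#'   `"unconstrained"`), `disjunctions` (list of surviving carrier index sets
#'   of present sites), and the site classifications.
#' @examples
#' blk <- toy_block()
#' bt <- beacon_table("toy", blk$sites$site_id, blk$sites$minor_allele,
#'                    c(TRUE, TRUE, FALSE, TRUE), n_genomes = 2)
#' derive_logical_constraints(blk, bt)$status  # x1 absent; x2, x3 present
#' @export
derive_logical_constraints <- function(block, bt) {
  if (!identical(as.character(bt$site_id), as.character(block$sites$site_id)))
    stop("beacon-table sites do not match block sites")
  B <- t(block$patterns)                   # L x t
  t_n <- ncol(B)
  status <- rep("unconstrained", t_n)
  # absence rule: one pass suffices (counts can only be forced to zero once)
  for (j in which(!bt$present))
    status[B[j, ] == 1L] <- "must_absent"
  # presence rule to fixed point: removing must_absent carriers can shrink a
  # carrier set to a single survivor, which in turn cannot shrink others,
  # but we iterate anyway to make order-independence explicit
  present_sites <- which(bt$present)
  repeat {
    changed <- FALSE
    for (j in present_sites) {
      carriers <- which(B[j, ] == 1L)
      live <- carriers[status[carriers] != "must_absent"]
      if (!length(live))
        stop(structure(class = c("haplomember_inconsistency_error", "error",
                                 "condition"),
             list(message = paste0(
               "site ", block$sites$site_id[j], " answers 'present' but all ",
               "carrier haplotypes are excluded: novel haplotype in the ",
               "database or corrupted table"), call = NULL)))
      if (length(live) == 1L && status[live] != "must_present") {
        status[live] <- "must_present"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # record one disjunction per distinct surviving carrier set
  disj <- list(); seen <- character()
  for (j in present_sites) {
    carriers <- which(B[j, ] == 1L)
    live <- carriers[status[carriers] != "must_absent"]
    key <- paste(live, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      disj[[length(disj) + 1L]] <- live
    }
  }
  names(status) <- rownames(block$patterns)
  structure(list(status = status, disjunctions = disj,
                 present_sites = present_sites,
                 absent_sites = which(!bt$present)),
            class = "logical_constraints")
}

#' @export
print.logical_constraints <- function(x, ...) {
  cat("Logical Beacon constraints:\n")
  for (s in c("must_present", "must_absent")) {
    ids <- names(x$status)[x$status == s]
    if (length(ids)) cat(" ", s, ":", paste(ids, collapse = ", "), "\n")
  }
  cat("  unconstrained:", sum(x$status == "unconstrained"), "haplotypes;",
      length(x$disjunctions), "presence disjunction(s)\n")
  invisible(x)
}

#' Multinomial count events
#'
#' An event is a conjunction of per-haplotype count predicates (lower/upper
#' bounds on each `n_i`) optionally conjoined with Beacon-consistency: every
#' present site has at least one carrier with count >= 1 and every absent
#' site has all carriers at 0.
#'
#' @param t_n number of haplotypes.
#' @param lo,hi integer bound vectors (recycled); defaults are the vacuous
#'   bounds `0` and `Inf`.
#' @param beacon optionally a [beacon_table] whose answers must be consistent.
#' @return a list of class `mn_event`.
#' @export
mn_event <- function(t_n, lo = 0L, hi = Inf, beacon = NULL) {
  structure(list(lo = rep_len(lo, t_n), hi = rep_len(hi, t_n),
                 beacon = beacon),
            class = "mn_event")
}

#' Monte-Carlo estimate of a multinomial event probability
#'
#' Approximates the probability, under a multinomial draw of 2N haplotypes
#' from the block's public frequencies, that the database counts satisfy the
#' event.  This replaces exact multinomial CDF computation, which is
#' intractable for realistic t and N; 5000 draws per estimate is the default
#' sample size.
#'
#' @param block a [haploblock] (supplies t and the frequencies).
#' @param event an [mn_event].
#' @param N database genome count; the draw has size 2N.
#' @param n_samples Monte-Carlo sample size (>= 1).
#' @param seed integer seed for reproducibility (local RNG stream; the
#'   caller's RNG state is untouched).
#' @return a list of class `mn_estimate` with `estimate`, `n_satisfied`,
#'   `n_samples`, `seed`.
#' @export
estimate_event_probability <- function(block, event, N, n_samples = 5000,
                                       seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  f <- block$frequencies
  if (any(f < 0)) stop("degenerate frequency vector")
  draws <- with_local_seed(seed, stats::rmultinom(n_samples, 2L * N, f))
  ok <- event_satisfied(draws, event, block)
  structure(list(estimate = mean(ok), n_satisfied = sum(ok),
                 n_samples = as.integer(n_samples), seed = seed),
            class = "mn_estimate")
}

# vectorised predicate evaluation over a t x n_samples draw matrix
event_satisfied <- function(draws, event, block) {
  ok <- colSums(draws < event$lo | draws > event$hi) == 0L
  if (!is.null(event$beacon)) {
    M <- t(block$patterns) %*% draws        # L x n_samples site counts
    pres <- event$beacon$present
    if (any(pres))
      ok <- ok & colSums(M[pres, , drop = FALSE] < 1L) == 0L
    if (any(!pres))
      ok <- ok & colSums(M[!pres, , drop = FALSE] > 0L) == 0L
  }
  ok
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Known-haplotype membership test on a Beacon table (KHB)
#'
#' First applies the logical deductions of [derive_logical_constraints]: a
#' `must_present` target gets posterior 1 (Lambda = 0) and a `must_absent`
#' target posterior 0 (Lambda = +Inf) outright.  Otherwise the likelihoods
#' are Monte-Carlo multinomial estimates.  In the default `"conditional"`
#' mode they are `P(beacon-consistent | n_A >= 1)` and
#' `P(beacon-consistent | n_A = 0)`; `"literal"` mode uses the joint events
#' `P(consistent & n_A >= 1)` and `P(consistent & n_A = 0)`, the direct
#' generalisation of the worked three-haplotype CDF expressions.  Bayes,
#' Lambda and the empirical-null p-value then follow exactly as in
#' [khf_test].  Zero-sample events are add-one smoothed ((k+1)/(n+2)) and
#' flagged in the result.
#'
#' @inheritParams khf_test
#' @param bt a [beacon_table].
#' @param n_samples Monte-Carlo draws per event (default 5000).
#' @param seed root seed for the test; the four event estimates use
#'   deterministically derived sub-seeds.
#' @param mode `"conditional"` (default) or `"literal"`.
#' @param constraints optionally precomputed [derive_logical_constraints].
#' @return a `haplo_inference` object (see [khf_test]).
#' @examples
#' blk <- toy_block()
#' bt <- beacon_table("toy", blk$sites$site_id, blk$sites$minor_allele,
#'                    c(TRUE, TRUE, FALSE, TRUE), n_genomes = 2)
#' khb_test(blk, bt, "x3", seed = 1)  # deduced present: posterior 1
#' @export
khb_test <- function(block, bt, target, null_dist = NULL, alpha = 0.05,
                     n_samples = 5000, seed = NULL,
                     mode = c("conditional", "literal"),
                     constraints = NULL) {
  mode <- match.arg(mode)
  i <- if (is.character(target)) match(target, rownames(block$patterns))
       else as.integer(target)
  if (is.na(i) || i < 1L || i > n_haplotypes(block))
    stop("target must be one of the block's known haplotypes")
  lc <- if (is.null(constraints)) derive_logical_constraints(block, bt)
        else constraints
  tid <- rownames(block$patterns)[i]
  f_pop <- block$frequencies[i]
  prior <- prior_presence(f_pop, bt$n_genomes)
  st <- lc$status[i]
  if (st == "must_present")
    return(finish_inference(tid, block$block_id, "khb", "deduced", mode,
                            prior, 1, 0, null_dist, alpha))
  if (st == "must_absent")
    return(finish_inference(tid, block$block_id, "khb", "deduced", mode,
                            prior, 0, 1, null_dist, alpha))
  t_n <- n_haplotypes(block)
  N <- bt$n_genomes
  seeds <- if (is.null(seed)) vector("list", 4L) else as.list(seed + 0:3)
  e_in  <- estimate_event_probability(block,
             mn_event(t_n, lo = ifelse(seq_len(t_n) == i, 1L, 0L),
                      beacon = bt), N, n_samples, seeds[[1L]])
  e_out <- estimate_event_probability(block,
             mn_event(t_n, hi = ifelse(seq_len(t_n) == i, 0L, Inf),
                      beacon = bt), N, n_samples, seeds[[2L]])
  smoothed <- FALSE
  if (mode == "literal") {
    lin <- e_in$estimate; lout <- e_out$estimate
    if (e_in$n_satisfied == 0L) {
      lin <- (e_in$n_satisfied + 1) / (e_in$n_samples + 2); smoothed <- TRUE
    }
    if (e_out$n_satisfied == 0L) {
      lout <- (e_out$n_satisfied + 1) / (e_out$n_samples + 2); smoothed <- TRUE
    }
  } else {
    m_in  <- estimate_event_probability(block,
               mn_event(t_n, lo = ifelse(seq_len(t_n) == i, 1L, 0L)),
               N, n_samples, seeds[[3L]])
    m_out <- estimate_event_probability(block,
               mn_event(t_n, hi = ifelse(seq_len(t_n) == i, 0L, Inf)),
               N, n_samples, seeds[[4L]])
    cond <- function(joint, marg) {
      # P(consistent | condition) from two estimates on a shared sample size;
      # smooth empty or degenerate cells and flag
      k <- joint$n_satisfied
      n <- round(marg$estimate * marg$n_samples)
      if (n == 0L || k == 0L || k >= n) {
        smoothed <<- TRUE
        (min(k, n) + 1) / (n + 2)
      } else k / n
    }
    lin <- cond(e_in, m_in)
    lout <- cond(e_out, m_out)
  }
  finish_inference(tid, block$block_id, "khb", "estimated", mode,
                   prior, lin, lout, null_dist, alpha, smoothed = smoothed)
}
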