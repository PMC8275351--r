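#' Empirical null distribution of the test statistic
#'
#' The distribution of Lambda is unknown analytically, so the null is built
#' empirically: compute Lambda for haplotypes known (or verifiable) to be
#' absent from the database and pool the values.  P-values are left-tail
#' ranks, since small Lambda favours presence.
#'
#' @param values numeric Lambda values (finite or `+Inf` sentinels).
#' @param engine which engine produced them (`"khf"`, `"khb"`, ...).
#' @param provenance free-text provenance (blocks/seeds).
#' @return a sorted numeric vector of class `null_dist`.
#' @export
null_dist <- function(values, engine = "khf", provenance = "") {
  values <- as.numeric(values)
  if (!length(values)) stop("empty null distribution")
  if (any(is.na(values))) stop("NA in null statistics")
  structure(sort(values), class = "null_dist", engine = engine,
            provenance = provenance)
}

#' @export
print.null_dist <- function(x, ...) {
  cat("Empirical null distribution (", attr(x, "engine"), "): M = ",
      length(x), " statistics, ", sum(is.infinite(x)),
      " at +Inf\n", sep = "")
  fin <- x[is.finite(x)]
  if (length(fin))
    cat("  finite quantiles:",
        paste(format(stats::quantile(fin, c(.05, .5, .95)), digits = 3),
              collapse = " / "), "(5% / 50% / 95%)\n")
  invisible(x)
}

#' Build an empirical null from absent targets
#'
#' Runs the chosen inference engine on haplotypes that are truly absent from
#' the summarised databases and pools the resulting Lambda statistics across
#' blocks (the faithful, pooled mode).  `stratify = TRUE` instead returns a
#' list of per-stratum nulls keyed by the block dimensions `t:L`, for
#' comparing pooled against size-matched calibration.
#'
#' @param blocks list of [haploblock]s.
#' @param tables list of matching [freq_table]s (engine `"khf"`) or
#'   [beacon_table]s (engine `"khb"`).
#' @param absent_targets list (one per block) of character vectors of target
#'   haplotype ids verifiably absent from that block's database.
#' @param engine `"khf"` or `"khb"`.
#' @param stratify return per-(t, L) nulls instead of one pooled null.
#' @param ... passed to [khf_test] / [khb_test] (e.g. `seed`, `n_samples`,
#'   `mode`).
#' @return a [null_dist], or a named list of them when `stratify = TRUE`.
#' @export
build_null <- function(blocks, tables, absent_targets,
                       engine = c("khf", "khb"), stratify = FALSE, ...) {
  engine <- match.arg(engine)
  if (!length(unlist(absent_targets))) stop("empty absent-target list")
  lam <- numeric(0); strata <- character(0)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]; tab <- tables[[b]]
    tg <- absent_targets[[b]]
    if (!length(tg)) next
    shared <- if (engine == "khf")
      enumerate_solutions(build_constraints(blk, tab))
    else derive_logical_constraints(blk, tab)
    for (id in tg) {
      res <- if (engine == "khf")
        khf_test(blk, tab, id, solutions = shared, ...)
      else khb_test(blk, tab, id, constraints = shared, ...)
      if (identical(res$outcome, "none") || is.na(res$lambda)) next
      lam <- c(lam, res$lambda)
      strata <- c(strata, paste0(n_haplotypes(blk), ":", n_sites(blk)))
    }
  }
  if (!length(lam)) stop("no usable null statistics")
  if (!stratify)
    return(null_dist(lam, engine = engine,
                     provenance = paste(length(blocks), "blocks")))
  lapply(split(lam, strata), null_dist, engine = engine,
         provenance = "stratified by t:L")
}

#' Empirical p-value of an observed statistic
#'
#' The add-one empirical left-tail estimator
#' `(1 + #\{Lambda_null <= lambda_obs\}) / (M + 1)`: small Lambda is evidence
#' of presence, so the rejection region is the left tail, and the add-one
#' form never returns 0.  `lambda_obs = +Inf` gives exactly 1.
#'
#' @param lambda_obs observed statistic.
#' @param null a [null_dist].
#' @return p-value in `(0, 1]`.
#' @examples
#' nd <- null_dist(1:9)
#' p_value(0, nd)    # 0.1
#' p_value(Inf, nd)  # 1
#' @export
p_value <- function(lambda_obs, null) {
  if (!length(null)) stop("empty null distribution")
  (1 + sum(null <= lambda_obs)) / (length(null) + 1)
}

#' Per-block statistical power of an inference run
#'
#' For result sets whose targets are all truly present, power is the fraction
#' of targets detected with p-value below `alpha`, reported per block and in
#' aggregate.
#'
#' @param results list of `haplo_inference` objects (or a data.frame from
#'   `as.data.frame`-ing them) for truly-present targets.
#' @param alpha significance level.
#' @return data.frame with columns `block_id`, `n`, `power`; the aggregate
#'   fraction is attached as attribute `"aggregate"`.  Empty groups are
#'   dropped with a warning.
#' @export
power_by_block <- function(results, alpha = 0.05) {
  df <- if (is.data.frame(results)) results
        else do.call(rbind, lapply(results, as.data.frame))
  df <- df[!is.na(df$p_value), , drop = FALSE]
  if (!nrow(df)) {
    warning("no completed tests with p-values; empty power report")
    return(structure(data.frame(block_id = character(), n = integer(),
                                power = numeric()), aggregate = NA_real_))
  }
  agg <- tapply(df$p_value < alpha, df$block_id, mean)
  n <- tapply(df$p_value, df$block_id, length)
  out <- data.frame(block_id = names(agg), n = as.integer(n),
                    power = as.numeric(agg), row.names = NULL)
  attr(out, "aggregate") <- mean(df$p_value < alpha)
  out
}

#' Log power ratio between two methods
#'
#' Per-block `log(power_a / power_b)` with powers floored at `eps` so that a
#' method detecting everything against one detecting nothing yields a large
#' finite ratio rather than infinity.
#'
#' @param power_a,power_b data.frames from [power_by_block] over the same
#'   blocks.
#' @param eps floor applied to both powers.
#' @return data.frame `block_id`, `power_a`, `power_b`, `log_ratio`, sorted
#'   by the ratio.
#' @export
log_power_ratio <- function(power_a, power_b, eps = 1e-6) {
  m <- merge(power_a, power_b, by = "block_id", suffixes = c("_a", "_b"))
  m$log_ratio <- log(pmax(m$power_a, eps) / pmax(m$power_b, eps))
  m[order(m$log_ratio), c("block_id", "power_a", "power_b", "log_ratio")]
}

#' False-positive-rate experiment
#'
#' Runs the chosen engine on truly-absent targets (selected with prior
#' presence probability below `prior_ceiling`) and reports the fraction
#' declared present at level `alpha`.
#'
#' @param blocks,tables,absent_targets as in [build_null]; the targets here
#'   are the *test* set, scored against `null`.
#' @param null a [null_dist] built from an independent absent cohort.
#' @param engine `"khf"` or `"khb"`.
#' @param alpha significance level.
#' @param prior_ceiling targets with prior presence above this are skipped
#'   (rare-target selection).
#' @param ... passed to the engine.
#' @return the false-positive fraction, with attributes `n` (targets tested)
#'   and `p_values`.
#' @export
fpr_experiment <- function(blocks, tables, absent_targets, null,
                           engine = c("khf", "khb"), alpha = 0.05,
                           prior_ceiling = 0.1, ...) {
  engine <- match.arg(engine)
  dec <- logical(0); pv <- numeric(0)
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]; tab <- tables[[b]]
    tg <- absent_targets[[b]]
    if (!length(tg)) next
    N <- tab$n_genomes
    shared <- if (engine == "khf")
      enumerate_solutions(build_constraints(blk, tab))
    else derive_logical_constraints(blk, tab)
    for (id in tg) {
      i <- match(id, rownames(blk$patterns))
      if (prior_presence(blk$frequencies[i], N) >= prior_ceiling) next
      res <- if (engine == "khf")
        khf_test(blk, tab, id, null_dist = null, alpha = alpha,
                 solutions = shared, ...)
      else khb_test(blk, tab, id, null_dist = null, alpha = alpha,
                    constraints = shared, ...)
      if (identical(res$outcome, "none") || is.na(res$p_value)) next
      dec <- c(dec, res$decision); pv <- c(pv, res$p_value)
    }
  }
  structure(if (length(dec)) mean(dec) else NA_real_,
            n = length(dec), p_values = pv)
}
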