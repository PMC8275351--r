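#' Simulate an empirical null distribution
#'
#' Generates synthetic haploblocks and databases and computes the inference
#' statistic for haplotypes that are truly absent from each database (count
#' 0 in the ground truth), pooling values across blocks until `M` statistics
#' are collected.  This is the synthetic analogue of building a null cohort
#' from genomes known not to be in the database.
#'
#' @param cfg a [sim_config] describing the null cohort's blocks.
#' @param engine `"khf"`, `"khb"`, `"snv"` or `"beacon"` (the last two are
#'   the SNV-based baselines, so that their p-values use like-for-like
#'   machinery).
#' @param M number of null statistics to collect.
#' @param seed root seed.
#' @param max_per_block at most this many absent targets per block.
#' @param prior_ceiling null targets use the same rare-target selection rule
#'   as test targets (prior presence below this), so null and test
#'   statistics are exchangeable; defaults to the config's ceiling.
#' @param n_samples,mode passed to [khb_test] when `engine = "khb"`.
#' @return a [null_dist] of size >= M (truncated to M).
#' @export
simulate_null <- function(cfg, engine = c("khf", "khb", "snv", "beacon"),
                          M = 300L, seed = 1L, max_per_block = 10L,
                          prior_ceiling = cfg$prior_ceiling,
                          n_samples = 5000L, mode = "conditional") {
  engine <- match.arg(engine)
  lam <- numeric(0)
  b <- 0L
  while (length(lam) < M) {
    b <- b + 1L
    if (b > 100L * max(1L, ceiling(M / max_per_block)))
      stop("null simulation failed to accumulate ", M, " statistics")
    blk <- generate_block(cfg, sprintf("NULL%04d", b), seed = seed + b)
    db <- sample_database(blk, cfg$N, seed = seed + 20000L + b)
    pri <- prior_presence(blk$frequencies, cfg$N)
    absent <- rownames(blk$patterns)[db$counts == 0L & pri < prior_ceiling]
    absent <- utils::head(
      absent[order(blk$frequencies[match(absent, rownames(blk$patterns))])],
      max_per_block)
    if (!length(absent)) next
    if (engine %in% c("khf", "snv"))
      tab <- summarize_database(db, blk, "frequency")
    else
      tab <- summarize_database(db, blk, "beacon")
    if (engine == "khf") {
      ss <- tryCatch(enumerate_solutions(build_constraints(blk, tab)),
                     haplomember_capacity_error = function(e) NULL)
      if (is.null(ss) || ss$outcome == "none") next
      for (id in absent) {
        r <- khf_test(blk, tab, id, solutions = ss)
        if (!is.na(r$lambda)) lam <- c(lam, r$lambda)
      }
    } else if (engine == "khb") {
      lc <- derive_logical_constraints(blk, tab)
      for (id in absent) {
        r <- khb_test(blk, tab, id, n_samples = n_samples, mode = mode,
                      seed = seed + 40000L + 31L * length(lam),
                      constraints = lc)
        if (!is.na(r$lambda)) lam <- c(lam, r$lambda)
      }
    } else {
      for (id in absent) {
        i <- match(id, rownames(blk$patterns))
        stat <- if (engine == "snv")
          snv_lrt(blk$patterns[i, ], tab, blk$sites$public_maf)
        else
          beacon_optimal_baseline(blk$patterns[i, ], tab,
                                  blk$sites$public_maf, tab$n_genomes)
        lam <- c(lam, as.numeric(stat))
      }
    }
  }
  null_dist(lam[seq_len(M)], engine = engine,
            provenance = paste0("simulated, seed ", seed))
}

#' Leave-one-out novel-haplotype reconstruction experiment
#'
#' The synthetic analogue of holding a haplotype out of the public panel:
#' for each simulated block, a private database is drawn with the rarest
#' known haplotype's count set to `novel_count`; that haplotype is then
#' dropped from the public panel (so it is novel to the attacker) while the
#' database keeps its carriers.  NHF reconstruction with d = 1 is run on the
#' published frequency table, the reconstruction is validated by KHF against
#' an empirical null, and exactness against the held-out ground truth is
#' recorded.
#'
#' @param cfg a [sim_config]; `cfg$n_blocks` experiment blocks are run.
#' @param novel_count planted database count of the held-out haplotype.
#' @param alpha validation significance level.
#' @param null either a [null_dist] or an integer M to simulate one of that
#'   size from matching blocks.
#' @param seed root seed.
#' @return data.frame with one row per block: reconstruction feasibility,
#'   exact pattern match, recovered count, validation p-value and decision.
#'   The percentage of exact matches among validated reconstructions is
#'   attached as attribute `"pct_exact_validated"`.
#' @export
experiment_leave_one_out <- function(cfg, novel_count = 10L, alpha = 0.05,
                                     null = 300L, seed = cfg$seed) {
  if (!inherits(null, "null_dist"))
    null <- simulate_null(cfg, "khf", M = as.integer(null),
                          seed = seed + 500000L)
  rows <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    blk <- generate_block(cfg, sprintf("LOO%03d", b), seed = seed + b)
    rare_id <- rownames(blk$patterns)[which.min(blk$frequencies)]
    db <- sample_database(blk, cfg$N, seed = seed + 10000L + b)
    db <- set_haplotype_count(db, rare_id, novel_count)
    held <- drop_haplotype(blk, rare_id)
    ft <- summarize_database(db, blk, "frequency")
    sol <- reconstruct_novel(held$block, ft, d_max = 1L)
    feasible <- isTRUE(sol$feasible)
    exact <- feasible && all(sol$z[1L, ] == held$pattern)
    p <- NA_real_; decided <- NA
    if (feasible) {
      val <- validate_novel(held$block, ft, sol, null_dist = null,
                            alpha = alpha)
      p <- val$results[[1L]]$p_value
      decided <- isTRUE(val$results[[1L]]$decision)
    }
    rows[[b]] <- data.frame(block_id = blk$block_id, held_out = rare_id,
                            feasible = feasible, exact = exact,
                            recovered_count =
                              if (feasible) sol$counts[1L] else NA_integer_,
                            p_value = p, validated = decided)
  }
  out <- do.call(rbind, rows)
  v <- out$validated %in% TRUE
  attr(out, "pct_exact_validated") <-
    if (any(v)) 100 * mean(out$exact[v]) else NA_real_
  attr(out, "n_validated") <- sum(v)
  out
}

#' Known-haplotype frequency-table power experiment
#'
#' Plants rare target haplotypes (prior presence < `prior_ceiling`) into
#' simulated databases, publishes the frequency tables, and runs the KHF
#' test against an empirical null.  Reports, among targets whose solution
#' enumeration completes, the fraction detected at `alpha`.
#'
#' @param cfg a [sim_config].
#' @param alpha significance level.
#' @param null a [null_dist] or an integer M to simulate.
#' @param max_targets targets per block.
#' @param seed root seed.
#' @return data.frame (one row per target) with attributes
#'   `"pct_significant"` (percentage of completed tests with p < alpha) and
#'   `"n_completed"`.
#' @export
experiment_khf_power <- function(cfg, alpha = 0.05, null = 300L,
                                 max_targets = 3L, seed = cfg$seed) {
  if (!inherits(null, "null_dist"))
    null <- simulate_null(cfg, "khf", M = as.integer(null),
                          seed = seed + 600000L)
  rows <- list()
  for (b in seq_len(cfg$n_blocks)) {
    blk <- generate_block(cfg, sprintf("PWR%03d", b), seed = seed + b)
    targets <- rare_targets(blk, cfg$N, cfg$prior_ceiling, max_targets)
    if (!length(targets)) next
    db <- sample_database(blk, cfg$N, forced_in = targets,
                          seed = seed + 10000L + b)
    ft <- summarize_database(db, blk, "frequency")
    ss <- tryCatch(enumerate_solutions(build_constraints(blk, ft)),
                   haplomember_capacity_error = function(e) NULL)
    for (id in targets) {
      if (is.null(ss)) {
        rows[[length(rows) + 1L]] <-
          data.frame(block_id = blk$block_id, target = id, completed = FALSE,
                     outcome = "capacity", posterior = NA_real_,
                     prior = NA_real_, p_value = NA_real_)
        next
      }
      r <- khf_test(blk, ft, id, null_dist = null, alpha = alpha,
                    solutions = ss)
      rows[[length(rows) + 1L]] <-
        data.frame(block_id = blk$block_id, target = id,
                   completed = r$outcome %in% c("unique", "multiple"),
                   outcome = r$outcome, posterior = r$posterior,
                   prior = r$prior, p_value = r$p_value)
    }
  }
  out <- do.call(rbind, rows)
  comp <- out$completed & !is.na(out$p_value)
  attr(out, "pct_significant") <-
    if (any(comp)) 100 * mean(out$p_value[comp] < alpha) else NA_real_
  attr(out, "n_completed") <- sum(comp)
  out
}

#' Null calibration experiment
#'
#' Draws truly-absent rare targets, scores them with the chosen engine
#' against an independently simulated null of size `M`, and reports the
#' p-value sample, its Kolmogorov-Smirnov distance from U(0,1), and the
#' false-positive rate at `alpha`.  Absent targets are forced out of each
#' database so the truth labels are exact.
#'
#' @param cfg a [sim_config]; for the KS check to be meaningful the
#'   statistic must be atom-free, which the `mutation = "drop"` generator
#'   provides for the KHB engine (no truly-absent target is logically
#'   deducible as absent, so no mass sits at Lambda = +Inf).
#' @param engine inference engine, as in [simulate_null].
#' @param M null-distribution size.
#' @param n_test number of test p-values.
#' @param alpha level for the false-positive rate.
#' @param n_samples Monte-Carlo draws per KHB event.
#' @param seed root seed.
#' @return list with `p_values`, `ks` (statistic and critical values),
#'   `fpr`, `n_test`.
#' @export
experiment_calibration <- function(cfg, engine = "khb", M = 500L,
                                   n_test = 300L, alpha = 0.05,
                                   n_samples = 5000L, seed = cfg$seed) {
  if (!engine %in% c("khf", "khb"))
    stop("calibration supports khf/khb engines")
  # one exchangeable pool of truly-absent rare targets, drawn with a single
  # selection rule, then split at random into the null and the test set --
  # exchangeability is what makes the rank p-values uniform
  lam <- numeric(0)
  need <- M + n_test
  b <- 0L
  while (length(lam) < need) {
    b <- b + 1L
    if (b > 50L * need) stop("calibration failed to accumulate targets")
    blk <- generate_block(cfg, sprintf("CAL%04d", b), seed = seed + b)
    targets <- rare_targets(blk, cfg$N, cfg$prior_ceiling, 3L)
    if (!length(targets)) next
    db <- sample_database(blk, cfg$N, forced_out = targets,
                          seed = seed + 10000L + b)
    tab <- summarize_database(db, blk,
                              if (engine == "khf") "frequency" else "beacon")
    shared <- if (engine == "khf")
      tryCatch(enumerate_solutions(build_constraints(blk, tab)),
               haplomember_capacity_error = function(e) NULL)
    else derive_logical_constraints(blk, tab)
    if (is.null(shared)) next
    for (id in targets) {
      if (length(lam) >= need) break
      r <- if (engine == "khf") {
        if (shared$outcome == "none") next
        khf_test(blk, tab, id, solutions = shared)
      } else
        khb_test(blk, tab, id, n_samples = n_samples,
                 seed = seed + 40000L + 31L * length(lam),
                 constraints = shared)
      if (is.na(r$lambda)) next
      lam <- c(lam, r$lambda)
    }
  }
  idx <- with_local_seed(seed + 900000L, sample.int(need, M))
  null <- null_dist(lam[idx], engine = engine,
                    provenance = "calibration pool split")
  pv <- vapply(lam[-idx], p_value, numeric(1L), null = null)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  list(p_values = pv,
       ks = list(statistic = unname(ks$statistic),
                 critical_1pct = 1.628 / sqrt(length(pv)),
                 p_value = ks$p.value),
       fpr = mean(pv < alpha), n_test = length(pv))
}

#' Power comparison between haplotype and SNV-based inference
#'
#' Plants rare present targets into simulated databases and measures, per
#' block, the power (fraction of targets with p < `alpha`) of the KHF test
#' against the SNV likelihood-ratio baseline on the same frequency tables,
#' and of the KHB test against the per-site Beacon baseline on the same
#' Beacon tables.  Each method's p-values use its own empirical null of size
#' `null_M` built from matching absent-target simulations.  Run once on
#' LD-structured blocks (founder clustering) and once on independent-site
#' blocks to see that the haplotype advantage comes from LD.
#'
#' @param cfg a [sim_config].
#' @param alpha significance level.
#' @param null_M per-method null size.
#' @param max_targets planted targets per block.
#' @param seed root seed.
#' @return list with per-block power data.frames `khf`, `snv`, `khb`,
#'   `beacon`, the merged comparison tables `freq_cmp`, `beacon_cmp`
#'   (including log power ratios) and aggregate powers.
#' @export
experiment_power_comparison <- function(cfg, alpha = 0.05, null_M = 100L,
                                        max_targets = 3L, seed = cfg$seed) {
  nulls <- list(
    khf = simulate_null(cfg, "khf", null_M, seed = seed + 810000L),
    snv = simulate_null(cfg, "snv", null_M, seed = seed + 820000L),
    khb = simulate_null(cfg, "khb", null_M, seed = seed + 830000L,
                        n_samples = 2000L),
    beacon = simulate_null(cfg, "beacon", null_M, seed = seed + 840000L))
  res <- list(khf = list(), snv = list(), khb = list(), beacon = list())
  for (b in seq_len(cfg$n_blocks)) {
    blk <- generate_block(cfg, sprintf("CMP%03d", b), seed = seed + b)
    targets <- rare_targets(blk, cfg$N, cfg$prior_ceiling, max_targets)
    if (!length(targets)) next
    db <- sample_database(blk, cfg$N, forced_in = targets,
                          seed = seed + 10000L + b)
    ft <- summarize_database(db, blk, "frequency")
    bt <- summarize_database(db, blk, "beacon")
    ss <- tryCatch(enumerate_solutions(build_constraints(blk, ft)),
                   haplomember_capacity_error = function(e) NULL)
    lc <- derive_logical_constraints(blk, bt)
    for (id in targets) {
      i <- match(id, rownames(blk$patterns))
      if (!is.null(ss) && ss$outcome != "none")
        res$khf[[length(res$khf) + 1L]] <- as.data.frame(
          khf_test(blk, ft, id, null_dist = nulls$khf, alpha = alpha,
                   solutions = ss))
      res$snv[[length(res$snv) + 1L]] <- as.data.frame(
        baseline_test(blk$patterns[i, ], ft, blk$sites$public_maf,
                      null = nulls$snv, engine = "snv", alpha = alpha,
                      target_id = id))
      res$khb[[length(res$khb) + 1L]] <- as.data.frame(
        khb_test(blk, bt, id, null_dist = nulls$khb, alpha = alpha,
                 n_samples = 2000L, seed = seed + 90000L + 131L * b + i,
                 constraints = lc))
      res$beacon[[length(res$beacon) + 1L]] <- as.data.frame(
        baseline_test(blk$patterns[i, ], bt, blk$sites$public_maf,
                      null = nulls$beacon, engine = "beacon", alpha = alpha,
                      target_id = id))
    }
  }
  pw <- lapply(res, function(r) power_by_block(do.call(rbind, r), alpha))
  freq_cmp <- log_power_ratio(pw$khf, pw$snv)
  beacon_cmp <- log_power_ratio(pw$khb, pw$beacon)
  list(khf = pw$khf, snv = pw$snv, khb = pw$khb, beacon = pw$beacon,
       freq_cmp = freq_cmp, beacon_cmp = beacon_cmp,
       aggregate = vapply(pw, attr, numeric(1L), "aggregate"))
}

#' Run a named end-to-end experiment preset
#'
#' Thin orchestration over the experiment functions: executes the preset,
#' writes its report as TSV and JSON plus a machine-readable provenance
#' record (inputs, seeds, package version) into `out_dir`.
#'
#' @param preset `"leave-one-out"`, `"khf-power"`, `"calibration"` or
#'   `"power-comparison"`.
#' @param cfg a [sim_config].
#' @param out_dir output directory.
#' @param alpha significance level.
#' @param seed root seed.
#' @param ... forwarded to the preset function.
#' @return the preset's return value, invisibly.
#' @export
run_experiment <- function(preset = c("leave-one-out", "khf-power",
                                      "calibration", "power-comparison"),
                           cfg, out_dir = ".", alpha = 0.05,
                           seed = cfg$seed, ...) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(preset,
    "leave-one-out" = experiment_leave_one_out(cfg, alpha = alpha,
                                               seed = seed, ...),
    "khf-power" = experiment_khf_power(cfg, alpha = alpha, seed = seed, ...),
    "calibration" = experiment_calibration(cfg, alpha = alpha, seed = seed,
                                           ...),
    "power-comparison" = experiment_power_comparison(cfg, alpha = alpha,
                                                     seed = seed, ...))
  if (is.data.frame(result))
    utils::write.table(result, file.path(out_dir, paste0(preset, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary_vals <- attributes(result)[setdiff(names(attributes(result)),
                                             c("names", "row.names",
                                               "class"))]
  jsonlite::write_json(
    list(preset = preset, summary = summary_vals,
         result = if (!is.data.frame(result)) result),
    file.path(out_dir, paste0(preset, ".json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  jsonlite::write_json(
    list(preset = preset, config = unclass(cfg), alpha = alpha, seed = seed,
         package_version = as.character(utils::packageVersion("haplomember")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, paste0(preset, ".provenance.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(result)
}
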