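#' SNV-based membership statistic on a frequency table
#'
#' The classical single-variant likelihood-ratio membership statistic,
#' summed over the block's sites at the target haplotype's alleles: each site
#' contributes `log(fhat / fref)` if the target carries the minor allele and
#' `log((1 - fhat) / (1 - fref))` otherwise, where `fhat` is the database
#' frequency and `fref` the public reference frequency.  Sites are assumed
#' independent -- the assumption the haplotype-level methods drop -- so the
#' statistic is site-decomposable by construction.  The sign is flipped so
#' that, as with Lambda, *small* values favour presence, letting the
#' empirical-null machinery ([null_dist], [p_value]) apply unchanged.
#' Database frequencies at 0 or 1 are clamped to `1/(4N)` from the boundary.
#'
#' @param target 0/1 allele vector of the target haplotype over the block's
#'   sites.
#' @param ft a [freq_table].
#' @param public_mafs per-site public reference minor-allele frequencies.
#' @return the statistic (numeric scalar), attribute `per_site` holding the
#'   per-site contributions.
#' @examples
#' blk <- toy_block()
#' ft <- freq_table("toy", blk$sites$site_id, blk$sites$minor_allele,
#'                  round(blk$sites$public_maf * 20), n_genomes = 10)
#' snv_lrt(blk$patterns[1, ], ft, blk$sites$public_maf)  # ~0: no signal
#' @export
snv_lrt <- function(target, ft, public_mafs) {
  target <- as.integer(target)
  if (length(target) != length(ft$counts))
    stop("target allele vector length does not match table")
  N <- ft$n_genomes
  eps <- 1 / (4 * N)
  fhat <- pmin(pmax(ft$counts / (2 * N), eps), 1 - eps)
  fref <- pmin(pmax(public_mafs, eps), 1 - eps)
  per_site <- ifelse(target == 1L, log(fhat / fref),
                     log((1 - fhat) / (1 - fref)))
  structure(-sum(per_site), per_site = -per_site)
}

#' Beacon-table membership statistic (per-site optimal-attack style)
#'
#' A per-site log-likelihood ratio of the observed Beacon answers under
#' "target in the database" versus "target not in": only sites where the
#' target carries the minor allele are informative.  Under absence the
#' probability of a "no" answer is `(1 - f)^(2N)`; under presence the target
#' itself contributes a copy, so a "no" requires an error/mismatch of
#' probability `delta`.  Rare alleles (small `f`) therefore dominate the
#' statistic, the weighting that published optimal Beacon attacks exploit.
#' Orientation matches Lambda: small values favour presence.
#'
#' @param target 0/1 allele vector of the target haplotype.
#' @param bt a [beacon_table].
#' @param public_mafs per-site public reference frequencies.
#' @param N database genome count.
#' @param delta mismatch probability for a "no" answer despite presence.
#' @return the statistic, attribute `per_site` as in [snv_lrt].
#' @export
beacon_optimal_baseline <- function(target, bt, public_mafs, N,
                                    delta = 1e-6) {
  target <- as.integer(target)
  if (length(target) != length(bt$present))
    stop("target allele vector length does not match table")
  eps <- 1 / (4 * N)
  f <- pmin(pmax(public_mafs, eps), 1 - eps)
  p_no_out <- (1 - f)^(2 * N)            # absent-target "no" probability
  p_no_in <- delta * (1 - f)^(2 * N - 1) # needs every other copy to miss too
  per_site <- ifelse(target == 1L,
                     ifelse(bt$present,
                            log((1 - p_no_in) / (1 - p_no_out)),
                            log(p_no_in / p_no_out)),
                     0)
  structure(-sum(per_site), per_site = -per_site)
}

#' Baseline membership test with empirical-null p-value
#'
#' Wraps either baseline statistic in the same empirical-null machinery used
#' for the haplotype tests, so power comparisons are like-for-like: the
#' p-value is the left-tail rank of the statistic among statistics of
#' truly-absent targets.
#'
#' @param target 0/1 allele vector.
#' @param table a [freq_table] (`engine = "snv"`) or [beacon_table]
#'   (`engine = "beacon"`).
#' @param public_mafs per-site reference frequencies.
#' @param null a [null_dist] of baseline statistics on absent targets.
#' @param engine `"snv"` or `"beacon"`.
#' @param alpha significance level.
#' @param block_id,target_id labels carried into the result.
#' @return a `haplo_inference`-classed result (posterior fields `NA`; only
#'   the statistic, p-value and decision are meaningful).
#' @export
baseline_test <- function(target, table, public_mafs, null = NULL,
                          engine = c("snv", "beacon"), alpha = 0.05,
                          block_id = table$block_id, target_id = "target") {
  engine <- match.arg(engine)
  stat <- if (engine == "snv") snv_lrt(target, table, public_mafs)
          else beacon_optimal_baseline(target, table, public_mafs,
                                       table$n_genomes)
  p <- if (is.null(null)) NA_real_ else p_value(as.numeric(stat), null)
  new_inference(target = target_id, block_id = block_id,
                engine = paste0("baseline_", engine), outcome = "statistic",
                mode = "baseline", prior = NA_real_, lambda = as.numeric(stat),
                p_value = p, alpha = alpha)
}
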