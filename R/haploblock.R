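#' Haploblock objects
#'
#' A haploblock is a contiguous genomic segment whose variation sites are in
#' strong linkage disequilibrium, so that only a small panel of allelic
#' sequences (haplotypes) is observed in the population.  A `haploblock`
#' bundles the ordered sites with the known haplotype panel: a 0/1 allele
#' matrix (1 = minor allele relative to the public reference) and the public
#' population frequency of each haplotype.
#'
#' @param block_id character scalar identifier.
#' @param sites data.frame with columns `site_id`, `position` (1-based),
#'   `major_allele`, `minor_allele`, `public_maf` (minor-allele frequency in
#'   the public reference, in `[0, 0.5]`).
#' @param patterns integer/numeric matrix, t rows (haplotypes) by L columns
#'   (sites), entries 0/1 with 1 = minor allele.  Row names are haplotype ids.
#' @param frequencies numeric vector of length t of public population
#'   frequencies; must be strictly positive and sum to 1 (haplotypes with
#'   frequency 0 are by definition novel and are rejected).
#' @param tol numeric tolerance on the frequency sum.
#'
#' @return An object of class `haploblock` with elements `block_id`, `sites`,
#'   `patterns` and `frequencies`.
#' @examples
#' blk <- toy_block()
#' blk
#' prior_presence(blk$frequencies[3], N = 500)
#' @export
haploblock <- function(block_id, sites, patterns, frequencies, tol = 1e-6) {
  stopifnot(is.character(block_id), length(block_id) == 1L)
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  obj <- structure(
    list(block_id = block_id,
         sites = as.data.frame(sites),
         patterns = patterns,
         frequencies = as.numeric(frequencies)),
    class = "haploblock")
  validate_haploblock(obj, tol = tol)
}

#' @rdname haploblock
#' @param x a putative `haploblock`.
#' @export
validate_haploblock <- function(x, tol = 1e-6) {
  s <- x$sites
  need <- c("site_id", "position", "major_allele", "minor_allele", "public_maf")
  if (!all(need %in% names(s)))
    stop("haploblock sites must have columns: ", paste(need, collapse = ", "))
  if (any(s$major_allele == s$minor_allele))
    stop("major and minor allele identical at site ",
         s$site_id[s$major_allele == s$minor_allele][1L])
  if (any(s$public_maf < -tol | s$public_maf > 0.5 + tol))
    stop("public_maf outside [0, 0.5] at site ",
         s$site_id[which(s$public_maf < -tol | s$public_maf > 0.5 + tol)[1L]])
  L <- nrow(s)
  t_n <- nrow(x$patterns)
  if (t_n < 1L) stop("haploblock '", x$block_id, "' has an empty haplotype panel")
  if (ncol(x$patterns) != L)
    stop("haplotype pattern length ", ncol(x$patterns),
         " does not match number of sites ", L)
  if (!all(x$patterns %in% c(0L, 1L)))
    stop("haplotype patterns must be 0/1")
  if (is.null(rownames(x$patterns)))
    rownames(x$patterns) <- paste0("hap", seq_len(t_n))
  if (anyDuplicated(rownames(x$patterns)))
    stop("duplicate haplotype ids")
  key <- apply(x$patterns, 1L, paste0, collapse = "")
  if (anyDuplicated(key))
    stop("duplicate haplotype pattern: ", key[duplicated(key)][1L])
  f <- x$frequencies
  if (length(f) != t_n)
    stop("length(frequencies) != number of haplotypes")
  if (any(f <= 0))
    stop("haplotype '", rownames(x$patterns)[which(f <= 0)[1L]],
         "' has population frequency <= 0; zero-frequency haplotypes are ",
         "novel by definition and cannot be in the known panel")
  if (abs(sum(f) - 1) > max(tol, 1e-6))
    stop("haplotype frequencies of block '", x$block_id, "' sum to ",
         format(sum(f)), ", not 1")
  x
}

#' @export
print.haploblock <- function(x, ...) {
  cat("Haploblock '", x$block_id, "': L = ", nrow(x$sites),
      " sites, t = ", nrow(x$patterns), " known haplotypes\n", sep = "")
  show <- utils::head(seq_len(nrow(x$patterns)), 8L)
  pat <- apply(x$patterns[show, , drop = FALSE], 1L, paste0, collapse = "")
  cat(sprintf("  %-12s %s  f = %.4g\n", rownames(x$patterns)[show],
              substr(pat, 1L, 40L), x$frequencies[show]), sep = "")
  if (nrow(x$patterns) > 8L) cat("  ...\n")
  invisible(x)
}

#' Number of sites / haplotypes of a haploblock
#' @param block a `haploblock`.
#' @return integer scalar.
#' @export
n_sites <- function(block) nrow(block$sites)

#' @rdname n_sites
#' @export
n_haplotypes <- function(block) nrow(block$patterns)

#' Prior probability that a haplotype is present in a database
#'
#' For a haplotype of population frequency `f_A`, the prior probability that
#' at least one of the 2N haplotypes of a database of N genomes carries it is
#' `1 - (1 - f_A)^(2N)` (each of the 2N chromosomes is an independent draw
#' from the population).
#'
#' @param f_A population frequency in `[0, 1]`.
#' @param N number of genomes in the database (>= 1); the database holds 2N
#'   haplotypes.
#' @return probability in `[0, 1]`; the complementary prior of absence is
#'   `1 - prior_presence(f_A, N)`.
#' @examples
#' prior_presence(0.5, 1)    # 0.75
#' prior_presence(1e-4, 500) # ~0.095: a "rare" target at N = 500
#' @export
prior_presence <- function(f_A, N) {
  if (any(f_A < 0 | f_A > 1)) stop("f_A must lie in [0, 1]")
  if (any(N < 1)) stop("N must be >= 1")
  1 - (1 - f_A)^(2 * N)
}

#' Remove a haplotype from a block's known panel
#'
#' Used by the leave-one-out novel-haplotype experiments: dropping a haplotype
#' from the public panel makes it "novel" (unobserved publicly) even though a
#' private database may still contain carriers.  The remaining public
#' frequencies are renormalised to sum to 1 and per-site public minor-allele
#' frequencies are recomputed from the reduced panel.
#'
#' @param block a `haploblock`.
#' @param haplotype_id id of the haplotype to drop.
#' @param renormalize logical; renormalise remaining frequencies (default).
#' @return a list with the reduced `block`, the dropped `pattern` (0/1
#'   vector), its original public `frequency`, and its `haplotype_id`.
#' @export
drop_haplotype <- function(block, haplotype_id, renormalize = TRUE) {
  i <- match(haplotype_id, rownames(block$patterns))
  if (is.na(i)) stop("no haplotype '", haplotype_id, "' in block")
  if (nrow(block$patterns) < 2L) stop("cannot drop the only haplotype")
  pat <- block$patterns[i, ]
  f <- block$frequencies[i]
  pats <- block$patterns[-i, , drop = FALSE]
  freqs <- block$frequencies[-i]
  if (renormalize) freqs <- freqs / sum(freqs)
  sites <- block$sites
  sites$public_maf <- pmin(0.5, as.numeric(crossprod(pats, freqs)))
  blk <- haploblock(block$block_id, sites, pats, freqs)
  list(block = blk, pattern = pat, frequency = f, haplotype_id = haplotype_id)
}

#' The four-site, three-haplotype toy haploblock
#'
#' A minimal worked example block with L = 4 sites and t = 3 known haplotypes
#' with allele patterns 1011, 1001 and 0100 (1 = minor allele).  The panel
#' frequencies (0.5, 0.25, 0.25) are synthetic.  Useful for demonstrating the
#' constraint systems and the logical Beacon deductions on input small
#' enough to verify by hand.
#'
#' @return a `haploblock`.
#' @export
toy_block <- function() {
  sites <- data.frame(
    site_id = paste0("y", 1:4),
    position = c(101L, 202L, 303L, 404L),
    major_allele = c("A", "C", "G", "T"),
    minor_allele = c("G", "T", "A", "C"),
    public_maf = NA_real_)
  pats <- rbind(x1 = c(1L, 0L, 1L, 1L),
                x2 = c(1L, 0L, 0L, 1L),
                x3 = c(0L, 1L, 0L, 0L))
  f <- c(0.5, 0.25, 0.25)
  sites$public_maf <- pmin(0.5, as.numeric(crossprod(pats, f)))
  haploblock("toy", sites, pats, f)
}

pattern_strings <- function(patterns) {
  apply(patterns, 1L, paste0, collapse = "")
}
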