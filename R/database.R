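#' Synthetic private genome databases
#'
#' A `genome_db` records the ground truth of a simulated private database: the
#' distinct haplotype patterns it contains (possibly including patterns absent
#' from any public panel) and their integer counts, which must sum to `2N`
#' haplotypes for `N` genomes.
#'
#' @param n_genomes integer N.
#' @param patterns 0/1 matrix of distinct haplotype patterns (rows).
#' @param counts nonnegative integer counts per pattern, summing to `2 * N`.
#' @return an object of class `genome_db`.
#' @export
genome_db <- function(n_genomes, patterns, counts) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "integer"
  counts <- as.integer(counts)
  if (length(counts) != nrow(patterns))
    stop("one count per pattern required")
  if (any(counts < 0)) stop("negative haplotype count")
  if (sum(counts) != 2L * n_genomes)
    stop("counts sum to ", sum(counts), ", expected 2N = ", 2L * n_genomes)
  if (anyDuplicated(pattern_strings(patterns)))
    stop("duplicate pattern in database")
  structure(list(n_genomes = as.integer(n_genomes),
                 patterns = patterns, counts = counts),
            class = "genome_db")
}

#' @export
print.genome_db <- function(x, ...) {
  cat("Private genome database: N =", x$n_genomes, "genomes (",
      2L * x$n_genomes, "haplotypes ),", nrow(x$patterns),
      "distinct patterns\n")
  invisible(x)
}

#' Count of a given pattern in a database
#' @param db a `genome_db`.
#' @param pattern 0/1 allele vector.
#' @return integer count (0 if the pattern does not occur).
#' @export
db_count <- function(db, pattern) {
  key <- paste0(as.integer(pattern), collapse = "")
  i <- match(key, pattern_strings(db$patterns))
  if (is.na(i)) 0L else db$counts[i]
}

#' Summarise a private database into a published table
#'
#' Computes the summary statistic a data owner would publish for a haploblock:
#' either the per-site minor-allele count/frequency (`"frequency"` mode) or
#' the Beacon-style presence/absence of each minor allele (`"beacon"` mode).
#' Minor alleles are defined by the block's public reference, so the count at
#' a site is the total number of database haplotypes (novel patterns included)
#' carrying the public minor allele there.
#'
#' @param db a `genome_db`.
#' @param block the `haploblock` defining sites and minor alleles.
#' @param mode `"frequency"` or `"beacon"`.
#' @return a `freq_table` (fields `block_id`, `site_id`, `minor_allele`,
#'   `counts`, `n_genomes`) or a `beacon_table` (field `present` instead of
#'   `counts`).
#' @examples
#' blk <- toy_block()
#' db <- genome_db(2, blk$patterns, c(2, 1, 1))
#' summarize_database(db, blk)$counts   # 3 1 2 3
#' @export
summarize_database <- function(db, block, mode = c("frequency", "beacon")) {
  mode <- match.arg(mode)
  if (ncol(db$patterns) != n_sites(block))
    stop("database pattern length does not match block")
  if (sum(db$counts) != 2L * db$n_genomes)
    stop("database counts do not sum to 2N")
  cj <- as.integer(crossprod(db$patterns, db$counts))
  if (mode == "frequency")
    freq_table(block$block_id, block$sites$site_id,
               block$sites$minor_allele, cj, db$n_genomes)
  else
    beacon_table(block$block_id, block$sites$site_id,
                 block$sites$minor_allele, cj >= 1L, db$n_genomes)
}

#' Published frequency table of a haploblock
#'
#' Per-site minor-allele counts `c_j` in a database of `N` genomes; the
#' published frequency is `f(y_j) = c_j / 2N`.  All inference internals work
#' on the integer counts, since the haplotype-count constraint systems only
#' admit exact solutions in integers.
#'
#' @param block_id,site_id,minor_allele identifiers (recycled as needed).
#' @param counts integer minor-allele counts in `[0, 2N]`.
#' @param n_genomes database size N.
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(block_id, site_id, minor_allele, counts, n_genomes) {
  counts <- as.integer(round(counts))
  n_genomes <- as.integer(n_genomes)
  if (any(counts < 0L | counts > 2L * n_genomes))
    stop("minor-allele count outside [0, 2N]")
  structure(list(block_id = block_id, site_id = as.character(site_id),
                 minor_allele = as.character(minor_allele),
                 counts = counts, n_genomes = n_genomes),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table for block '", x$block_id, "' (N = ", x$n_genomes,
      " genomes)\n", sep = "")
  print(data.frame(site_id = x$site_id, count = x$counts,
                   frequency = x$counts / (2 * x$n_genomes)), ...)
  invisible(x)
}

#' Published Beacon table of a haploblock
#'
#' Per-site yes/no answers: is the minor allele present in at least one
#' database haplotype?  The database size `N` is carried along because the
#' inference conditions on it (whether a Beacon attacker knows N exactly is
#' an assumption; here it is a required input).
#'
#' @inheritParams freq_table
#' @param present logical vector, one answer per site.
#' @return an object of class `beacon_table`.
#' @export
beacon_table <- function(block_id, site_id, minor_allele, present, n_genomes) {
  structure(list(block_id = block_id, site_id = as.character(site_id),
                 minor_allele = as.character(minor_allele),
                 present = as.logical(present),
                 n_genomes = as.integer(n_genomes)),
            class = "beacon_table")
}

#' @export
print.beacon_table <- function(x, ...) {
  cat("Beacon table for block '", x$block_id, "' (N = ", x$n_genomes,
      " genomes)\n", sep = "")
  print(data.frame(site_id = x$site_id, present = x$present), ...)
  invisible(x)
}

#' Convert a frequency table to a Beacon table
#'
#' Thresholds the per-site counts at >= 1; by construction this equals
#' `summarize_database(db, block, "beacon")` for the same database.
#' @param ft a `freq_table`.
#' @return a `beacon_table`.
#' @export
as_beacon <- function(ft) {
  beacon_table(ft$block_id, ft$site_id, ft$minor_allele,
               ft$counts >= 1L, ft$n_genomes)
}
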