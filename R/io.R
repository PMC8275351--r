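#' Read and write haploblock and table files
#'
#' Haploblocks are stored as JSON:
#' `{block_id, sites: [{site_id, position, major, minor, public_maf}],
#'   haplotypes: [{id, pattern: "1011", freq}]}`.
#' Frequency tables are TSV with columns
#' `block_id, site_id, minor_allele, count, n_genomes`; Beacon tables are TSV
#' with `block_id, site_id, minor_allele, present` plus an `n_genomes` column.
#' Writing then reading any of these is the identity (bit-exact for counts
#' and patterns, to near machine precision for frequencies).
#'
#' @param path file path.
#' @param renormalize if `TRUE`, haplotype frequencies that do not sum to 1
#'   within `tol` are rescaled instead of rejected.
#' @param tol tolerance on the frequency sum.
#' @return `read_haploblock()` returns a [haploblock]; the writers return the
#'   path invisibly.
#' @name haploblock_io
NULL

#' @rdname haploblock_io
#' @export
read_haploblock <- function(path, renormalize = FALSE, tol = 1e-6) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$block_id) || is.null(x$sites) || is.null(x$haplotypes))
    stop("haploblock JSON '", path,
         "' must have fields block_id, sites, haplotypes")
  s <- as.data.frame(x$sites)
  names(s)[names(s) == "major"] <- "major_allele"
  names(s)[names(s) == "minor"] <- "minor_allele"
  h <- as.data.frame(x$haplotypes)
  if (nrow(h) == 0L)
    stop("haploblock '", x$block_id, "' has an empty haplotype list")
  L <- nrow(s)
  bad <- which(nchar(h$pattern) != L)
  if (length(bad))
    stop("haplotype '", h$id[bad[1L]], "' pattern length ",
         nchar(h$pattern[bad[1L]]), " != L = ", L)
  pats <- do.call(rbind, lapply(strsplit(h$pattern, ""), as.integer))
  rownames(pats) <- h$id
  f <- as.numeric(h$freq)
  if (renormalize && sum(f) > 0) f <- f / sum(f)
  haploblock(x$block_id, s, pats, f, tol = tol)
}

#' @rdname haploblock_io
#' @param block a [haploblock].
#' @export
write_haploblock <- function(block, path) {
  x <- list(
    block_id = block$block_id,
    sites = data.frame(site_id = block$sites$site_id,
                       position = block$sites$position,
                       major = block$sites$major_allele,
                       minor = block$sites$minor_allele,
                       public_maf = block$sites$public_maf),
    haplotypes = data.frame(id = rownames(block$patterns),
                            pattern = unname(pattern_strings(block$patterns)),
                            freq = block$frequencies,
                            row.names = NULL))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname haploblock_io
#' @export
read_freq_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ft <- freq_table(d$block_id[1L], d$site_id, d$minor_allele,
                   d$count, d$n_genomes[1L])
  if (!is.null(d$frequency)) {
    # reject tables whose printed frequencies are inconsistent with N
    dev <- abs(d$frequency * 2 * ft$n_genomes - ft$counts)
    if (any(dev > 0.01))
      stop("frequency column inconsistent with count/n_genomes at site ",
           d$site_id[which(dev > 0.01)[1L]])
  }
  ft
}

#' @rdname haploblock_io
#' @param ft a [freq_table].
#' @export
write_freq_table <- function(ft, path) {
  utils::write.table(
    data.frame(block_id = ft$block_id, site_id = ft$site_id,
               minor_allele = ft$minor_allele, count = ft$counts,
               n_genomes = ft$n_genomes,
               frequency = ft$counts / (2 * ft$n_genomes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname haploblock_io
#' @export
read_beacon_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  beacon_table(d$block_id[1L], d$site_id, d$minor_allele,
               d$present == 1L | d$present == TRUE, d$n_genomes[1L])
}

#' @rdname haploblock_io
#' @param bt a [beacon_table].
#' @export
write_beacon_table <- function(bt, path) {
  utils::write.table(
    data.frame(block_id = bt$block_id, site_id = bt$site_id,
               minor_allele = bt$minor_allele,
               present = as.integer(bt$present), n_genomes = bt$n_genomes),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a haploblock from phased VCF genotypes
#'
#' Builds the known-haplotype panel of a block directly from the phased
#' genotypes of a public reference VCF: every chromosome column becomes one
#' haplotype observation, the distinct observed patterns form the panel and
#' their observed fractions the public frequencies.  Only biallelic SNV
#' records with phased GT ("|" separator) are accepted; multiallelic or
#' unphased records raise an error.  This is a minimal ingestion path for the
#' common case of a small site subset; no VCF feature beyond GT is used.
#'
#' @param path path to an uncompressed VCF.
#' @param block_id id for the resulting block.
#' @return a [haploblock].
#' @export
haploblock_from_vcf <- function(path, block_id = "vcf_block") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "##")]
  if (!length(ln) || !startsWith(ln[1L], "#CHROM"))
    stop("not a VCF: missing #CHROM header line")
  header <- strsplit(sub("^#", "", ln[1L]), "\t", fixed = TRUE)[[1L]]
  body <- ln[-1L]
  if (!length(body)) stop("VCF has no variant records")
  rec <- strsplit(body, "\t", fixed = TRUE)
  nsamp <- length(header) - 9L
  if (nsamp < 1L) stop("VCF has no sample columns")
  pos <- integer(length(rec)); ref <- alt <- id <- character(length(rec))
  hapmat <- matrix(NA_integer_, nrow = 2L * nsamp, ncol = length(rec))
  for (j in seq_along(rec)) {
    r <- rec[[j]]
    if (grepl(",", r[5L], fixed = TRUE))
      stop("multiallelic record at position ", r[2L], "; biallelic SNVs only")
    if (nchar(r[4L]) != 1L || nchar(r[5L]) != 1L)
      stop("non-SNV record at position ", r[2L])
    pos[j] <- as.integer(r[2L])
    id[j] <- if (r[3L] == ".") paste0("site", r[2L]) else r[3L]
    ref[j] <- r[4L]; alt[j] <- r[5L]
    gt <- sub(":.*$", "", r[10:(9L + nsamp)])
    if (any(!grepl("^[01]\\|[01]$", gt)))
      stop("unphased or missing genotype at position ", r[2L],
           "; phased biallelic GT required")
    al <- as.integer(unlist(strsplit(gt, "|", fixed = TRUE)))
    hapmat[, j] <- al
  }
  key <- apply(hapmat, 1L, paste0, collapse = "")
  tab <- table(key)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  rownames(pats) <- paste0("hap", seq_len(nrow(pats)))
  f <- as.numeric(tab) / sum(tab)
  maf <- as.numeric(crossprod(pats, f))
  # orient so that 1 marks the minor allele in the panel
  flip <- maf > 0.5
  if (any(flip)) {
    pats[, flip] <- 1L - pats[, flip]
    tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
    maf[flip] <- 1 - maf[flip]
    key2 <- apply(pats, 1L, paste0, collapse = "")
    agg <- tapply(f, key2, sum)
    pats <- do.call(rbind, lapply(strsplit(names(agg), ""), as.integer))
    rownames(pats) <- paste0("hap", seq_len(nrow(pats)))
    f <- as.numeric(agg)
  }
  sites <- data.frame(site_id = id, position = pos, major_allele = ref,
                      minor_allele = alt, public_maf = maf)
  haploblock(block_id, sites, pats, f)
}

#' Read / write an empirical null distribution
#'
#' Stored as a single-column TSV of sorted statistic values with `#`-prefixed
#' provenance header lines (engine, size, free-text provenance).
#'
#' @param null a [null_dist].
#' @param path file path.
#' @return `read_null_dist()` returns a [null_dist].
#' @export
write_null_dist <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# engine: ", attr(null, "engine")),
               paste0("# M: ", length(null)),
               paste0("# provenance: ", attr(null, "provenance")),
               "lambda"), con)
  writeLines(format(as.numeric(null), digits = 17), con)
  invisible(path)
}

#' @rdname write_null_dist
#' @export
read_null_dist <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  body <- ln[!startsWith(ln, "#")]
  vals <- as.numeric(body[-1L])  # drop column name
  engine <- sub("^# engine: ", "", hdr[startsWith(hdr, "# engine:")])
  prov <- sub("^# provenance: ", "", hdr[startsWith(hdr, "# provenance:")])
  null_dist(vals, engine = if (length(engine)) engine else "unknown",
            provenance = if (length(prov)) prov else "")
}
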