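test_that("prior presence probability follows the closed form", {
  expect_equal(prior_presence(0, 100), 0)
  expect_equal(prior_presence(1, 7), 1)
  expect_equal(prior_presence(0.5, 1), 0.75)
  expect_equal(prior_presence(0.01, 50), 1 - 0.99^100)
  expect_error(prior_presence(-0.1, 10), "\\[0, 1\\]")
  expect_error(prior_presence(1.2, 10), "\\[0, 1\\]")
  expect_error(prior_presence(0.2, 0), "N must be")
  # monotone nondecreasing in both arguments
  f <- seq(0, 1, by = 0.05)
  expect_true(all(diff(prior_presence(f, 20)) >= 0))
  Ns <- 1:50
  expect_true(all(diff(prior_presence(0.01, Ns)) >= 0))
})

test_that("haploblock validation rejects malformed panels", {
  blk <- toy_block()
  expect_s3_class(blk, "haploblock")
  # duplicate pattern
  expect_error(
    haploblock("b", blk$sites, blk$patterns[c(1, 1, 2), ], c(.5, .3, .2)),
    "duplicate haplotype")
  # zero population frequency is by definition novel
  expect_error(
    haploblock("b", blk$sites, blk$patterns, c(0.75, 0.25, 0)),
    "novel")
  # frequencies must sum to one
  expect_error(
    haploblock("b", blk$sites, blk$patterns, c(0.5, 0.25, 0.1)),
    "sum to")
  # pattern length must match site count
  expect_error(
    haploblock("b", blk$sites, blk$patterns[, 1:3], c(0.5, 0.25, 0.25)),
    "does not match")
  # degenerate monomorphic block is legal
  one <- haploblock("mono", blk$sites,
                    matrix(c(0L, 1L, 0L, 0L), 1, 4,
                           dimnames = list("only", NULL)), 1)
  expect_equal(n_haplotypes(one), 1L)
})

test_that("haploblock JSON round-trips the worked toy example unchanged", {
  blk <- toy_block()
  path <- withr::local_tempfile(fileext = ".json")
  write_haploblock(blk, path)
  back <- read_haploblock(path)
  expect_identical(back$patterns, blk$patterns)
  expect_equal(back$frequencies, blk$frequencies)
  expect_equal(back$sites$position, blk$sites$position)
  expect_equal(back$sites$public_maf, blk$sites$public_maf)
  # a second round trip is bit-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_haploblock(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # the shipped fixture matches the in-code constructor
  shipped <- read_haploblock(system.file("extdata", "toy_block.json",
                                         package = "haplomember"))
  expect_identical(shipped$patterns, blk$patterns)
})

test_that("frequency and Beacon tables round-trip through TSV", {
  blk <- toy_block()
  db <- genome_db(2, blk$patterns, c(2L, 1L, 1L))
  ft <- summarize_database(db, blk)
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_freq_table(ft, fpath)
  ft2 <- read_freq_table(fpath)
  expect_identical(ft2$counts, ft$counts)
  expect_identical(ft2$n_genomes, ft$n_genomes)
  bt <- summarize_database(db, blk, "beacon")
  bpath <- withr::local_tempfile(fileext = ".tsv")
  write_beacon_table(bt, bpath)
  expect_identical(read_beacon_table(bpath)$present, bt$present)
  # a frequency column inconsistent with N is rejected
  d <- utils::read.delim(fpath)
  d$frequency <- d$frequency + 0.1
  utils::write.table(d, fpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_freq_table(fpath), "inconsistent")
})

test_that("database summaries count minor alleles per site", {
  blk <- toy_block()
  db <- genome_db(2, blk$patterns, c(2L, 1L, 1L))
  ft <- summarize_database(db, blk)
  expect_identical(ft$counts, c(3L, 1L, 2L, 3L))  # hand-summed columns
  # all-major database: no minor allele anywhere
  db0 <- genome_db(3, matrix(0L, 1, 4), 6L)
  expect_identical(summarize_database(db0, blk)$counts, rep(0L, 4))
  expect_false(any(summarize_database(db0, blk, "beacon")$present))
  # novel patterns contribute to the counts
  dbn <- genome_db(3, rbind(blk$patterns, novel = c(0L, 1L, 1L, 0L)),
                   c(2L, 1L, 1L, 2L))
  expect_identical(summarize_database(dbn, blk)$counts,
                   c(3L, 3L, 4L, 3L))
  expect_error(genome_db(2, blk$patterns, c(2L, 1L, 2L)), "sum to")
})

test_that("beacon summaries equal thresholded frequency summaries", {
  set.seed(404)
  cfg <- sim_config(L = 8, t = 5, N = 10, seed = 404)
  for (r in 1:100) {
    blk <- generate_block(cfg, paste0("R", r), seed = 404 + r)
    db <- sample_database(blk, 10, seed = 1000 + r)
    ft <- summarize_database(db, blk)
    bt <- summarize_database(db, blk, "beacon")
    expect_identical(bt$present, ft$counts >= 1L)
    expect_identical(as_beacon(ft)$present, bt$present)
  }
})

test_that("phased VCF ingestion builds a panel; bad records are rejected", {
  hdr <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", "S2", sep = "\t"))
  rec <- function(pos, ref, alt, g1, g2)
    paste("1", pos, ".", ref, alt, ".", "PASS", ".", "GT", g1, g2,
          sep = "\t")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr, rec(100, "A", "G", "0|1", "0|0"),
               rec(200, "C", "T", "1|1", "0|1")), path)
  blk <- haploblock_from_vcf(path)
  expect_s3_class(blk, "haploblock")
  expect_equal(n_sites(blk), 2L)
  expect_equal(sum(blk$frequencies), 1)
  # 4 chromosomes: patterns 01, 11, 00, 01 -> three distinct haplotypes
  expect_equal(n_haplotypes(blk), 3L)
  writeLines(c(hdr, rec(100, "A", "G", "0/1", "0|0")), path)
  expect_error(haploblock_from_vcf(path), "unphased")
  writeLines(c(hdr, rec(100, "A", "G,T", "0|1", "0|0")), path)
  expect_error(haploblock_from_vcf(path), "multiallelic")
})

test_that("null distributions round-trip with provenance", {
  nd <- null_dist(c(3, 1, Inf, 2), engine = "khf", provenance = "unit test")
  expect_equal(as.numeric(nd), c(1, 2, 3, Inf))  # sorted
  path <- withr::local_tempfile(fileext = ".tsv")
  write_null_dist(nd, path)
  back <- read_null_dist(path)
  expect_equal(as.numeric(back), as.numeric(nd))
  expect_equal(attr(back, "engine"), "khf")
  expect_error(null_dist(numeric(0)), "empty")
})
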