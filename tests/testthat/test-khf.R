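toy_ft <- function(counts = c(3L, 1L, 2L, 3L), N = 2L) {
  blk <- toy_block()
  freq_table(blk$block_id, blk$sites$site_id, blk$sites$minor_allele,
             counts, N)
}

test_that("the toy constraint system encodes the per-site carrier sums", {
  blk <- toy_block()
  cs <- build_constraints(blk, toy_ft())
  # row j holds b_ij: y1 <- x1+x2, y2 <- x3, y3 <- x1, y4 <- x1+x2
  expect_equal(unname(cs$B), rbind(c(1, 1, 0), c(0, 0, 1),
                                   c(1, 0, 0), c(1, 1, 0)))
  expect_equal(cs$c, c(3L, 1L, 2L, 3L))
  expect_equal(cs$two_N, 4L)
  expect_error(
    build_constraints(blk, freq_table("toy", paste0("z", 1:4), "G",
                                      c(1, 1, 1, 1), 2)),
    "do not match")
  # single-haplotype block: trivially consistent system
  one <- haploblock("mono", blk$sites,
                    matrix(c(1L, 0L, 1L, 1L), 1, 4,
                           dimnames = list("only", NULL)), 1)
  ft1 <- freq_table("mono", blk$sites$site_id, blk$sites$minor_allele,
                    c(6L, 0L, 6L, 6L), 3L)
  ss1 <- enumerate_solutions(build_constraints(one, ft1))
  expect_equal(ss1$outcome, "unique")
  expect_equal(unname(ss1$solutions[1, ]), 6L)
})

test_that("toy enumeration finds the unique composition (2, 1, 1)", {
  ss <- enumerate_solutions(build_constraints(toy_block(), toy_ft()))
  expect_equal(ss$outcome, "unique")
  expect_equal(unname(ss$solutions[1, ]), c(2L, 1L, 1L))
})

test_that("all-zero table resolves through the all-major haplotype or not at all", {
  # no all-major haplotype in the toy panel: outcome none
  blk <- toy_block()
  ss <- enumerate_solutions(build_constraints(blk, toy_ft(rep(0L, 4))))
  expect_equal(ss$outcome, "none")
  # add an all-major haplotype: everything must sit on it
  pats <- rbind(blk$patterns, x0 = rep(0L, 4))
  blk2 <- haploblock("toy2", blk$sites, pats, c(.4, .2, .2, .2))
  ft <- freq_table("toy2", blk$sites$site_id, blk$sites$minor_allele,
                   rep(0L, 4), 2L)
  ss2 <- enumerate_solutions(build_constraints(blk2, ft))
  expect_equal(ss2$outcome, "unique")
  expect_equal(unname(ss2$solutions[1, ]), c(0L, 0L, 0L, 4L))
})

test_that("depth-first enumeration equals brute-force composition search", {
  for (r in 1:60) {
    sys <- random_system(t_max = 6L, two_N_max = 20L, seed = 7000 + r)
    oracle <- brute_solutions(sys$B, sys$c, sys$two_N)
    got <- haplomember:::enumerate_counts(sys$B, sys$c, sys$two_N)
    expect_equal(unname(got$n), unname(oracle), ignore_attr = TRUE)
    expect_gte(nrow(got$n), 1L)   # the generating truth is always a solution
  }
})

test_that("every solution satisfies the constraints exactly and revealing a site never adds solutions", {
  for (r in 1:20) {
    sys <- random_system(t_max = 5L, two_N_max = 16L, seed = 8100 + r)
    full <- haplomember:::enumerate_counts(sys$B, sys$c, sys$two_N)
    for (k in seq_len(nrow(full$n))) {
      expect_identical(as.integer(sys$B %*% full$n[k, ]), sys$c)
      expect_identical(sum(full$n[k, ]), sys$two_N)
    }
    if (nrow(sys$B) >= 2L) {
      part <- haplomember:::enumerate_counts(
        sys$B[-1L, , drop = FALSE], sys$c[-1L], sys$two_N)
      expect_lte(nrow(full$n), nrow(part$n))
    }
  }
})

test_that("solution capacity overrun raises a capacity error", {
  # 1-site system over 5 haplotypes, massively underdetermined
  B <- matrix(c(1L, 0L, 0L, 0L, 0L), 1, 5)
  expect_error(
    haplomember:::enumerate_counts(B, 3L, 60L, max_solutions = 10),
    class = "haplomember_capacity_error")
})

test_that("literal likelihoods follow the printed solution sums", {
  # unique solution: indicator semantics
  ss <- enumerate_solutions(build_constraints(toy_block(), toy_ft()))
  expect_equal(likelihood_present(ss, "x1"), 1)
  expect_equal(likelihood_absent(ss, "x1"), 0)
  # craft a two-solution set: target has n = 1 in one, 0 in the other
  ss2 <- structure(list(outcome = "multiple",
                        solutions = rbind(c(1L, 3L), c(0L, 4L)),
                        two_N = 4L, haplotype_ids = c("a", "b")),
                   class = "solution_set")
  expect_equal(likelihood_present(ss2, 1),
               choose(4, 1) * 0.25 * 0.75^3)     # Binomial(4, 1/4) at 1
  expect_equal(likelihood_absent(ss2, 1), 1)     # one A-free solution
  # three solutions, target absent in two: literal absent likelihood is 2
  ss3 <- structure(list(outcome = "multiple",
                        solutions = rbind(c(2L, 2L), c(0L, 4L), c(0L, 4L)),
                        two_N = 4L, haplotype_ids = c("a", "b")),
                   class = "solution_set")
  expect_equal(likelihood_absent(ss3, 1), 2)
  # population-frequency mode substitutes the public frequency
  expect_equal(likelihood_present(ss2, 1, freq_mode = "population",
                                  f_pop = 0.1),
               dbinom(1, 4, 0.1))
  expect_equal(likelihood_absent(ss2, 1, freq_mode = "population",
                                 f_pop = 0.1), 0.9^4)
  expect_error(likelihood_present(
    structure(list(outcome = "none", solutions = matrix(0L, 0, 2),
                   two_N = 4L, haplotype_ids = c("a", "b")),
              class = "solution_set"), 1), "novel")
})

test_that("unique solutions give certainty: posterior 1 or 0, Lambda 0 or Inf", {
  blk <- toy_block()
  ft <- toy_ft()
  for (id in c("x1", "x2", "x3")) {
    r <- khf_test(blk, ft, id)
    expect_equal(r$posterior, 1)
    expect_equal(r$lambda, 0)
  }
  # remove x3 from the database: counts (2, 2, 0, 4), 2N = 4
  db <- genome_db(2, blk$patterns, c(2L, 2L, 0L))
  r0 <- khf_test(blk, summarize_database(db, blk), "x3")
  expect_equal(r0$posterior, 0)
  expect_equal(r0$lambda, Inf)
  # with a null distribution, Lambda = Inf maps to p-value 1
  nd <- null_dist(c(0.5, 2, 10))
  r1 <- khf_test(blk, summarize_database(db, blk), "x3", null_dist = nd)
  expect_equal(r1$p_value, 1)
  expect_false(r1$decision)
})

test_that("normalising the likelihood pair leaves the posterior unchanged", {
  blk <- toy_block()
  ss <- structure(list(outcome = "multiple",
                       solutions = rbind(c(1L, 0L, 3L), c(0L, 1L, 3L),
                                         c(2L, 1L, 1L)),
                       two_N = 4L, haplotype_ids = c("x1", "x2", "x3")),
                  class = "solution_set")
  lit <- khf_test(blk, toy_ft(), "x1", solutions = ss, mode = "literal")
  nrm <- khf_test(blk, toy_ft(), "x1", solutions = ss, mode = "normalized")
  expect_equal(nrm$posterior, lit$posterior)
  expect_equal(nrm$lik_in + nrm$lik_out, 1)
  # a flat likelihood pair returns exactly the prior odds
  r <- khf_test(blk, toy_ft(), "x2", solutions =
    structure(list(outcome = "multiple",
                   solutions = rbind(c(2L, 1L, 1L), c(3L, 0L, 1L)),
                   two_N = 4L, haplotype_ids = c("x1", "x2", "x3")),
              class = "solution_set"))
  expect_true(r$posterior > 0 && r$posterior < 1)
})

test_that("posterior exceeds the prior for truly present rare targets", {
  cfg <- sim_config(L = 12, t = 6, N = 60, seed = 314)
  post <- prior <- numeric(0)
  for (r in 1:40) {
    blk <- generate_block(cfg, paste0("P", r), seed = 314 + r)
    tg <- rare_targets(blk, 60, 0.5, 1L)
    if (!length(tg)) next
    db <- sample_database(blk, 60, forced_in = tg, seed = 5000 + r)
    res <- khf_test(blk, summarize_database(db, blk), tg)
    if (res$outcome == "none" || is.na(res$posterior)) next
    post <- c(post, res$posterior); prior <- c(prior, res$prior)
  }
  expect_gt(length(post), 20)
  expect_gt(mean(post), mean(prior))
})

test_that("inference results carry the Bayes identity", {
  blk <- toy_block()
  ss2 <- structure(list(outcome = "multiple",
                        solutions = rbind(c(1L, 0L, 3L), c(0L, 1L, 3L)),
                        two_N = 4L, haplotype_ids = c("x1", "x2", "x3")),
                   class = "solution_set")
  ft <- toy_ft()
  r <- khf_test(blk, ft, "x1", solutions = ss2)
  lin <- likelihood_present(ss2, 1); lout <- likelihood_absent(ss2, 1)
  expect_equal(r$lambda,
               (lout * (1 - r$prior)) / (lin * r$prior))
  expect_true(r$posterior >= 0 && r$posterior <= 1)
})
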