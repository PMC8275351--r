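toy_bt <- function(present = c(TRUE, TRUE, FALSE, TRUE), N = 2L) {
  blk <- toy_block()
  beacon_table(blk$block_id, blk$sites$site_id, blk$sites$minor_allele,
               present, N)
}

test_that("the worked Beacon deduction identifies x2, x3 present and x1 absent", {
  lc <- derive_logical_constraints(toy_block(), toy_bt())
  expect_equal(unname(lc$status),
               c("must_absent", "must_present", "must_present"))
  # y4 has the same carrier set as y1 after exclusion: one disjunction each
  # for the two distinct surviving sets ({x2} and {x3})
  expect_equal(length(lc$disjunctions), 2L)
})

test_that("constraint derivation is order-independent and handles edge cases", {
  blk <- toy_block()
  bt <- toy_bt()
  base <- derive_logical_constraints(blk, bt)$status
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    sites <- blk$sites[perm, ]
    pats <- blk$patterns[, perm]
    blk_p <- haploblock("toy", sites, pats, blk$frequencies)
    bt_p <- beacon_table("toy", sites$site_id, sites$minor_allele,
                         bt$present[perm], 2L)
    expect_equal(unname(derive_logical_constraints(blk_p, bt_p)$status),
                 unname(base))
  }
  # all sites absent: every minor-allele carrier excluded
  lc0 <- derive_logical_constraints(blk, toy_bt(rep(FALSE, 4)))
  expect_equal(unname(lc0$status), rep("must_absent", 3))
  # a present site whose carriers are all excluded is a contradiction
  expect_error(
    derive_logical_constraints(blk, toy_bt(c(FALSE, FALSE, TRUE, FALSE))),
    class = "haplomember_inconsistency_error")
  # all answers present: x1 and x3 are forced by their singleton-carrier
  # sites, while the shared site y1 leaves x2 unconstrained (a recorded
  # disjunction only)
  lc2 <- derive_logical_constraints(blk, toy_bt(rep(TRUE, 4)))
  expect_equal(unname(lc2$status),
               c("must_present", "unconstrained", "must_present"))
})

test_that("Monte-Carlo event estimates match closed forms and exact sums", {
  blk <- toy_block()
  t_n <- 3L
  # vacuous event
  e0 <- estimate_event_probability(blk, mn_event(t_n), N = 5, seed = 1)
  expect_equal(e0$estimate, 1)
  # marginal {n_i >= 1} against its closed form 1 - (1 - f)^2N
  for (i in 1:3) {
    f <- blk$frequencies[i]
    est <- estimate_event_probability(
      blk, mn_event(t_n, lo = ifelse(1:3 == i, 1L, 0L)),
      N = 5, n_samples = 5000, seed = 10 + i)
    exact <- 1 - (1 - f)^10
    se <- sqrt(exact * (1 - exact) / 5000)
    expect_lt(abs(est$estimate - exact), 3 * se + 1e-12)
  }
  # the printed three-haplotype scheme (Q = y1's minor allele present):
  # P(Q|x3 in DB) = p(n3>=1) - p(n1=0, n2=0, n3>=1), each term a CDF-style
  # box event over the counts
  exact_a <- exact_event_probability(
    blk$frequencies, 10, lo = c(0, 0, 1), hi = c(10, 10, 10))
  exact_b <- exact_event_probability(
    blk$frequencies, 10, lo = c(0, 0, 1), hi = c(0, 0, 10))
  est_a <- estimate_event_probability(
    blk, mn_event(t_n, lo = c(0, 0, 1)), N = 5,
    n_samples = 5000, seed = 77)$estimate
  est_b <- estimate_event_probability(
    blk, mn_event(t_n, lo = c(0, 0, 1), hi = c(0, 0, Inf)), N = 5,
    n_samples = 5000, seed = 78)$estimate
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(est_a - exact_a), 3 * se + 1e-12)
  expect_lt(abs(est_b - exact_b), 3 * se + 1e-12)
  expect_lt(abs((est_a - est_b) - (exact_a - exact_b)), 5 * se + 1e-12)
  expect_error(estimate_event_probability(blk, mn_event(3), N = 5,
                                          n_samples = 0), "n_samples")
})

test_that("beacon-consistency events agree with exhaustive composition sums", {
  for (r in 1:8) {
    set.seed(6200 + r)
    t_n <- sample(2:4, 1)
    L <- sample(2:4, 1)
    repeat {
      pats <- matrix(rbinom(t_n * L, 1, 0.5), t_n, L)
      if (!anyDuplicated(apply(pats, 1, paste0, collapse = ""))) break
    }
    f <- as.numeric(rmultinom(1, 50, rep(1 / t_n, t_n)) + 1)
    f <- f / sum(f)
    blk <- block_from_patterns(pats, f)
    N <- sample(2:5, 1)
    db <- sample_database(blk, N, seed = 6300 + r)
    bt <- summarize_database(db, blk, "beacon")
    i <- sample(t_n, 1)
    lo <- ifelse(seq_len(t_n) == i, 1L, 0L)
    est <- estimate_event_probability(
      blk, mn_event(t_n, lo = lo, beacon = bt), N,
      n_samples = 5000, seed = 6400 + r)
    exact <- exact_event_probability(f, 2 * N, lo, rep(2 * N, t_n),
                                     patterns = pats, present = bt$present)
    se <- sqrt(max(exact * (1 - exact), 1e-6) / 5000)
    expect_lt(abs(est$estimate - exact), 4 * se + 2e-3)
  }
})

test_that("deduced targets bypass estimation with posterior 1 or 0", {
  blk <- toy_block()
  bt <- toy_bt()
  r3 <- khb_test(blk, bt, "x3", seed = 5)
  expect_equal(r3$posterior, 1)
  expect_equal(r3$lambda, 0)
  r1 <- khb_test(blk, bt, "x1", seed = 5)
  expect_equal(r1$posterior, 0)
  expect_equal(r1$lambda, Inf)
  nd <- null_dist(c(1, 2, 3))
  expect_equal(khb_test(blk, bt, "x1", null_dist = nd, seed = 5)$p_value, 1)
})

test_that("Monte-Carlo standard error shrinks like one over root n", {
  blk <- toy_block()
  t_n <- 3L
  sds <- vapply(c(250, 1000, 4000), function(n) {
    ests <- vapply(1:30, function(s)
      estimate_event_probability(
        blk, mn_event(t_n, lo = c(0, 0, 1)), N = 5,
        n_samples = n, seed = 1000 * n + s)$estimate, numeric(1))
    sd(ests)
  }, numeric(1))
  fit <- stats::lm(log(sds) ~ log(c(250, 1000, 4000)))
  expect_lt(abs(unname(coef(fit)[2]) + 0.5), 0.2)
})

test_that("estimation is reproducible under a seed and posterior beats the prior when present", {
  cfg <- sim_config(L = 10, t = 6, N = 40, seed = 99)
  blk <- generate_block(cfg, "S", seed = 99)
  db <- sample_database(blk, 40, seed = 100)
  bt <- summarize_database(db, blk, "beacon")
  tg <- rownames(blk$patterns)[which.min(blk$frequencies)]
  a <- khb_test(blk, bt, tg, seed = 42)
  b <- khb_test(blk, bt, tg, seed = 42)
  expect_identical(a$lambda, b$lambda)
  # truly-present rare targets: posterior above prior in most fixtures
  wins <- 0L; tot <- 0L
  for (r in 1:25) {
    blk <- generate_block(cfg, paste0("W", r), seed = 200 + r)
    tg <- rare_targets(blk, 40, 0.5, 1L)
    if (!length(tg)) next
    db <- sample_database(blk, 40, forced_in = tg, seed = 300 + r)
    bt <- summarize_database(db, blk, "beacon")
    res <- khb_test(blk, bt, tg, seed = 400 + r, n_samples = 2000)
    if (is.na(res$posterior)) next
    tot <- tot + 1L
    if (res$posterior > res$prior) wins <- wins + 1L
  }
  expect_gt(tot, 12)
  expect_gte(wins / tot, 0.8)
})
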