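test_that("problem formulation validates its inputs", {
  blk <- toy_block()
  ft <- freq_table("toy", blk$sites$site_id, blk$sites$minor_allele,
                   c(3L, 1L, 2L, 3L), 2L)
  expect_error(formulate_ilp(blk, ft, 0, integer(0)), "positive")
  expect_error(formulate_ilp(blk, ft, 1, 0L), "positive")
  expect_error(formulate_ilp(blk, ft, 1, 5L), "exceed")
  ilp <- formulate_ilp(blk, ft, 2, c(1L, 2L))
  expect_equal(ilp$k_vector, c(1L, 2L))
  expect_equal(ilp$two_N, 4L)
})

test_that("reconstruction recovers a planted novel haplotype on the toy block", {
  blk <- toy_block()
  db <- genome_db(3, rbind(blk$patterns, novel = c(0L, 1L, 1L, 0L)),
                  c(2L, 1L, 1L, 2L))
  ft <- summarize_database(db, blk)
  # the known panel alone cannot explain this table
  expect_equal(enumerate_solutions(build_constraints(blk, ft))$outcome,
               "none")
  sol <- reconstruct_novel(blk, ft, d_max = 1)
  expect_true(sol$feasible)
  expect_equal(unname(sol$z[1, ]), c(0L, 1L, 1L, 0L))
  # feasibility certificate: solution reproduces the table exactly
  recon <- as.integer(t(blk$patterns) %*% sol$n + sol$counts[1] * sol$z[1, ])
  expect_identical(recon, ft$counts)
})

test_that("returned counts and patterns are minimal and optimal versus exhaustive search", {
  n_checked <- 0L
  for (r in 1:25) {
    set.seed(7700 + r)
    t_n <- sample(2:4, 1); L <- sample(3:6, 1)
    repeat {
      pats <- matrix(rbinom(t_n * L, 1, 0.4), t_n, L)
      if (!anyDuplicated(apply(pats, 1, paste0, collapse = ""))) break
    }
    f <- as.numeric(rmultinom(1, 40, rep(1 / t_n, t_n)) + 1); f <- f / sum(f)
    blk <- block_from_patterns(pats, f)
    N <- sample(3:8, 1)
    # plant an unseen pattern
    repeat {
      novel <- rbinom(L, 1, 0.4)
      if (!(paste0(novel, collapse = "") %in%
            apply(pats, 1, paste0, collapse = ""))) break
    }
    k_true <- sample(1:3, 1)
    counts <- as.integer(rmultinom(1, 2 * N - k_true, f))
    db <- genome_db(N, rbind(pats, novel), c(counts, k_true))
    ft <- summarize_database(db, blk)
    if (enumerate_solutions(build_constraints(blk, ft))$outcome != "none")
      next  # pattern absorbed by the knowns: nothing novel to find
    sol <- reconstruct_novel(blk, ft, d_max = 1)
    oracle <- brute_novel_d1(t(pats), ft$counts, 2 * N, pats)
    expect_true(sol$feasible)
    expect_false(is.null(oracle))
    expect_equal(sol$counts[1], oracle$k)        # smallest feasible count
    expect_equal(sol$objective, oracle$obj)      # minimum minor alleles
    expect_equal(unname(sol$z[1, ]), unname(oracle$z))  # lexicographic tie
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 10L)
})

test_that("reconstructed patterns are always distinct from the known panel", {
  for (r in 1:15) {
    set.seed(8800 + r)
    t_n <- 3L; L <- 5L
    repeat {
      pats <- matrix(rbinom(t_n * L, 1, 0.4), t_n, L)
      if (!anyDuplicated(apply(pats, 1, paste0, collapse = ""))) break
    }
    f <- c(0.5, 0.3, 0.2)
    blk <- block_from_patterns(pats, f)
    db <- sample_database(blk, 6, seed = 8900 + r)
    ft <- summarize_database(db, blk)
    # the table is consistent with the knowns; a forced novel search must
    # never return one of the known patterns
    sol <- reconstruct_novel(blk, ft, d_max = 1)
    if (sol$feasible)
      expect_false(paste0(sol$z[1, ], collapse = "") %in%
                     apply(pats, 1, paste0, collapse = ""))
  }
})

# two known haplotypes on disjoint site pairs plus two novel haplotypes on
# the remaining sites with different counts: no single novel haplotype can
# explain the residuals (1, 1, 2, 2), so the search must raise d to 2
two_novel_fixture <- function() {
  pats <- rbind(a = c(1L, 0L, 0L, 0L, 0L, 0L),
                b = c(0L, 1L, 0L, 0L, 0L, 0L))
  blk <- block_from_patterns(pats, c(0.6, 0.4))
  nov <- rbind(c(0L, 0L, 1L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L, 1L, 1L))
  db <- genome_db(5, rbind(pats, n1 = nov[1, ], n2 = nov[2, ]),
                  c(3L, 4L, 1L, 2L))
  list(blk = blk, nov = nov, ft = summarize_database(db, blk))
}

test_that("two planted novel haplotypes are recovered at d = 2", {
  fx <- two_novel_fixture()
  sol <- reconstruct_novel(fx$blk, fx$ft, d_max = 2)
  expect_true(sol$feasible)
  expect_equal(sol$d, 2L)
  got <- sort(apply(sol$z, 1, paste0, collapse = ""))
  expect_equal(got, sort(apply(fx$nov, 1, paste0, collapse = "")))
  recon <- as.integer(t(fx$blk$patterns) %*% sol$n +
                        t(sol$z) %*% sol$counts)
  expect_identical(recon, fx$ft$counts)
})

test_that("a not-found search returns a result object, not an error", {
  fx <- two_novel_fixture()
  sol <- reconstruct_novel(fx$blk, fx$ft, d_max = 1)  # needs d = 2
  expect_false(sol$feasible)
  expect_error(validate_novel(fx$blk, fx$ft, sol), "not-found")
})

test_that("validation reruns the frequency test on the augmented panel", {
  cfg <- sim_config(L = 12, t = 6, N = 100, seed = 55)
  blk <- generate_block(cfg, "V", seed = 55)
  rare <- rownames(blk$patterns)[which.min(blk$frequencies)]
  db <- set_haplotype_count(sample_database(blk, 100, seed = 56), rare, 10L)
  held <- drop_haplotype(blk, rare)
  ft <- summarize_database(db, blk)
  sol <- reconstruct_novel(held$block, ft, d_max = 1)
  expect_true(sol$feasible)
  nd <- null_dist(c(0.5, 1, 5, Inf, Inf))
  val <- validate_novel(held$block, ft, sol, null_dist = nd, alpha = 0.05)
  expect_length(val$results, 1L)
  r <- val$results[[1]]
  expect_equal(r$posterior, 1)       # planted pattern, unique completion
  expect_equal(r$p_value, 1 / 6)
  expect_lt(r$prior, 0.1)            # one pseudo-observation prior is small
})

test_that("patterns one flip away from a common haplotype are flagged", {
  blk <- toy_block()
  flip1 <- blk$patterns[1, ]; flip1[2] <- 1L   # 1111: one SNV from x1
  db <- genome_db(4, rbind(blk$patterns, nv = flip1), c(3L, 2L, 1L, 2L))
  ft <- summarize_database(db, blk)
  sol <- reconstruct_novel(blk, ft, d_max = 1)
  expect_true(sol$feasible)
  val <- validate_novel(blk, ft, sol, alpha = 0.05)
  if (identical(unname(sol$z[1, ]), unname(flip1)))
    expect_true(val$artifact_flags[1])
})
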