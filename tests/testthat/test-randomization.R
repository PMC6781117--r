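# a small two-pond design with named candidates
toy_design <- function(nf = c(3, 2), nm = c(2, 3), n_pairs = c(3, 2)) {
  tibble::tibble(
    pond = c("A", "B")[seq_along(nf)],
    n_pairs = n_pairs,
    females = lapply(seq_along(nf), function(p)
      sprintf("F%s%d", c("A", "B")[p], seq_len(nf[p]))),
    males = lapply(seq_along(nm), function(p)
      sprintf("M%s%d", c("A", "B")[p], seq_len(nm[p]))))
}

test_that("null pair sampling respects the stratified design", {
  d <- toy_design()
  rep1 <- sample_null_pairs(d, seed = 5, replicate = 1)
  expect_equal(nrow(rep1), 5)
  expect_equal(sum(rep1$pond == "A"), 3)
  expect_true(all(grepl("^FA", rep1$female_id[rep1$pond == "A"])))
  expect_true(all(grepl("^MB", rep1$male_id[rep1$pond == "B"])))

  # same (design, seed, replicate) triple reproduces exactly
  expect_identical(rep1, sample_null_pairs(d, seed = 5, replicate = 1))
  # and replicate 3 is the same whether or not replicates 4+ are ever drawn
  expect_identical(sample_null_pairs(d, seed = 5, replicate = 3),
                   sample_null_pairs(d, seed = 5, replicate = 3))

  # a 1-female/1-male pond can only repeat its single pair
  d1 <- toy_design(nf = c(1), nm = c(1), n_pairs = c(2))
  r <- sample_null_pairs(d1, seed = 1)
  expect_equal(nrow(r), 2)
  expect_equal(unique(r$female_id), "FA1")
  expect_equal(unique(r$male_id), "MA1")

  # a pond with pairs but no males errors at design construction
  loci <- ms_loci(1)
  ind <- make_inds(list(F1 = list(L1 = c(100, 102)),
                        F2 = list(L1 = c(100, 100))), loci,
                   sex = c("female", "female"))
  pr <- tibble::tibble(female_id = "F1", male_id = "F2", pond = "A",
                       n_offspring = 1)
  expect_error(stratified_design(pr, ind), "no candidate")
})

test_that("empirical p-values and CI rule behave on engineered nulls", {
  d <- toy_design()
  mats_const <- lapply(setNames(d$pond, d$pond), function(p) {
    i <- match(p, d$pond)
    matrix(7, length(d$females[[i]]), length(d$males[[i]]),
           dimnames = list(d$females[[i]], d$males[[i]]))
  })
  res <- randomize_statistic(d, mats_const, observed = 7, mode = "pair",
                             n_iter = 199, seed = 1)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_true(all(res$null[[1]] == 7))

  # observed beyond every null mean: p = 2 * 1 / (n_iter + 1)
  withr::with_seed(2, {
    mats_rand <- lapply(setNames(d$pond, d$pond), function(p) {
      i <- match(p, d$pond)
      matrix(runif(length(d$females[[i]]) * length(d$males[[i]])),
             length(d$females[[i]]), length(d$males[[i]]),
             dimnames = list(d$females[[i]], d$males[[i]]))
    })
  })
  res2 <- randomize_statistic(d, mats_rand, observed = 99, mode = "pair",
                              n_iter = 999, seed = 3)
  expect_equal(res2$p_value, 2 / 1000)
  expect_true(res2$significant)

  # two-tailed symmetry: p(obs; null) = p(-obs; -null)
  neg <- lapply(mats_rand, function(m) -m)
  a <- randomize_statistic(d, mats_rand, observed = 0.7, mode = "pair",
                           n_iter = 499, seed = 11)
  b <- randomize_statistic(d, neg, observed = -0.7, mode = "pair",
                           n_iter = 499, seed = 11)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$null[[1]], -b$null[[1]], tolerance = 1e-12)
})

test_that("null mean converges to the exact enumeration on a toy problem", {
  d <- toy_design(nf = c(3, 2), nm = c(3, 2), n_pairs = c(4, 2))
  withr::with_seed(9, {
    mats <- lapply(setNames(d$pond, d$pond), function(p) {
      i <- match(p, d$pond)
      matrix(rnorm(length(d$females[[i]]) * length(d$males[[i]])),
             length(d$females[[i]]), length(d$males[[i]]),
             dimnames = list(d$females[[i]], d$males[[i]]))
    })
  })
  exact <- expected_null_mean(d, mats, mode = "pair")
  res <- randomize_statistic(d, mats, observed = exact, mode = "pair",
                             n_iter = 4999, seed = 21)
  null <- res$null[[1]]
  mc_se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - exact), 3 * mc_se)
})

test_that("undefined statistic values follow the declared policy", {
  d <- toy_design(nf = c(2), nm = c(2), n_pairs = c(3))
  m <- matrix(c(1, NA, 2, 3), 2, 2,
              dimnames = list(d$females[[1]], d$males[[1]]))
  res <- randomize_statistic(d, list(A = m), observed = 2, mode = "pair",
                             n_iter = 99, seed = 2)
  expect_gt(res$n_dropped, 0)
  expect_true(all(is.finite(res$null[[1]])))
  expect_error(
    randomize_statistic(d, list(A = m), observed = 2, mode = "pair",
                        n_iter = 99, seed = 2, na_policy = "abort"),
    "undefined")
})

test_that("male and unique-male modes weight males as documented", {
  d <- toy_design(nf = c(2), nm = c(2), n_pairs = c(2))
  v <- list(A = setNames(c(0, 1), d$males[[1]]))
  res <- randomize_statistic(d, v, observed = 0.5, mode = "male",
                             n_iter = 2999, seed = 4)
  # pair-weighted male mean: expectation 0.5, lattice {0, .5, 1}
  expect_true(all(res$null[[1]] %in% c(0, 0.5, 1)))
  expect_equal(mean(res$null[[1]]), 0.5, tolerance = 0.03)

  # unique-male replicates average each drawn male once
  res_u <- randomize_statistic(d, v, observed = 0.5, mode = "unique-male",
                               n_iter = 2999, seed = 4)
  # drawing both males gives 0.5; drawing one twice gives 0 or 1
  expect_true(all(res_u$null[[1]] %in% c(0, 0.5, 1)))
  # P(same male twice) = 0.5 -> mean share of 0.5-replicates is about half
  expect_equal(mean(res_u$null[[1]] == 0.5), 0.5, tolerance = 0.05)
})

test_that("the full suite is reproducible byte for byte", {
  ds <- simulate_alligator_dataset(sim_config(
    seed = 77, ponds = tibble::tibble(pond = c("A", "B"),
                                      n_females = c(12L, 10L),
                                      n_males = c(6L, 5L)),
    n_clutches = 18L, make_offspring = FALSE))
  s1 <- run_mate_choice_suite(ds$individuals, ds$loci, ds$pairs, ds$alleles,
                              n_iter = 199, seed = 13)
  s2 <- run_mate_choice_suite(ds$individuals, ds$loci, ds$pairs, ds$alleles,
                              n_iter = 199, seed = 13)
  expect_identical(s1, s2)
  # all eight statistic families are present
  expect_setequal(unique(s1$statistic),
                  c("af", "d2", "sh", "ho", "aa_dist", "aa_func_dist",
                    "nsa", "r_qg"))
  # per-locus statistics appear once per MHC locus
  expect_equal(sum(s1$statistic == "nsa"), 2)
  expect_true(all(s1$p_value > 0 & s1$p_value <= 1))
  expect_true(all(s1$ci_lower <= s1$ci_upper))
})
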