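test_that("Brownie-to-Seber conversion and its inverse", {
  expect_equal(r_from_f(0.02, 0.90), 0.20)
  expect_equal(r_from_f(0, 0.5), 0)
  set.seed(11)
  for (i in 1:20) {
    S <- runif(1, 0, 0.99); r <- runif(1)
    expect_equal(r_from_f((1 - S) * r, S), r, tolerance = 1e-12)
  }
  expect_error(r_from_f(0.02, 1), "undefined")
  expect_error(r_from_f(0.3, 0.9), "1 - S")
})

test_that("m-array bookkeeping from encounter histories", {
  # one animal marked at occasion 1, recovered at occasion 3 (death interval 2)
  sym <- matrix(c(1L, 0L, 2L, 0L), 1)
  h <- encounter_histories(sym, 1L)
  ma <- build_marray(h)
  expect_equal(ma$releases, c(1, 0, 0, 0))
  expect_equal(ma$recoveries[1, 2], 1)
  expect_equal(sum(ma$recoveries), 1)
  expect_equal(ma$never_recovered[1], 0)
  # a cohort never recovered is all remainder
  sym2 <- matrix(rep(c(1L, 0L, 0L, 0L), each = 100), 100)
  ma2 <- build_marray(encounter_histories(sym2, rep(1L, 100)))
  expect_equal(ma2$never_recovered[1], 100)
  expect_true(all(ma2$recoveries == 0))
  # releases always balance recoveries plus remainder
  d <- sim_design(n_new_per_year = 200, n_years = 6, seed = 13,
                  param_means = list(S = 0.8, F = 0.9, r = 0.3, p = 0.2))
  ma3 <- build_marray(simulate_histories(d)$histories)
  expect_equal(rowSums(ma3$recoveries) + ma3$never_recovered, ma3$releases,
               ignore_attr = TRUE)
  expect_error(marray(1, matrix(c(0, 1, 0, 0), 2, byrow = TRUE)),
               "one recovery row")
  expect_error(marray(c(1, 1), matrix(c(0, 0, 1, 0), 2, byrow = TRUE)),
               "before release")
})

test_that("recovery cell frequencies match the Seber cell probabilities", {
  S <- 0.9; r <- 0.2
  d <- sim_design(n_new_per_year = c(10000, rep(1, 4)), n_years = 5, seed = 17,
                  param_means = list(S = S, F = 0.9, r = r, p = 0.3),
                  param_sds = list(S = 0, F = 0, r = 0, p = 0))
  ap <- annual_params(S = rep(S, 4), F = rep(0.9, 4), r = rep(r, 4),
                      p = rep(0.3, 4))
  ma <- build_marray(simulate_histories(d, ap)$histories)
  R1 <- ma$releases[1]
  p11 <- (1 - S) * r                     # 0.02
  p12 <- S * (1 - S) * r                 # 0.018
  expect_lt(abs(ma$recoveries[1, 1] / R1 - p11),
            3 * sqrt(p11 * (1 - p11) / R1))
  expect_lt(abs(ma$recoveries[1, 2] / R1 - p12),
            3 * sqrt(p12 * (1 - p12) / R1))
})

test_that("m-array rows are normalized and the likelihood matches oracles", {
  set.seed(19)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    S <- runif(K, 0.05, 0.95); r <- runif(K, 0.05, 0.95)
    pr <- marray_cell_probs(S, r)
    expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(pr >= 0))
  }
  # single recovered animal
  expect_equal(marray_loglik(marray(1, matrix(1, 1, 1)), S = 0.9, r = 0.2),
               log(0.02))
  # no recoveries at all: remainder-only likelihood
  ma0 <- marray(c(10, 5), matrix(0, 2, 2))
  S <- c(0.8, 0.7); r <- c(0.3, 0.2)
  pr <- marray_cell_probs(S, r, J = 2)
  expect_equal(marray_loglik(ma0, S, r),
               unname(10 * log(pr[1, 3]) + 5 * log(pr[2, 3])))
  # 3-year toy: equals the per-individual enumeration of fates
  d <- sim_design(n_new_per_year = 15, n_years = 3, seed = 23,
                  param_means = list(S = 0.7, F = 0.8, r = 0.4, p = 0.3))
  sim <- simulate_histories(d)
  ap <- design_params(d)
  ma <- build_marray(sim$histories)
  h <- sim$histories
  per_ind <- sum(vapply(seq_len(nrow(h$symbols)), function(i) {
    rec <- which(h$symbols[i, ] == 2L)
    log(oracle_dr_individual(h$first_occasion[i],
                             if (length(rec)) rec else NA_integer_,
                             3L, ap$S, ap$r))
  }, numeric(1)))
  expect_equal(marray_loglik(ma, ap$S, ap$r), per_ind, tolerance = 1e-10)
})

test_that("the m-array is sufficient for a recovery-only observation model", {
  # with recapture switched off, the exact JE likelihood must coincide with
  # the multinomial m-array likelihood (coefficient omitted) for any S, r
  set.seed(29)
  for (i in 1:5) {
    d <- sim_design(n_new_per_year = 50, n_years = 5, seed = 100 + i,
                    param_means = list(S = 0.8, F = 0.7, r = 0.35, p = 0.3))
    sim <- simulate_histories(d)
    # strip live recaptures so the data are recovery-only
    sym <- sim$histories$symbols
    post <- col(sym) > sim$histories$first_occasion
    sym[post & sym == 1L] <- 0L
    h <- encounter_histories(sym, sim$histories$first_occasion)
    S <- runif(4, 0.2, 0.9); r <- runif(4, 0.1, 0.9); F <- runif(4)
    ap <- annual_params(S = S, F = F, r = r, p = rep(0, 4))
    expect_equal(dataset_loglik(h, ap),
                 marray_loglik(build_marray(h), S, r), tolerance = 1e-10)
  }
})

test_that("the m-array round-trips through CSV", {
  d <- sim_design(n_new_per_year = 100, n_years = 5, seed = 37,
                  param_means = list(S = 0.8, F = 0.9, r = 0.3, p = 0.2))
  ma <- build_marray(simulate_histories(d)$histories)
  path <- withr::local_tempfile(fileext = ".csv")
  write_marray(ma, path)
  back <- read_marray(path)
  expect_equal(back$releases, ma$releases)
  expect_equal(back$recoveries, ma$recoveries, ignore_attr = TRUE)
  expect_equal(back$never_recovered, ma$never_recovered)
})
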