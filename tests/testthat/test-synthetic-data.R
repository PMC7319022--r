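test_that("logit-normal annual draws respect mean, spread and seed", {
  # zero annual variation collapses to the mean exactly
  expect_equal(gen_annual_params(0.90, 0, 5), rep(0.90, 5))
  # reproducible under a fixed seed
  expect_identical(gen_annual_params(0.7, 0.05, 9, seed = 11),
                   gen_annual_params(0.7, 0.05, 9, seed = 11))
  # all draws are probabilities
  x <- gen_annual_params(0.5, 0.4, 1000, seed = 2)
  expect_true(all(x > 0 & x < 1))
  # delta-method SD convention: back-transformed draws recover the target
  # mean and probability-scale SD at large n
  y <- gen_annual_params(0.90, 0.02, 1e5, seed = 3)
  expect_lt(abs(mean(y) - 0.90), 0.01)
  expect_lt(abs(sd(y) - 0.02), 0.005)
  expect_error(gen_annual_params(1.2, 0.1, 5), "mean")
})

test_that("the canonical study vectors are served for every study cell", {
  ap <- reference_annual_params(r_mean = 0.10, p_mean = 0.01)
  expect_equal(ap$S, c(0.93, 0.88, 0.91, 0.74, 0.90, 0.86, 0.95, 0.90, 0.82))
  expect_equal(ap$F, c(0.84, 0.93, 0.65, 0.83, 0.72, 0.99, 0.90, 0.74, 0.89))
  expect_equal(ap$r, c(0.10, 0.06, 0.13, 0.09, 0.12, 0.13, 0.11, 0.08, 0.10))
  expect_equal(reference_annual_params(r_mean = 0.19)$r,
               c(0.22, 0.24, 0.17, 0.17, 0.20, 0.22, 0.20, 0.19, 0.14))
  expect_equal(reference_annual_params(p_mean = 0.9)$p,
               c(0.91, 0.94, 0.85, 0.84, 0.93, 0.92, 0.88, 0.92, 0.93))
  expect_equal(n_years(ap), 10L)
  expect_error(reference_annual_params(r_mean = 0.5), "r_mean")
  # the design round-trips through its YAML serialization
  d <- sim_design(n_new_per_year = 100, n_years = 10,
                  param_means = list(S = 0.9, F = 0.9, r = 0.19, p = 0.5),
                  seed = 42, use_reference_vectors = TRUE)
  path <- withr::local_tempfile(fileext = ".yml")
  write_sim_design(d, path)
  expect_equal(read_sim_design(path), d)
})

test_that("degenerate designs produce the deterministic histories", {
  # certain survival, fidelity and detection: seen alive at every occasion
  d <- sim_design(n_new_per_year = 25, n_years = 5, seed = 5)
  certain <- annual_params(S = rep(1, 4), F = rep(1, 4), r = rep(0.5, 4),
                           p = rep(1, 4))
  sim <- simulate_histories(d, certain)
  for (i in seq_len(nrow(sim$histories$symbols))) {
    f <- sim$histories$first_occasion[i]
    expect_true(all(sim$histories$symbols[i, f:5] == 1L))
  }
  # certain death and reporting: recovered dead in the first interval
  doomed <- annual_params(S = rep(0, 4), F = rep(0.5, 4), r = rep(1, 4),
                          p = rep(0.5, 4))
  sim2 <- simulate_histories(d, doomed)
  h <- sim2$histories
  for (i in seq_len(nrow(h$symbols))) {
    f <- h$first_occasion[i]
    if (f < 5L) expect_equal(h$symbols[i, f + 1L], 2L)
  }
  # the final cohort carries no post-marking records
  last <- h$first_occasion == 5L
  expect_true(all(is.na(h$symbols[last, 1:4])))
})

test_that("sampled trajectories never violate the structural zeros", {
  d <- sim_design(n_new_per_year = 400, n_years = 6, seed = 9,
                  param_means = list(S = 0.8, F = 0.7, r = 0.3, p = 0.5),
                  param_sds = list(S = 0.05, F = 0.05, r = 0.05, p = 0.05))
  sim <- simulate_histories(d)
  z <- sim$latent; y <- sim$histories$symbols
  for (t in 1:5) {
    a <- z[, t]; b <- z[, t + 1L]
    ok <- !is.na(a) & !is.na(b)
    expect_false(any(a[ok] == 2L & b[ok] == 1L))   # no return from outside
    expect_true(all(b[ok & a == 3L] == 4L))        # recently dead -> dead
    expect_true(all(b[ok & a == 4L] == 4L))        # dead is absorbing
  }
  # observation legality: seen alive only inside; recovered only recently dead
  post <- !is.na(y) & col(y) > sim$histories$first_occasion
  expect_true(all(z[post & y == 1L] == 1L))
  expect_true(all(z[post & y == 2L] == 3L))
  expect_true(all(z[post & y == 0L] != 3L))
  # reproducibility: identical design -> identical histories
  sim_b <- simulate_histories(d)
  expect_identical(sim$histories$symbols, sim_b$histories$symbols)
})

test_that("one-step empirical transition frequencies match the matrix", {
  S <- 0.85; F <- 0.75; r <- 0.25; p <- 0.5
  d <- sim_design(n_new_per_year = c(20000, 1, 1), n_years = 3, seed = 77,
                  param_means = list(S = S, F = F, r = r, p = p),
                  param_sds = list(S = 0, F = 0, r = 0, p = 0))
  sim <- simulate_histories(d, annual_params(S = rep(S, 2), F = rep(F, 2),
                                             r = rep(r, 2), p = rep(p, 2)))
  from_inside <- which(sim$latent[, 1] == 1L)
  nxt <- sim$latent[from_inside, 2]
  n <- length(from_inside)
  expected <- build_transition_matrix(S, F, r)["alive_inside", ]
  emp <- tabulate(nxt, 4) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(emp - expected) <= 3 * se + 1e-12))
  # recovery frequency in the first interval ~ (1 - S) * r
  rec <- mean(sim$histories$symbols[from_inside, 2] == 2L)
  pe <- (1 - S) * r
  expect_lt(abs(rec - pe), 3 * sqrt(pe * (1 - pe) / n))
})

test_that("histories survive CSV and LD round trips", {
  d <- sim_design(n_new_per_year = 40, n_years = 6, seed = 21,
                  param_means = list(S = 0.85, F = 0.8, r = 0.3, p = 0.4))
  sim <- simulate_histories(d)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histories(sim$histories, path)
  back <- read_histories(path)
  expect_equal(back$symbols, sim$histories$symbols,
               ignore_attr = TRUE)
  expect_equal(back$first_occasion, sim$histories$first_occasion)
  ld <- to_ld_strings(sim$histories)
  expect_true(all(nchar(ld) == 12L))
  back2 <- from_ld_strings(ld, sim$histories$first_occasion)
  expect_equal(back2$symbols, sim$histories$symbols, ignore_attr = TRUE)
  # pooling conserves individuals and collapses duplicates
  pooled <- pool_histories(sim$histories)
  expect_equal(sum(pooled$multiplicity), sum(sim$histories$multiplicity))
  expect_lte(nrow(pooled$symbols), nrow(sim$histories$symbols))
})
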