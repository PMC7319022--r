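test_that("transition and observation matrices carry the model structure", {
  m <- build_transition_matrix(0.90, 0.90, 0.10)
  expect_equal(unname(m["alive_inside", ]), c(0.81, 0.09, 0.01, 0.09))
  expect_equal(unname(m["alive_outside", ]), c(0, 0.90, 0.01, 0.09))
  expect_equal(unname(m["recently_dead", ]), c(0, 0, 0, 1))
  expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  # no-mortality limit
  m1 <- build_transition_matrix(1, 0.7, 0.3)
  expect_equal(unname(m1["alive_inside", ]), c(0.7, 0.3, 0, 0))
  # rows are stochastic for arbitrary parameters
  for (i in 1:20) {
    m2 <- build_transition_matrix(runif(1), runif(1), runif(1))
    expect_equal(rowSums(m2), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  }
  o <- build_observation_matrix(0.5)
  expect_equal(unname(o["alive_inside", ]), c(0.5, 0, 0.5))
  expect_equal(unname(o["recently_dead", ]), c(0, 1, 0))
  expect_equal(unname(o["alive_outside", ]), c(0, 0, 1))
  expect_equal(unname(o["dead", ]), c(0, 0, 1))
  expect_equal(unname(build_observation_matrix(0)["alive_inside", ]),
               c(0, 0, 1))
  expect_error(build_transition_matrix(1.2, 0.5, 0.5), "probabilit")
  expect_error(build_observation_matrix(-0.1), "probabilit")
})

test_that("single-history likelihoods match closed forms", {
  ap <- annual_params(S = 0.9, F = 0.9, r = 0.1, p = 0.5)
  # marked at the final occasion: no information
  expect_equal(history_loglik(list(first_occasion = 2, symbols = c(NA, 1)), ap), 0)
  # recovered dead in the first interval: (1 - S) * r
  expect_equal(history_loglik(list(first_occasion = 1, symbols = c(1, 2)), ap),
               log(0.01))
  # not seen at occasion 2: inside & missed, emigrated, or died unreported
  expect_equal(history_loglik(list(first_occasion = 1, symbols = c(1, 0)), ap),
               log(0.9 * 0.9 * 0.5 + 0.9 * 0.1 + 0.1 * 0.9))
  # illegal histories are a validation error, not -Inf
  expect_error(history_loglik(list(first_occasion = 1, symbols = c(1, 2, 1)), ap),
               "after the dead recovery")
  expect_error(history_loglik(list(first_occasion = 1, symbols = c(0, 1)), ap),
               "seen alive")
})

test_that("forward likelihood equals latent-path enumeration", {
  set.seed(401)
  for (rep in 1:40) {
    T_ <- sample(2:5, 1)
    ap <- random_params(T_)
    f <- sample(seq_len(T_ - 1L), 1)
    tail <- legal_symbol_tails(T_ - f)
    sym <- rep(NA_integer_, T_)
    sym[f] <- 1L
    sym[(f + 1):T_] <- tail[sample(nrow(tail), 1), ]
    lik <- oracle_history_lik(f, sym, ap$S, ap$F, ap$r, ap$p)
    expect_equal(history_loglik(list(first_occasion = f, symbols = sym), ap),
                 log(lik), tolerance = 1e-10)
  }
})

test_that("likelihood is normalized over the observable history space", {
  set.seed(402)
  for (rep in 1:5) {
    T_ <- 4
    ap <- random_params(T_)
    for (f in 1:3) {
      tails <- legal_symbol_tails(T_ - f)
      tot <- sum(apply(tails, 1, function(s) {
        sym <- rep(NA_integer_, T_)
        sym[f] <- 1L
        sym[(f + 1):T_] <- s
        exp(history_loglik(list(first_occasion = f, symbols = sym), ap))
      }))
      expect_equal(tot, 1, tolerance = 1e-10)
    }
  }
})

test_that("a long unobserved history is non-increasing in recapture", {
  sym <- c(1L, rep(0L, 5))
  ps <- seq(0.01, 0.99, length.out = 25)
  ll <- vapply(ps, function(p) {
    ap <- annual_params(S = rep(0.9, 5), F = rep(0.8, 5), r = rep(0.1, 5),
                        p = rep(p, 5))
    history_loglik(list(first_occasion = 1, symbols = sym), ap)
  }, numeric(1))
  expect_true(all(diff(ll) <= 1e-12))
})

test_that("dataset likelihood is the multiplicity-weighted sum", {
  set.seed(403)
  d <- sim_design(n_new_per_year = 60, n_years = 5, seed = 31,
                  param_means = list(S = 0.85, F = 0.8, r = 0.25, p = 0.45))
  sim <- simulate_histories(d)
  ap <- design_params(d)
  h <- sim$histories
  # pooling changes nothing but runtime
  expect_equal(dataset_loglik(pool_histories(h), ap), dataset_loglik(h, ap),
               tolerance = 1e-10)
  # duplicating via multiplicity equals listing twice
  one <- encounter_histories(h$symbols[3, , drop = FALSE], h$first_occasion[3])
  two <- encounter_histories(h$symbols[c(3, 3), ], h$first_occasion[c(3, 3)])
  dup <- encounter_histories(h$symbols[3, , drop = FALSE], h$first_occasion[3],
                             multiplicity = 2)
  expect_equal(dataset_loglik(dup, ap), dataset_loglik(two, ap),
               tolerance = 1e-12)
  expect_equal(dataset_loglik(dup, ap), 2 * dataset_loglik(one, ap),
               tolerance = 1e-12)
  # the unpooled sum equals per-history evaluation
  per <- sum(vapply(seq_len(nrow(h$symbols)), function(i) {
    history_loglik(list(first_occasion = h$first_occasion[i],
                        symbols = h$symbols[i, ]), ap)
  }, numeric(1)))
  expect_equal(dataset_loglik(h, ap), per, tolerance = 1e-10)
  # empty collections are a warning, not an error
  empty <- encounter_histories(matrix(integer(0), 0, 5), integer(0),
                               numeric(0))
  expect_warning(ll0 <- dataset_loglik(empty, ap), "empty")
  expect_equal(ll0, 0)
  # a tiny dataset matches the full joint enumeration product
  small <- encounter_histories(h$symbols[1:5, ], h$first_occasion[1:5])
  joint <- sum(log(vapply(1:5, function(i) {
    oracle_history_lik(small$first_occasion[i], small$symbols[i, ],
                       ap$S, ap$F, ap$r, ap$p)
  }, numeric(1))))
  expect_equal(dataset_loglik(small, ap), joint, tolerance = 1e-10)
})
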