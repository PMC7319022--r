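#' Prior specification
#'
#' Priors for the Bayesian fits: an independent uniform prior on the grand
#' mean (probability scale) of each parameter family, and a uniform prior on
#' the logit-scale random-effect SD `sigma` of each family. Year-specific
#' values are modeled as `logit(theta_t) = logit(mu) + eps_t` with
#' `eps_t ~ N(0, sigma^2)`.
#'
#' @param S,F,r,p length-2 vectors `c(lower, upper)` bounding the mean of
#'   each family on the probability scale.
#' @param sigma_upper upper bound of the `U(0, sigma_upper)` prior on each
#'   family's logit-scale SD.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()                                  # minimally informative
#' prior_spec(S = c(0.5, 1), F = c(0.5, 1),      # informed case-study priors
#'            p = c(0, 0.3), r = c(0, 0.5))
#' @export
prior_spec <- function(S = c(0, 1), F = c(0, 1), r = c(0, 1), p = c(0, 1),
                       sigma_upper = 2) {
  bounds <- list(S = S, F = F, r = r, p = p)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] < 0 || b[2] > 1 || b[1] >= b[2]) {
      stop("bounds for ", nm, " must satisfy 0 <= lower < upper <= 1")
    }
  }
  if (sigma_upper <= 0) stop("sigma_upper must be > 0")
  structure(list(mean_bounds = bounds, sigma_upper = sigma_upper),
            class = "prior_spec")
}

#' MCMC settings and named presets
#'
#' @param n_chains number of chains (>= 2 so that R-hat is defined).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations (< `n_iter`); proposal scales adapt
#'   only during burn-in, so the retained chain is a fixed Markov kernel.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer seed; identical settings and seed give bit-identical
#'   draws.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 40000, n_burnin = 20000,
                          thin = 10, seed = 1L) {
  if (n_chains < 2) stop("n_chains must be >= 2 for R-hat")
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @param name preset name. `"default"` is the standard production run
#'   (3 x 40,000, burn-in 20,000, thin 10); `"fast"` (3 x 4,000, burn-in
#'   2,000, thin 2) is for quick studies and continuous testing and does not
#'   match production precision; the `"long-*"` presets are the heavier
#'   schedules needed for the hardest low-information study cells; the
#'   `"case-*"` presets are the case-study schedules.
#' @export
mcmc_preset <- function(name = c("default", "fast", "long-r10-p01",
                                 "long-r10-p20", "long-r10-p50",
                                 "long-r10-p90", "case-je", "case-dr"),
                        seed = 1L) {
  name <- match.arg(name)
  args <- switch(name,
    "default"      = list(40000L, 20000L, 10L),
    "fast"         = list(4000L, 2000L, 2L),
    "long-r10-p01" = list(500000L, 100000L, 10L),
    "long-r10-p20" = list(600000L, 550000L, 10L),
    "long-r10-p50" = list(400000L, 350000L, 10L),
    "long-r10-p90" = list(150000L, 100000L, 10L),
    "case-je"      = list(80000L, 40000L, 10L),
    "case-dr"      = list(50000L, 25000L, 10L))
  mcmc_settings(n_chains = 3, n_iter = args[[1]], n_burnin = args[[2]],
                thin = args[[3]], seed = seed)
}

#' Gelman-Rubin potential scale reduction factor (rank-normalized, split)
#'
#' Each chain is split in half, all draws are rank-normalized jointly
#' (normal scores), and the classic between/within variance-ratio statistic
#' is computed on the normalized split chains. Values near 1 indicate the
#' chains have mixed; the conventional acceptance gate in this package is
#' `R-hat < 1.05`.
#'
#' @param chains a matrix (iterations x chains) or a list of equal-length
#'   numeric vectors, at least 2 chains of at least 10 draws.
#' @return The R-hat statistic (>= 1 up to numerical noise); exactly
#'   constant chains return 1 with a warning.
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  n <- nrow(chains); m <- ncol(chains)
  if (m < 2) stop("at least 2 chains are required")
  if (n < 10) stop("chains must have at least 10 draws")
  if (stats::var(as.vector(chains)) == 0) {
    warning("constant chains; R-hat defined as 1")
    return(1)
  }
  half <- n %/% 2L
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[(n - half + 1L):n, , drop = FALSE])
  rk <- matrix(rank(split, ties.method = "average"), nrow = half)
  z <- stats::qnorm((rk - 3 / 8) / (length(split) + 1 / 4))
  nn <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) {
    warning("zero within-chain variance after rank normalization; R-hat defined as 1")
    return(1)
  }
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# ---- internal sampler machinery -------------------------------------------

# Index layout of the transformed parameter vector for a set of families,
# each with K random effects: per family (u, v, eps_1..eps_K) where
# mu = a + (b-a) * plogis(u), sigma = sigma_upper * plogis(v).
.par_layout <- function(families, K) {
  off <- 0L
  idx <- list()
  for (f in families) {
    idx[[f]] <- list(u = off + 1L, v = off + 2L, eps = off + 2L + seq_len(K))
    off <- off + 2L + K
  }
  list(idx = idx, n_par = off, K = K, families = families)
}

# Transformed vector -> list of natural-scale family parameters
.unpack <- function(x, layout, priors) {
  out <- list()
  for (f in layout$families) {
    ix <- layout$idx[[f]]
    b <- priors$mean_bounds[[f]]
    mu <- b[1] + (b[2] - b[1]) * stats::plogis(x[ix$u])
    sigma <- priors$sigma_upper * stats::plogis(x[ix$v])
    theta <- stats::plogis(stats::qlogis(mu) + x[ix$eps])
    out[[f]] <- list(mu = mu, sigma = sigma, theta = theta)
  }
  out
}

# Shared driver: run compiled adaptive Metropolis-within-Gibbs chains and
# assemble monitored natural-scale draws. model_type: 0 prior-only, 1 JE
# (data: sym/first/mult), 2 DR (data: counts). Chains are seeded from the
# settings seed, and initial points are drawn from the priors (random-effect
# scale capped at 0.5), re-drawn up to 25 times if the posterior is
# non-finite at the start.
.sample_model <- function(model_type, data, layout, priors, settings) {
  fams <- layout$families
  K <- layout$K
  lo <- vapply(fams, function(f) priors$mean_bounds[[f]][1], numeric(1))
  wd <- vapply(fams, function(f) diff(priors$mean_bounds[[f]]), numeric(1))
  init <- function() {
    x <- numeric(layout$n_par)
    for (f in fams) {
      ix <- layout$idx[[f]]
      x[ix$u] <- stats::rlogis(1)
      x[ix$v] <- stats::rlogis(1)
      sigma <- priors$sigma_upper * stats::plogis(x[ix$v])
      x[ix$eps] <- stats::rnorm(K, 0, min(sigma, 0.5))
    }
    x
  }
  set.seed(settings$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, settings$n_chains)
  raw <- lapply(seq_len(settings$n_chains), function(cc) {
    set.seed(chain_seeds[cc])
    for (try in 1:25) {
      out <- tryCatch(
        mwg_chain_cpp(model_type, data, length(fams), K, lo, wd,
                      priors$sigma_upper, settings$n_iter, settings$n_burnin,
                      settings$thin, init()),
        error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("could not find a finite-posterior initial point")
  })
  # monitored, natural-scale draws
  mon_names <- unlist(lapply(layout$families, function(f) {
    c(paste0("mu_", f), paste0("sigma_", f),
      paste0(f, "[", seq_len(layout$K), "]"))
  }))
  draws <- lapply(raw, function(mat) {
    out <- matrix(NA_real_, nrow(mat), length(mon_names),
                  dimnames = list(NULL, mon_names))
    for (i in seq_len(nrow(mat))) {
      th <- .unpack(mat[i, ], layout, priors)
      out[i, ] <- unlist(lapply(layout$families, function(f) {
        c(th[[f]]$mu, th[[f]]$sigma, th[[f]]$theta)
      }))
    }
    out
  })
  draws
}

.summarize_draws <- function(draws, families, K) {
  mon_names <- colnames(draws[[1]])
  all_mat <- do.call(rbind, draws)
  qs <- apply(all_mat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  rh <- vapply(mon_names, function(nm) {
    suppressWarnings(rhat(lapply(draws, function(d) d[, nm])))
  }, numeric(1))
  param <- sub("^(mu|sigma)_", "\\1_", sub("\\[.*", "", mon_names))
  year <- suppressWarnings(as.integer(sub("^.*\\[(\\d+)\\]$", "\\1", mon_names)))
  year[!grepl("\\[", mon_names)] <- NA_integer_
  data.frame(parameter = param, year = year,
             mean = colMeans(all_mat), sd = apply(all_mat, 2, stats::sd),
             q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
             rhat = rh, row.names = NULL, stringsAsFactors = FALSE)
}

.make_fit <- function(draws, layout, priors, settings, model) {
  summ <- .summarize_draws(draws, layout$families, layout$K)
  structure(list(draws = draws, summary = summ,
                 max_rhat = max(summ$rhat),
                 converged = max(summ$rhat) < 1.05,
                 families = layout$families, K = layout$K,
                 priors = priors, settings = settings, model = model),
            class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Bayesian ", toupper(x$model), " model fit: ",
      length(x$draws), " chains x ", nrow(x$draws[[1]]), " kept draws\n",
      sep = "")
  cat("  max R-hat = ", round(x$max_rhat, 4),
      if (x$converged) "  (converged)" else "  (NOT converged)", "\n", sep = "")
  hyper <- x$summary[is.na(x$summary$year), ]
  print(cbind(hyper[, c("parameter", "mean", "sd")],
              round(hyper[, c("q2.5", "q97.5", "rhat")], 4)),
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Fit the joint encounter model
#'
#' Samples the posterior of the multistate joint live-recapture/dead-recovery
#' model with logit-normal random time effects on all four parameter
#' families (S, F, r, p), using an adaptive random-walk Metropolis-within-
#' Gibbs sampler on the exact marginalized likelihood. Histories are pooled
#' before evaluation.
#'
#' @param histories an [encounter_histories] object, or `NULL` for a
#'   prior-only run (no likelihood contribution).
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()] or [mcmc_preset()].
#' @param n_occasions required when `histories` is `NULL`.
#' @return A `jm_fit` object: per-chain natural-scale draws of each family's
#'   grand mean `mu`, random-effect SD `sigma` and year-specific values,
#'   plus a summary table (posterior mean, SD, 2.5/50/97.5 percentiles and
#'   R-hat per quantity) and a convergence flag (`max R-hat < 1.05`).
#' @export
fit_je <- function(histories, priors = prior_spec(),
                   settings = mcmc_preset("fast"), n_occasions = NULL) {
  if (is.null(histories)) {
    if (is.null(n_occasions)) stop("n_occasions is required for a prior-only run")
    K <- n_occasions - 1L
    model_type <- 0L
    data <- list()
  } else {
    stopifnot(inherits(histories, "encounter_histories"))
    histories <- pool_histories(histories)
    K <- ncol(histories$symbols) - 1L
    sym <- histories$symbols
    sym[is.na(sym)] <- -1L
    model_type <- 1L
    data <- list(sym = sym, first = histories$first_occasion,
                 mult = histories$multiplicity)
  }
  layout <- .par_layout(c("S", "F", "r", "p"), K)
  draws <- .sample_model(model_type, data, layout, priors, settings)
  .make_fit(draws, layout, priors, settings, "je")
}

#' Fit the Seber dead-recovery model
#'
#' Samples the posterior of the m-array dead-recovery model (families S and
#' r only) with logit-normal random time effects, using the same sampler as
#' [fit_je()].
#'
#' @param marr an [marray] object, or `NULL` for a prior-only run.
#' @param priors a [prior_spec()] (the F and p bounds are unused).
#' @param settings an [mcmc_settings()].
#' @param n_intervals required when `marr` is `NULL`.
#' @return A `jm_fit` object (see [fit_je()]).
#' @export
fit_dr <- function(marr, priors = prior_spec(),
                   settings = mcmc_preset("fast"), n_intervals = NULL) {
  if (is.null(marr)) {
    if (is.null(n_intervals)) stop("n_intervals is required for a prior-only run")
    K <- as.integer(n_intervals)
    model_type <- 0L
    data <- list()
  } else {
    stopifnot(inherits(marr, "marray"))
    K <- ncol(marr$recoveries)
    model_type <- 2L
    data <- list(counts = cbind(marr$recoveries, marr$never_recovered))
  }
  layout <- .par_layout(c("S", "r"), K)
  draws <- .sample_model(model_type, data, layout, priors, settings)
  .make_fit(draws, layout, priors, settings, "dr")
}

#' Sample a posterior for either model
#'
#' Thin dispatcher over [fit_je()] and [fit_dr()], for callers that select
#' the model by name.
#'
#' @param model `"je"` or `"dr"`.
#' @param data an [encounter_histories] (JE) or [marray] (DR) object; `NULL`
#'   for a prior-only run.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param ... passed through (`n_occasions` / `n_intervals` for prior-only
#'   runs).
#' @return A `jm_fit` object.
#' @export
sample_posterior <- function(model = c("je", "dr"), data, priors = prior_spec(),
                             settings = mcmc_preset("fast"), ...) {
  model <- match.arg(model)
  if (model == "je") fit_je(data, priors, settings, ...)
  else fit_dr(data, priors, settings, ...)
}

#' Refit until converged, doubling iterations
#'
#' Re-runs a fit with doubled iteration and burn-in counts (and a shifted
#' seed) while any monitored R-hat is at or above 1.05, up to `max_retries`
#' times.
#'
#' @param fit_fun function taking an [mcmc_settings()] and returning a
#'   `jm_fit`.
#' @param settings initial [mcmc_settings()].
#' @param max_retries maximum number of doublings.
#' @return The last `jm_fit` (check its `converged` flag).
#' @export
fit_until_converged <- function(fit_fun, settings, max_retries = 2) {
  fit <- fit_fun(settings)
  tries <- 0
  while (!fit$converged && tries < max_retries) {
    tries <- tries + 1
    settings <- mcmc_settings(n_chains = settings$n_chains,
                              n_iter = settings$n_iter * 2L,
                              n_burnin = settings$n_burnin * 2L,
                              thin = settings$thin,
                              seed = settings$seed + 1000L * tries)
    fit <- fit_fun(settings)
  }
  fit
}

#' Extract a monitored quantity's draws across chains
#'
#' @param fit a `jm_fit`.
#' @param name monitored column name, e.g. `"mu_S"` or `"F[3]"`.
#' @return Matrix of draws, iterations x chains.
#' @export
fit_draws <- function(fit, name) {
  stopifnot(inherits(fit, "jm_fit"))
  if (!name %in% colnames(fit$draws[[1]])) stop("unknown quantity: ", name)
  do.call(cbind, lapply(fit$draws, function(d) d[, name]))
}

#' Write posterior draws / summaries to text files
#'
#' Draws go to a long columnar CSV (`parameter, year, chain, iteration,
#' value`); summaries to a per-quantity CSV.
#'
#' @param fit a `jm_fit`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "jm_fit"))
  pieces <- lapply(seq_along(fit$draws), function(cc) {
    d <- fit$draws[[cc]]
    data.frame(parameter = rep(colnames(d), each = nrow(d)),
               chain = cc, iteration = seq_len(nrow(d)),
               value = as.vector(d))
  })
  long <- do.call(rbind, pieces)
  long$year <- suppressWarnings(as.integer(sub("^.*\\[(\\d+)\\]$", "\\1",
                                               long$parameter)))
  long$parameter <- sub("\\[.*", "", long$parameter)
  utils::write.csv(long[, c("parameter", "year", "chain", "iteration", "value")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_draws
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "jm_fit"))
  utils::write.csv(fit$summary, path, row.names = FALSE, na = "")
  invisible(path)
}
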