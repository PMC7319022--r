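#' State transition matrix of the joint encounter model
#'
#' Builds the 4x4 one-interval transition matrix over the latent states
#' `alive inside`, `alive outside`, `recently dead`, `dead`. An animal alive
#' inside the study area survives with probability `S` and then stays with
#' probability `F`; an animal alive outside survives with `S` but can never
#' return; a death in the interval is reported with probability `r`, placing
#' the animal in the transient `recently dead` state for exactly one
#' occasion, after which (or directly, if unreported) it is absorbed in
#' `dead`.
#'
#' @param S,F,r survival, fidelity and reported-mortality probabilities for
#'   one interval, each in `[0,1]`.
#' @return A 4x4 row-stochastic matrix with dimnames.
#' @examples
#' build_transition_matrix(0.90, 0.90, 0.10)
#' @export
build_transition_matrix <- function(S, F, r) {
  for (v in c(S = S, F = F, r = r)) {
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      stop("S, F and r must be probabilities in [0,1]")
    }
  }
  states <- c("alive_inside", "alive_outside", "recently_dead", "dead")
  m <- matrix(c(
    S * F, S * (1 - F), (1 - S) * r, (1 - S) * (1 - r),
    0,     S,           (1 - S) * r, (1 - S) * (1 - r),
    0,     0,           0,           1,
    0,     0,           0,           1
  ), nrow = 4, byrow = TRUE, dimnames = list(states, states))
  m
}

#' Observation matrix of the joint encounter model
#'
#' Links the latent state at an occasion to the three observable symbols
#' `seen alive`, `recovered dead`, `not seen`. Only animals alive inside the
#' study area can be recaptured (with probability `p`); a recently dead
#' animal is, by construction of the latent process, one whose death was
#' reported, so it is recovered with certainty; animals alive outside or
#' long dead are never observed.
#'
#' @param p recapture probability at the occasion, in `[0,1]`.
#' @return A 4x3 row-stochastic matrix with dimnames.
#' @examples
#' build_observation_matrix(0.5)
#' @export
build_observation_matrix <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("p must be a probability in [0,1]")
  }
  states <- c("alive_inside", "alive_outside", "recently_dead", "dead")
  obs <- c("seen_alive", "recovered_dead", "not_seen")
  matrix(c(
    p, 0, 1 - p,
    0, 0, 1,
    0, 1, 0,
    0, 0, 1
  ), nrow = 4, byrow = TRUE, dimnames = list(states, obs))
}

.as_history_matrix <- function(history) {
  if (inherits(history, "encounter_histories")) return(history)
  if (is.list(history) && !is.null(history$symbols)) {
    sym <- matrix(as.integer(history$symbols), nrow = 1)
    return(encounter_histories(sym, history$first_occasion))
  }
  stop("history must be an encounter_histories object or a list with ",
       "symbols and first_occasion")
}

#' Marginal log-likelihood of one encounter history
#'
#' Evaluates `log P(symbols after marking | marked alive inside)` exactly,
#' by running the forward algorithm over the four latent states: the latent
#' trajectory is integrated out rather than sampled, so the value is the
#' exact marginal likelihood of the observed symbols. Conditioning is on the
#' first release, which is observed with certainty.
#'
#' @param history a single-row [encounter_histories] object, or a list with
#'   `first_occasion` and `symbols` (full-length symbol vector, `NA` before
#'   marking).
#' @param params an [annual_params] object spanning all occasions.
#' @return Log-probability (0 for an individual marked at the final occasion).
#' @examples
#' p <- annual_params(S = 0.9, F = 0.9, r = 0.1, p = 0.5)
#' history_loglik(list(first_occasion = 1, symbols = c(1, 2)), p)  # log(0.01)
#' @export
history_loglik <- function(history, params) {
  h <- .as_history_matrix(history)
  validate_histories(h)
  dataset_loglik(h, params, warn_empty = FALSE)
}

#' Marginal log-likelihood of a set of encounter histories
#'
#' Sum of multiplicity-weighted per-history log-likelihoods; individuals are
#' independent, so pooling identical histories changes runtime only.
#'
#' @param histories an [encounter_histories] object.
#' @param params an [annual_params] object spanning all occasions.
#' @param warn_empty warn (and return 0) on an empty collection.
#' @return Total log-probability of the data.
#' @export
dataset_loglik <- function(histories, params, warn_empty = TRUE) {
  stopifnot(inherits(histories, "encounter_histories"),
            inherits(params, "annual_params"))
  if (nrow(histories$symbols) == 0L) {
    if (warn_empty) warning("empty history collection; log-likelihood is 0")
    return(0)
  }
  if (ncol(histories$symbols) != n_years(params)) {
    stop("params span ", n_years(params), " occasions but histories have ",
         ncol(histories$symbols))
  }
  sym <- histories$symbols
  sym[is.na(sym)] <- -1L
  je_loglik_cpp(sym, histories$first_occasion, histories$multiplicity,
                params$S, params$F, params$r, params$p)
}
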