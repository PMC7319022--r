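#' Encounter histories
#'
#' A set of individual encounter histories: for each individual its marking
#' occasion and, from that occasion on, one observed symbol per occasion.
#' Symbols follow the usual joint live/dead coding:
#' `0` = not seen or recovered, `1` = seen alive, `2` = recovered dead.
#' Cells before the marking occasion are `NA`. Identical histories may be
#' pooled with a multiplicity weight, which changes runtime but never the
#' likelihood.
#'
#' @param symbols integer matrix, individuals x occasions, coded 0/1/2 with
#'   `NA` before each individual's marking occasion.
#' @param first_occasion integer vector of marking occasions (1-based).
#' @param multiplicity positive counts of identical histories (default 1).
#' @param validate check the structural legality of each history.
#' @return An object of class `encounter_histories`.
#' @export
encounter_histories <- function(symbols, first_occasion,
                                multiplicity = rep(1, nrow(symbols)),
                                validate = TRUE) {
  symbols <- as.matrix(symbols)
  storage.mode(symbols) <- "integer"
  first_occasion <- as.integer(first_occasion)
  if (nrow(symbols) != length(first_occasion)) {
    stop("one first_occasion per history row is required")
  }
  if (length(multiplicity) != nrow(symbols) || any(multiplicity < 1)) {
    stop("multiplicity must give a positive count per history")
  }
  h <- structure(
    list(symbols = symbols, first_occasion = first_occasion,
         multiplicity = as.numeric(multiplicity)),
    class = "encounter_histories"
  )
  if (validate) validate_histories(h)
  h
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("Encounter histories: ", sum(x$multiplicity), " individuals (",
      nrow(x$symbols), " distinct), ", ncol(x$symbols), " occasions\n",
      sep = "")
  cat("  recovered dead: ", sum(x$multiplicity[apply(x$symbols == 2L, 1,
                                                     any, na.rm = TRUE)]),
      "; ever recaptured: ",
      sum(x$multiplicity[rowSums(x$symbols == 1L, na.rm = TRUE) > 1L]),
      "\n", sep = "")
  invisible(x)
}

#' Validate the structural legality of encounter histories
#'
#' A legal history is observed `seen alive` at its marking occasion, has at
#' most one `recovered dead` symbol, and only `not seen` afterwards (the
#' dead state is absorbing and unobservable after the recovery occasion).
#'
#' @param h an [encounter_histories] object.
#' @return `h`, invisibly; throws a validation error otherwise.
#' @export
validate_histories <- function(h) {
  sym <- h$symbols
  T_ <- ncol(sym)
  if (any(h$first_occasion < 1L | h$first_occasion > T_)) {
    stop("first_occasion out of range")
  }
  for (i in seq_len(nrow(sym))) {
    f <- h$first_occasion[i]
    s <- sym[i, ]
    if (f > 1L && !all(is.na(s[seq_len(f - 1L)]))) {
      stop("history ", i, ": symbols present before the marking occasion")
    }
    s <- s[f:T_]
    if (anyNA(s)) stop("history ", i, ": NA symbol after marking")
    if (!all(s %in% 0:2)) stop("history ", i, ": symbols must be coded 0/1/2")
    if (s[1] != 1L) stop("history ", i, ": the marking occasion must be 'seen alive'")
    dead <- which(s == 2L)
    if (length(dead) > 1L) stop("history ", i, ": more than one dead recovery")
    if (length(dead) == 1L && dead < length(s) &&
        any(s[(dead + 1L):length(s)] != 0L)) {
      stop("history ", i, ": observations after the dead recovery")
    }
  }
  invisible(h)
}

#' Pool identical encounter histories
#'
#' Collapses identical (marking occasion, symbol sequence) rows into one row
#' with summed multiplicity. Pooling is what makes likelihood evaluation on
#' large banding data sets (tens of thousands of individuals, few distinct
#' observable patterns) tractable.
#'
#' @param h an [encounter_histories] object.
#' @return An [encounter_histories] object with distinct rows.
#' @export
pool_histories <- function(h) {
  stopifnot(inherits(h, "encounter_histories"))
  key <- paste(h$first_occasion,
               apply(h$symbols, 1, function(s) paste(ifelse(is.na(s), ".", s),
                                                     collapse = "")))
  idx <- split(seq_along(key), key)
  keep <- vapply(idx, `[`, integer(1), 1L)
  mult <- vapply(idx, function(i) sum(h$multiplicity[i]), numeric(1))
  o <- order(h$first_occasion[keep], keep)
  encounter_histories(h$symbols[keep[o], , drop = FALSE],
                      h$first_occasion[keep[o]], mult[o], validate = FALSE)
}

#' Simulate encounter histories from the four-state latent process
#'
#' New cohorts enter as `alive inside` at their marking occasion and evolve
#' through the latent states (alive inside / alive outside / recently dead /
#' dead) with the per-interval transition probabilities of
#' [build_transition_matrix()]; observations after marking follow
#' [build_observation_matrix()]. Deaths in interval `[t, t+1)` that are
#' reported appear as `recovered dead` at occasion `t+1`; the recently-dead
#' state lasts exactly one occasion. Individuals marked at the final
#' occasion carry no post-marking information.
#'
#' @param design a [sim_design()] object.
#' @param params an [annual_params] object consistent with the design; if
#'   missing, derived from the design via [design_params()].
#' @return A list with `histories` (unpooled [encounter_histories]),
#'   `latent` (individuals x occasions matrix of true state codes 1-4, NA
#'   before marking) and `params` (the generating [annual_params]).
#' @examples
#' d <- sim_design(n_new_per_year = 20, n_years = 5,
#'                 param_sds = list(S = 0, F = 0, r = 0, p = 0), seed = 7)
#' sim <- simulate_histories(d)
#' sim$histories
#' @export
simulate_histories <- function(design, params = design_params(design)) {
  stopifnot(inherits(design, "sim_design"), inherits(params, "annual_params"))
  T_ <- design$n_years
  if (n_years(params) != T_) stop("params span a different number of occasions")
  set.seed(design$seed)

  n_tot <- sum(design$n_new_per_year)
  first <- rep(seq_len(T_), design$n_new_per_year)
  z <- matrix(NA_integer_, n_tot, T_)
  y <- matrix(NA_integer_, n_tot, T_)
  z[cbind(seq_len(n_tot), first)] <- 1L  # marked alive inside the study area
  y[cbind(seq_len(n_tot), first)] <- 1L  # first encounter observed exactly

  for (t in seq_len(T_ - 1L)) {
    alive_idx <- which(first <= t & !is.na(z[, t]))
    if (!length(alive_idx)) next
    Om <- build_transition_matrix(params$S[t], params$F[t], params$r[t])
    cur <- z[alive_idx, t]
    u <- stats::runif(length(alive_idx))
    cum <- t(apply(Om, 1, cumsum))
    nxt <- 1L + rowSums(u > cum[cur, c(1, 2, 3), drop = FALSE])
    z[alive_idx, t + 1L] <- nxt
    # observation at occasion t+1 (recapture probability p for that occasion)
    p_t <- params$p[t]
    obs <- integer(length(alive_idx))
    obs[nxt == 1L] <- ifelse(stats::runif(sum(nxt == 1L)) < p_t, 1L, 0L)
    obs[nxt == 3L] <- 2L  # recently dead and reported -> recovered
    y[alive_idx, t + 1L] <- obs
  }

  list(histories = encounter_histories(y, first, validate = FALSE),
       latent = z, params = params)
}

#' Read and write encounter histories as CSV
#'
#' The on-disk layout has one row per individual: `id`, `cohort_year`
#' (marking occasion, 1-based), then one `occ_<t>` column per occasion coded
#' 0 = not seen, 1 = seen alive, 2 = recovered dead; cells before the
#' marking occasion are empty. `multiplicity`, when present, carries pooled
#' counts.
#'
#' @param h an [encounter_histories] object.
#' @param path file path.
#' @return `read_histories` returns an [encounter_histories] object.
#' @export
write_histories <- function(h, path) {
  stopifnot(inherits(h, "encounter_histories"))
  df <- data.frame(id = seq_len(nrow(h$symbols)),
                   cohort_year = h$first_occasion,
                   multiplicity = h$multiplicity)
  sym <- as.data.frame(h$symbols)
  names(sym) <- paste0("occ_", seq_len(ncol(sym)))
  utils::write.csv(cbind(df, sym), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_histories
#' @export
read_histories <- function(path) {
  df <- utils::read.csv(path)
  occ <- grep("^occ_", names(df))
  sym <- as.matrix(df[, occ, drop = FALSE])
  mult <- if ("multiplicity" %in% names(df)) df$multiplicity else rep(1, nrow(df))
  encounter_histories(sym, df$cohort_year, mult)
}

#' Convert encounter histories to and from LD strings
#'
#' The LD ("live/dead") encoding writes two digits per occasion: first the
#' live-capture indicator, then the dead-recovery indicator, concatenated
#' over occasions (the layout used by banding-analysis software for joint
#' data). Occasions before marking are `00`.
#'
#' @param h an [encounter_histories] object.
#' @param ld character vector of LD strings (even length, 2 x occasions).
#' @param first_occasion marking occasions; if missing, taken as the first
#'   occasion with a live capture.
#' @return `to_ld_strings` a character vector; `from_ld_strings` an
#'   [encounter_histories] object.
#' @export
to_ld_strings <- function(h) {
  stopifnot(inherits(h, "encounter_histories"))
  apply(h$symbols, 1, function(s) {
    s[is.na(s)] <- 0L
    paste0(ifelse(s == 1L, "1", "0"), ifelse(s == 2L, "1", "0"),
           collapse = "")
  })
}

#' @rdname to_ld_strings
#' @export
from_ld_strings <- function(ld, first_occasion = NULL) {
  T2 <- unique(nchar(ld))
  if (length(T2) != 1L || T2 %% 2L != 0L) {
    stop("all LD strings must share one even length")
  }
  T_ <- T2 %/% 2L
  dig <- matrix(as.integer(unlist(strsplit(ld, ""))), ncol = T2, byrow = TRUE)
  L <- dig[, seq(1, T2, by = 2), drop = FALSE]
  D <- dig[, seq(2, T2, by = 2), drop = FALSE]
  sym <- L + 2L * D
  if (any(sym > 2L)) stop("an occasion cannot be both live capture and dead recovery")
  if (is.null(first_occasion)) {
    first_occasion <- apply(L == 1L, 1, function(x) which(x)[1])
    if (anyNA(first_occasion)) stop("history without any live capture")
  }
  for (i in seq_len(nrow(sym))) {
    if (first_occasion[i] > 1L) sym[i, seq_len(first_occasion[i] - 1L)] <- NA_integer_
  }
  encounter_histories(sym, first_occasion)
}
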