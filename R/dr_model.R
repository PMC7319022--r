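#' Convert a Brownie recovery probability to reported mortality
#'
#' The Brownie recovery probability `f` is the unconditional probability
#' that a marked animal dies in an interval and is reported; the Seber
#' reported-mortality probability conditions on death: r = f/(1 - S).
#'
#' @param f Brownie recovery probability, with `0 <= f <= 1 - S`.
#' @param S survival probability, `< 1`.
#' @return Reported-mortality probability in `[0,1]`.
#' @examples
#' r_from_f(0.02, 0.90)  # 0.20
#' @export
r_from_f <- function(f, S) {
  if (any(S >= 1)) stop("r is undefined when S = 1 (no deaths to report)")
  if (any(f < 0) || any(f > 1 - S)) stop("f must satisfy 0 <= f <= 1 - S")
  f / (1 - S)
}

#' m-array of dead recoveries
#'
#' The sufficient statistic of the Seber dead-recovery model: per release
#' cohort `j`, the number released `R_j`, the counts `m[j, k]` first
#' reported dead in interval `k >= j`, and the never-recovered remainder.
#'
#' @param releases vector of cohort sizes `R_j`.
#' @param recoveries upper-triangular matrix of counts `m[j, k]` (release
#'   cohort x death interval).
#' @return An object of class `marray`.
#' @export
marray <- function(releases, recoveries) {
  recoveries <- as.matrix(recoveries)
  J <- length(releases)
  if (nrow(recoveries) != J) stop("one recovery row per release cohort")
  if (any(releases < 0) || any(recoveries < 0)) stop("counts must be >= 0")
  for (j in seq_len(J)) {
    if (j > 1L && any(recoveries[j, seq_len(j - 1L)] != 0)) {
      stop("recovery before release in cohort ", j)
    }
  }
  nr <- releases - rowSums(recoveries)
  if (any(nr < 0)) stop("more recoveries than releases in a cohort")
  structure(list(releases = as.numeric(releases), recoveries = recoveries,
                 never_recovered = as.numeric(nr)),
            class = "marray")
}

#' @export
print.marray <- function(x, ...) {
  cat("m-array: ", length(x$releases), " release cohorts, ",
      ncol(x$recoveries), " recovery intervals\n", sep = "")
  m <- cbind(released = x$releases, x$recoveries, never = x$never_recovered)
  print(m)
  invisible(x)
}

#' Summarize encounter histories into a dead-recovery m-array
#'
#' Each individual contributes to exactly one release cohort (its marking
#' occasion); live recaptures are ignored, since the dead-recovery model is
#' defined on first captures only. A recovery observed at occasion `t`
#' corresponds to a death in interval `t-1` and is attributed to m-array
#' column `t-1`.
#'
#' @param histories an [encounter_histories] object.
#' @return An [marray] with one row per marking occasion and one column per
#'   interval (`n_occasions - 1`).
#' @export
build_marray <- function(histories) {
  stopifnot(inherits(histories, "encounter_histories"))
  validate_histories(histories)
  T_ <- ncol(histories$symbols)
  J <- T_          # cohorts can be released at any occasion incl. the last
  K <- T_ - 1L
  rel <- numeric(J)
  m <- matrix(0, J, K,
              dimnames = list(paste0("rel_", seq_len(J)),
                              paste0("int_", seq_len(K))))
  for (i in seq_len(nrow(histories$symbols))) {
    f <- histories$first_occasion[i]
    w <- histories$multiplicity[i]
    rel[f] <- rel[f] + w
    rec <- which(histories$symbols[i, ] == 2L)
    if (length(rec)) m[f, rec - 1L] <- m[f, rec - 1L] + w
  }
  marray(rel, m)
}

#' Seber dead-recovery cell probabilities
#'
#' For a cohort released at occasion `j`, the probability of first being
#' reported dead in interval `k` is survival through intervals `j .. k-1`
#' times death in interval `k` times reporting:
#' `pi[j, k] = prod(S[j..(k-1)]) * (1 - S[k]) * r[k]`, with
#' `pi[j, j] = (1 - S[j]) * r[j]`. The remainder (never recovered within the
#' study) completes each row to 1.
#'
#' @param S,r per-interval survival and reported-mortality probabilities.
#' @param J number of release cohorts (default: all `length(S)` plus the
#'   final-occasion cohort, which has no exposure and an all-remainder row).
#' @return A `J x (K + 1)` matrix; the last column is the remainder.
#' @export
marray_cell_probs <- function(S, r, J = length(S) + 1L) {
  K <- length(S)
  if (length(r) != K) stop("S and r must have equal lengths")
  cp <- c(1, cumprod(S))           # cp[k] = prod(S[1..k-1])
  v <- cp[seq_len(K)] * (1 - S) * r
  pi <- outer(1 / cp[seq_len(J)], v)
  pi[col(pi) < row(pi)] <- 0
  cbind(pi, remainder = 1 - rowSums(pi))
}

#' Multinomial log-likelihood of an m-array under the Seber model
#'
#' Each release row is multinomial over the first-recovery intervals plus
#' the never-recovered remainder, with cell probabilities from
#' [marray_cell_probs()]. The multinomial coefficient is omitted, so the
#' value equals the product of independent per-individual outcome
#' probabilities exactly.
#'
#' @param marr an [marray] object.
#' @param S,r per-interval survival and reported-mortality probabilities
#'   spanning all intervals of the m-array.
#' @return Log-probability of the recovery table.
#' @examples
#' ma <- marray(1, matrix(1, 1, 1))
#' marray_loglik(ma, S = 0.9, r = 0.2)  # log(0.02)
#' @export
marray_loglik <- function(marr, S, r) {
  stopifnot(inherits(marr, "marray"))
  K <- ncol(marr$recoveries)
  if (length(S) < K) stop("params must span all intervals of the m-array")
  pr <- marray_cell_probs(S[seq_len(K)], r[seq_len(K)],
                          J = length(marr$releases))
  if (any(pr < -1e-12) || any(pr > 1 + 1e-12)) {
    stop("inconsistent cell probabilities")
  }
  counts <- cbind(marr$recoveries, marr$never_recovered)
  ll <- 0
  pos <- counts > 0
  ll <- sum(counts[pos] * log(pr[pos]))
  ll
}

#' Read and write an m-array as labeled CSV
#'
#' Layout: one row per release cohort with columns `cohort`, `released`,
#' one `int_<k>` column per recovery interval, and `never_recovered`.
#'
#' @param marr an [marray] object.
#' @param path file path.
#' @return `read_marray` returns an [marray] object.
#' @export
write_marray <- function(marr, path) {
  stopifnot(inherits(marr, "marray"))
  df <- data.frame(cohort = seq_along(marr$releases),
                   released = marr$releases)
  rec <- as.data.frame(marr$recoveries)
  names(rec) <- paste0("int_", seq_len(ncol(rec)))
  df <- cbind(df, rec, never_recovered = marr$never_recovered)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marray
#' @export
read_marray <- function(path) {
  df <- utils::read.csv(path)
  cols <- grep("^int_", names(df))
  marray(df$released, as.matrix(df[, cols, drop = FALSE]))
}
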