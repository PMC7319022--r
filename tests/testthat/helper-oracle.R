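# Independent brute-force oracles, written directly from the model
# definition (no shared code with the forward algorithm in src/).
#
# Latent states: 1 alive inside, 2 alive outside, 3 recently dead, 4 dead.
# Symbols: 0 not seen, 1 seen alive, 2 recovered dead.

oracle_transition <- function(S, F, r) {
  matrix(c(S * F, S * (1 - F), (1 - S) * r, (1 - S) * (1 - r),
           0,     S,           (1 - S) * r, (1 - S) * (1 - r),
           0,     0,           0,           1,
           0,     0,           0,           1),
         4, 4, byrow = TRUE)
}

oracle_obs_prob <- function(state, symbol, p) {
  if (state == 1) return(switch(symbol + 1L, 1 - p, p, 0))
  if (state == 2) return(switch(symbol + 1L, 1, 0, 0))
  if (state == 3) return(switch(symbol + 1L, 0, 0, 1))
  switch(symbol + 1L, 1, 0, 0)
}

# Exact likelihood of one history by summing over all 4^(T-f) latent paths.
oracle_history_lik <- function(first, symbols, S, F, r, p) {
  T_ <- length(symbols)
  if (first == T_) return(1)
  n_step <- T_ - first
  paths <- as.matrix(expand.grid(rep(list(1:4), n_step)))
  tot <- 0
  for (row in seq_len(nrow(paths))) {
    z <- c(1L, paths[row, ])
    pr <- 1
    for (k in 2:length(z)) {
      t_int <- first + k - 2L            # interval (t -> t+1), 1-based
      occ <- first + k - 1L              # occasion of the observation
      pr <- pr * oracle_transition(S[t_int], F[t_int], r[t_int])[z[k - 1], z[k]]
      pr <- pr * oracle_obs_prob(z[k], symbols[occ], p[occ - 1L])
      if (pr == 0) break
    }
    tot <- tot + pr
  }
  tot
}

# All structurally legal symbol sequences after marking: at most one dead
# recovery, nothing but "not seen" afterwards.
legal_symbol_tails <- function(n) {
  tails <- as.matrix(expand.grid(rep(list(0:2), n)))
  keep <- apply(tails, 1, function(s) {
    d <- which(s == 2L)
    length(d) <= 1L && (length(d) == 0L || d == n || all(s[(d + 1L):n] == 0L))
  })
  tails[keep, , drop = FALSE]
}

# A small random parameter set over T occasions (interior probabilities).
random_params <- function(T_, lo = 0.05, hi = 0.95) {
  k <- T_ - 1L
  annual_params(S = runif(k, lo, hi), F = runif(k, lo, hi),
                r = runif(k, lo, hi), p = runif(k, lo, hi))
}

# Per-individual dead-recovery outcome log-probability (for the m-array
# sufficiency check): death interval enumeration for an animal released at f.
oracle_dr_individual <- function(first, recovery_occasion, T_, S, r) {
  # recovery_occasion NA: never recovered within the study.
  if (!is.na(recovery_occasion)) {
    k <- recovery_occasion - 1L          # death interval
    pr <- 1
    if (k - 1L >= first) for (t in first:(k - 1L)) pr <- pr * S[t]
    pr * (1 - S[k]) * r[k]
  } else if (first >= T_) {
    1  # released at the final occasion: nothing observable
  } else {
    # sum over all unobserved fates: die unreported in some interval, or
    # survive (inside or outside) to the end of the study
    tot <- 0
    surv <- 1
    for (t in first:(T_ - 1L)) {
      tot <- tot + surv * (1 - S[t]) * (1 - r[t])
      surv <- surv * S[t]
    }
    tot + surv
  }
}
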