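# Independent oracles for the SOP recurrences, kept deliberately separate
# from the package's implementation: a scalar spreadsheet-style iteration of
# the deterministic proportions, and a per-element stochastic simulator.

# Scalar iteration for a single stimulus with no associative links.
# `present` is a 0/1 vector over moments. Returns a moments x 3 matrix.
oracle_single_stimulus <- function(present, intensity, pd1, pd2) {
  pI <- 1; pA1 <- 0; pA2 <- 0
  out <- matrix(NA_real_, length(present), 3,
                dimnames = list(NULL, c("pI", "pA1", "pA2")))
  for (m in seq_along(present)) {
    d1 <- pd1 * pA1
    d2 <- pd2 * pA2
    pA1 <- pA1 - d1
    pA2 <- pA2 + d1 - d2
    pI <- pI + d2
    if (present[m] == 1) {
      a <- intensity * pI
      pI <- pI - a
      pA1 <- pA1 + a
    }
    out[m, ] <- c(pI, pA1, pA2)
  }
  out
}

# Per-element stochastic simulator: n independent elements, same transition
# probabilities as the deterministic recurrence, applied per moment in the
# same sub-step order (decay decided from the pre-moment state, then
# activation of currently inactive elements).
oracle_stochastic_elements <- function(present, intensity, pd1, pd2,
                                       n_elements) {
  state <- rep(0L, n_elements)  # 0 = I, 1 = A1, 2 = A2
  out <- matrix(NA_real_, length(present), 3,
                dimnames = list(NULL, c("pI", "pA1", "pA2")))
  for (m in seq_along(present)) {
    u <- runif(n_elements)
    was_a1 <- state == 1L
    was_a2 <- state == 2L
    state[was_a1 & u < pd1] <- 2L
    state[was_a2 & u < pd2] <- 0L
    if (present[m] == 1) {
      inactive <- state == 0L
      act <- inactive & runif(n_elements) < intensity
      state[act] <- 1L
    }
    out[m, ] <- c(mean(state == 0L), mean(state == 1L), mean(state == 2L))
  }
  out
}

wt_params <- function() sop_params()
ko_params <- function() sop_params(pd1 = 0.11)

state_unclassed <- function(s) as.numeric(unclass(s))
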