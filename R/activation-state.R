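#' Activation state of one stimulus representation
#'
#' The proportions of a stimulus's memory elements that are inactive (`pI`),
#' in the primary activity state (`pA1`) and in the secondary activity state
#' (`pA2`). The three proportions are non-negative and sum to one (within
#' 1e-12); elements occupy exactly one state at a time.
#'
#' @param pI,pA1,pA2 State proportions.
#' @return A named numeric vector of class `activation_state`.
#' @examples
#' rest_state()
#' activation_state(0.8, 0.2, 0)
#' @export
activation_state <- function(pI = 1, pA1 = 0, pA2 = 0) {
  s <- c(pI = pI, pA1 = pA1, pA2 = pA2)
  validate_activation_state(s)
  structure(s, class = "activation_state")
}

#' @rdname activation_state
#' @export
rest_state <- function() activation_state(1, 0, 0)

# conservation tolerance for pI + pA1 + pA2 == 1
.state_tol <- 1e-12

validate_activation_state <- function(s) {
  if (!is.numeric(s) || length(s) != 3L || anyNA(s))
    stop("an activation state is three numeric proportions", call. = FALSE)
  if (any(s < -.state_tol) || any(s > 1 + .state_tol))
    stop("state proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(s) - 1) > 1e-9)
    stop("state proportions must sum to 1 (got ", format(sum(s)), ")",
         call. = FALSE)
  invisible(s)
}

# clip tiny negative / >1 excursions introduced by floating point, then
# re-normalise the residual into pI so conservation holds exactly enough
.clip_state <- function(s) {
  s <- pmin(pmax(s, 0), 1)
  s[1L] <- s[1L] + (1 - sum(s))
  s
}

#' @export
print.activation_state <- function(x, ...) {
  cat(sprintf("activation state: pI = %.6g, pA1 = %.6g, pA2 = %.6g\n",
              x[["pI"]], x[["pA1"]], x[["pA2"]]))
  invisible(x)
}

#' Response strength generated by an activation state
#'
#' Elements in A1 generate strong responding (weight `w1`); elements in A2
#' respond only weakly (weight `w2`); inactive elements do not respond.
#'
#' @param state An [activation_state()] (or any numeric vector with `pA1`
#'   and `pA2` entries).
#' @param w1 Weight on A1 activity; must satisfy `w1 > w2`.
#' @param w2 Weight on A2 activity, `0 <= w2 < w1`.
#' @return A single response value `w1 * pA1 + w2 * pA2`.
#' @examples
#' response_strength(activation_state(0.8, 0.2, 0))           # 0.2
#' response_strength(activation_state(0.8, 0, 0.2), w2 = 0.2) # 0.04
#' @export
response_strength <- function(state, w1 = 1, w2 = 0.1) {
  if (!is.numeric(w1) || !is.numeric(w2) || w2 < 0 || w2 >= w1)
    stop("response weights must satisfy w1 > w2 >= 0", call. = FALSE)
  w1 * state[["pA1"]] + w2 * state[["pA2"]]
}
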