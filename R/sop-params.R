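#' SOP model parameters
#'
#' Bundle the five rate parameters of the sometimes-opponent-process (SOP)
#' element model for one simulated genotype. All rates are per-moment
#' proportions and must lie in `[0, 1]`.
#'
#' @param intensity Probability per moment that an inactive element of a
#'   present stimulus is recruited into the primary activity state A1.
#' @param pd1 Proportion of A1 elements decaying to the secondary activity
#'   state A2 per moment (self-generated priming). The modelled effect of
#'   GluA1 deletion is a reduction of this rate.
#' @param pd2 Proportion of A2 elements returning to the inactive state I per
#'   moment.
#' @param l_excit Excitatory learning rate: gain on concurrent predictor-A1
#'   by target-A1 activity.
#' @param l_inhib Inhibitory learning rate: gain on concurrent predictor-A1
#'   by target-A2 activity (the opponent term).
#'
#' @return An object of class `sop_params`.
#' @examples
#' sop_params()                 # wild-type defaults
#' sop_params(pd1 = 0.11)      # slowed A1 -> A2 decay (knockout)
#' @export
sop_params <- function(intensity = 0.2, pd1 = 0.2, pd2 = 0.04,
                       l_excit = 0.07, l_inhib = 0.014) {
  p <- list(intensity = intensity, pd1 = pd1, pd2 = pd2,
            l_excit = l_excit, l_inhib = l_inhib)
  validate_sop_params(p)
  structure(p, class = "sop_params")
}

validate_sop_params <- function(p) {
  for (nm in c("intensity", "pd1", "pd2", "l_excit", "l_inhib")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("`", nm, "` must be a single numeric value", call. = FALSE)
    if (v < 0 || v > 1)
      stop("`", nm, "` must lie in [0, 1], got ", format(v), call. = FALSE)
  }
  invisible(p)
}

#' Reduce the A1-to-A2 decay rate by a fraction
#'
#' @param params An [sop_params()] object.
#' @param fraction Reduction fraction in `[0, 1]`; the returned parameter set
#'   has `pd1 = pd1 * (1 - fraction)`.
#' @return An `sop_params` object with the reduced `pd1`.
#' @export
reduce_pd1 <- function(params, fraction) {
  stopifnot(inherits(params, "sop_params"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("`fraction` must be a single value in [0, 1]", call. = FALSE)
  sop_params(intensity = params$intensity,
             pd1 = params$pd1 * (1 - fraction),
             pd2 = params$pd2,
             l_excit = params$l_excit,
             l_inhib = params$l_inhib)
}

#' @export
print.sop_params <- function(x, ...) {
  cat("SOP parameters\n")
  cat(sprintf("  intensity (p1): %.4g\n", x$intensity))
  cat(sprintf("  pd1 (A1 -> A2): %.4g\n", x$pd1))
  cat(sprintf("  pd2 (A2 -> I) : %.4g\n", x$pd2))
  cat(sprintf("  l_excit       : %.4g\n", x$l_excit))
  cat(sprintf("  l_inhib       : %.4g\n", x$l_inhib))
  invisible(x)
}
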