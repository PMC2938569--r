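#' @name sop_steps
#' @title Per-moment SOP state transitions
#'
#' @description
#' The four sub-steps applied to every stimulus representation at each
#' discrete moment, in order:
#'
#' 1. `step_decay()` — self-generated priming: a proportion `pd1` of A1
#'    elements transfers to A2, and a proportion `pd2` of the *pre-transfer*
#'    A2 elements returns to I.
#' 2. `step_activation()` — if the stimulus is present, a proportion
#'    `intensity` of inactive elements is recruited into A1. Elements in A2
#'    cannot return to A1.
#' 3. `step_retrieval_priming()` — associative activation: predictors with
#'    positive net associative strength toward the target transfer a
#'    proportion `r = min(1, sum(pA1_predictor * max(v_net, 0)))` of the
#'    target's inactive elements directly into A2.
#' 4. `step_learning()` — opponent learning: the excitatory strength of a
#'    predictor-target link grows by `l_excit * pA1_pred * pA1_targ` and the
#'    inhibitory strength by `l_inhib * pA1_pred * pA2_targ`. Strengths never
#'    decrease.
#'
#' Each function is total on valid states and preserves
#' `pI + pA1 + pA2 == 1`.
NULL

# internal arithmetic on a plain states matrix (rows = stimuli,
# cols = pI, pA1, pA2); single source of truth for the recurrences
.decay_mat <- function(S, pd1, pd2) {
  toA2 <- pd1 * S[, 2L]
  toI  <- pd2 * S[, 3L]
  S[, 1L] <- S[, 1L] + toI
  S[, 2L] <- S[, 2L] - toA2
  S[, 3L] <- S[, 3L] + toA2 - toI
  S
}

.activate_mat <- function(S, present, intensity) {
  tr <- ifelse(present, intensity * S[, 1L], 0)
  S[, 1L] <- S[, 1L] - tr
  S[, 2L] <- S[, 2L] + tr
  S
}

# priming rates for all targets given current A1 column and net strengths;
# ve, vi are predictor x target matrices
.priming_rates <- function(a1, ve, vi, enabled) {
  vnet <- pmax(ve - vi, 0)
  vnet[!enabled] <- 0
  pmin(1, as.vector(crossprod(vnet, a1)))
}

#' @rdname sop_steps
#' @param state,target_state An [activation_state()].
#' @param params An [sop_params()] object.
#' @return An updated `activation_state` (steps 1-3) or link (step 4).
#' @examples
#' step_decay(activation_state(0.8, 0.2, 0), sop_params())  # (0.8, 0.16, 0.04)
#' @export
step_decay <- function(state, params) {
  validate_activation_state(state)
  S <- .decay_mat(matrix(unclass(state), 1L), params$pd1, params$pd2)
  activation_state(S[1L], S[2L], S[3L])
}

#' @rdname sop_steps
#' @param present Logical flag: is the stimulus present at this moment?
#' @export
step_activation <- function(state, present, params) {
  validate_activation_state(state)
  if (!present) return(state)
  S <- .activate_mat(matrix(unclass(state), 1L), TRUE, params$intensity)
  activation_state(S[1L], S[2L], S[3L])
}

#' @rdname sop_steps
#' @param predictor_a1 Numeric vector of predictor A1 activities.
#' @param v_net Numeric vector of net associative strengths of the links
#'   from each predictor to the target; non-positive entries contribute no
#'   priming.
#' @export
step_retrieval_priming <- function(target_state, predictor_a1, v_net) {
  validate_activation_state(target_state)
  if (length(predictor_a1) != length(v_net))
    stop("`predictor_a1` and `v_net` must have equal length", call. = FALSE)
  r <- min(1, sum(predictor_a1 * pmax(v_net, 0)))
  tr <- r * target_state[["pI"]]
  activation_state(target_state[["pI"]] - tr,
                   target_state[["pA1"]],
                   target_state[["pA2"]] + tr)
}

#' @rdname sop_steps
#' @param predictor_state An [activation_state()] of the predictor stimulus.
#' @param link Named numeric vector `c(v_excit = , v_inhib = )`, both `>= 0`.
#' @export
step_learning <- function(predictor_state, target_state, link, params) {
  validate_activation_state(predictor_state)
  validate_activation_state(target_state)
  if (any(link < 0)) stop("link strengths must be non-negative", call. = FALSE)
  c(v_excit = link[["v_excit"]] +
      params$l_excit * predictor_state[["pA1"]] * target_state[["pA1"]],
    v_inhib = link[["v_inhib"]] +
      params$l_inhib * predictor_state[["pA1"]] * target_state[["pA2"]])
}

#' Advance every stimulus by one moment
#'
#' Applies, in order, decay, activation of present stimuli, retrieval
#' priming of every target, and learning on every enabled ordered pair,
#' using the post-transfer activities of the current moment throughout.
#'
#' @param states Numeric matrix (stimuli x 3) of `pI, pA1, pA2` rows.
#' @param links List with predictor-by-target matrices `ve` and `vi` and a
#'   logical matrix `enabled` selecting the ordered pairs that learn.
#' @param present Logical vector: which stimuli are present this moment.
#' @param params An [sop_params()] object.
#' @return List with updated `states` and `links`.
#' @export
advance_moment <- function(states, links, present, params) {
  S <- .decay_mat(states, params$pd1, params$pd2)
  S <- .activate_mat(S, present, params$intensity)
  r <- .priming_rates(S[, 2L], links$ve, links$vi, links$enabled)
  tr <- r * S[, 1L]
  S[, 1L] <- S[, 1L] - tr
  S[, 3L] <- S[, 3L] + tr
  # absorb floating-point excursions so conservation holds at every moment:
  # clip to [0, 1] and fold the (sub-machine-epsilon) residual into each
  # row's largest component, which cannot be driven out of range by it
  S[S < 0] <- 0
  S[S > 1] <- 1
  imax <- max.col(S)
  S[cbind(seq_len(nrow(S)), imax)] <-
    S[cbind(seq_len(nrow(S)), imax)] + (1 - rowSums(S))
  if (any(links$enabled)) {
    links$ve <- links$ve +
      params$l_excit * links$enabled * outer(S[, 2L], S[, 2L])
    links$vi <- links$vi +
      params$l_inhib * links$enabled * outer(S[, 2L], S[, 3L])
  }
  list(states = S, links = links)
}

#' Create an empty link structure
#'
#' @param stim_names Character vector of stimulus names.
#' @param enabled_pairs Two-column character matrix (or data.frame) of
#'   (predictor, target) ordered pairs on which learning operates. `NULL`
#'   enables no pairs.
#' @return A link structure for [run_schedule()] / [advance_moment()].
#' @export
init_links <- function(stim_names, enabled_pairs = NULL) {
  n <- length(stim_names)
  z <- matrix(0, n, n, dimnames = list(stim_names, stim_names))
  en <- matrix(FALSE, n, n, dimnames = list(stim_names, stim_names))
  if (!is.null(enabled_pairs)) {
    enabled_pairs <- as.matrix(enabled_pairs)
    if (ncol(enabled_pairs) != 2L)
      stop("`enabled_pairs` must have two columns (predictor, target)",
           call. = FALSE)
    if (!all(enabled_pairs %in% stim_names))
      stop("enabled pair names must match the schedule's stimuli",
           call. = FALSE)
    if (any(enabled_pairs[, 1L] == enabled_pairs[, 2L]))
      stop("a stimulus cannot predict itself", call. = FALSE)
    en[enabled_pairs] <- TRUE
  }
  list(ve = z, vi = z, enabled = en)
}

#' Run a schedule through the SOP recurrences
#'
#' Iterates [advance_moment()] over every moment of a schedule, starting from
#' rest (all elements inactive) and zero associative strength unless initial
#' values are supplied. The trace records every stimulus's activation state
#' and the link matrices after each full moment, plus the momentary change in
#' net associative strength of every enabled pair.
#'
#' @param schedule An [sop_schedule()].
#' @param params An [sop_params()] object.
#' @param enabled_pairs Ordered (predictor, target) pairs that learn; see
#'   [init_links()].
#' @param initial_links Optional link structure to start from (for chained
#'   phases); defaults to zero strengths.
#' @return An object of class `sop_trace` with elements `states` (array
#'   moments x stimuli x 3), `dv` (matrix moments x enabled pairs of
#'   momentary net-strength changes), `links` (final link structure),
#'   `schedule` and `params`.
#' @examples
#' sch <- sop_schedule(matrix(1, 10, 1, dimnames = list(NULL, "cs")))
#' tr <- run_schedule(sch, sop_params())
#' tr$states[1, "cs", ]  # (0.8, 0.2, 0) after the first presentation
#' @export
run_schedule <- function(schedule, params, enabled_pairs = NULL,
                         initial_links = NULL) {
  stopifnot(inherits(schedule, "sop_schedule"),
            inherits(params, "sop_params"))
  pres <- schedule$presence
  nm <- nrow(pres)
  if (nm < 1L) stop("cannot run an empty schedule", call. = FALSE)
  stim <- stimuli(schedule)
  ns <- length(stim)

  links <- if (is.null(initial_links)) init_links(stim, enabled_pairs)
           else initial_links
  S <- matrix(c(rep(1, ns), rep(0, 2L * ns)), ns, 3L,
              dimnames = list(stim, c("pI", "pA1", "pA2")))

  pair_idx <- which(links$enabled, arr.ind = TRUE)
  pair_names <- if (nrow(pair_idx))
    paste(stim[pair_idx[, 1L]], stim[pair_idx[, 2L]], sep = "->") else
    character(0)

  states <- array(NA_real_, dim = c(nm, ns, 3L),
                  dimnames = list(NULL, stim, c("pI", "pA1", "pA2")))
  dv <- matrix(NA_real_, nm, length(pair_names),
               dimnames = list(NULL, pair_names))
  ve_t <- vi_t <- matrix(NA_real_, nm, length(pair_names),
                         dimnames = list(NULL, pair_names))

  for (m in seq_len(nm)) {
    vnet0 <- links$ve[pair_idx] - links$vi[pair_idx]
    step <- advance_moment(S, links, pres[m, ] == 1, params)
    S <- step$states
    links <- step$links
    states[m, , ] <- S
    if (length(pair_names)) {
      dv[m, ] <- (links$ve[pair_idx] - links$vi[pair_idx]) - vnet0
      ve_t[m, ] <- links$ve[pair_idx]
      vi_t[m, ] <- links$vi[pair_idx]
    }
  }

  structure(list(states = states, dv = dv, v_excit = ve_t, v_inhib = vi_t,
                 links = links, schedule = schedule, params = params),
            class = "sop_trace")
}

#' @export
print.sop_trace <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf("SOP trace: %d moments, %d stimuli\n", d[1L], d[2L]))
  if (ncol(x$dv)) {
    vn <- x$links$ve - x$links$vi
    for (p in colnames(x$dv)) {
      pt <- strsplit(p, "->", fixed = TRUE)[[1L]]
      cat(sprintf("  %s: final v_net = %.6g\n", p, vn[pt[1L], pt[2L]]))
    }
  }
  invisible(x)
}

#' Tidy per-moment state trace
#'
#' @param x An `sop_trace`.
#' @param ... Unused.
#' @return A data.frame with columns `moment`, `stimulus`, `pI`, `pA1`,
#'   `pA2`, one row per stimulus per moment.
#' @export
as.data.frame.sop_trace <- function(x, ...) {
  d <- dim(x$states)
  stim <- dimnames(x$states)[[2L]]
  data.frame(
    moment = rep(seq_len(d[1L]), times = d[2L]),
    stimulus = rep(stim, each = d[1L]),
    pI = as.vector(x$states[, , "pI"]),
    pA1 = as.vector(x$states[, , "pA1"]),
    pA2 = as.vector(x$states[, , "pA2"]),
    stringsAsFactors = FALSE
  )
}

#' Tidy per-moment link trace
#'
#' @param trace An `sop_trace`.
#' @return A data.frame with one row per enabled pair per moment and columns
#'   `moment`, `predictor`, `target`, `v_excit`, `v_inhib`, `v_net` and
#'   `v_net_change` (the momentary increment plotted in net-strength
#'   traces).
#' @export
link_trace <- function(trace) {
  stopifnot(inherits(trace, "sop_trace"))
  if (!ncol(trace$dv))
    return(data.frame(moment = integer(0), predictor = character(0),
                      target = character(0), v_excit = numeric(0),
                      v_inhib = numeric(0), v_net = numeric(0),
                      v_net_change = numeric(0)))
  out <- lapply(colnames(trace$dv), function(p) {
    pt <- strsplit(p, "->", fixed = TRUE)[[1L]]
    data.frame(moment = seq_len(nrow(trace$dv)),
               predictor = pt[1L], target = pt[2L],
               v_excit = trace$v_excit[, p],
               v_inhib = trace$v_inhib[, p],
               v_net = trace$v_excit[, p] - trace$v_inhib[, p],
               v_net_change = trace$dv[, p],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
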