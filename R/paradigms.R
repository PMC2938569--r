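#' Y-maze novelty-preference paradigm specification
#'
#' Trial structure of the simulated spatial-novelty-preference experiment:
#' exposure training trials in which a context/start-arm stimulus (the CS,
#' active throughout each trial) co-terminates with a sample-arm stimulus
#' (the trained US, active at the end of each trial), followed after a test
#' interval by a novelty test in which the CS is presented with the trained
#' US and a never-before-seen novel US co-terminating on its final moment.
#'
#' @param cs_moments Training CS duration in moments.
#' @param us_moments Training US duration; the US co-terminates with the CS,
#'   so it must not exceed `cs_moments`.
#' @param n_training_trials Number of exposure training trials.
#' @param training_iti Moments between training trials (all stimuli off).
#' @param test_interval Moments between the last training trial and the test.
#' @param test_cs_moments CS duration at test.
#' @param test_us_moments Duration of the two USs at test (co-terminating
#'   with the test CS).
#' @return An object of class `novelty_spec`.
#' @examples
#' novelty_spec()                       # massed training, early test
#' novelty_spec(training_iti = 100, test_interval = 100)  # spaced, late
#' @export
novelty_spec <- function(cs_moments = 10, us_moments = 5,
                         n_training_trials = 2, training_iti = 5,
                         test_interval = 5, test_cs_moments = 6,
                         test_us_moments = 1) {
  spec <- list(cs_moments = cs_moments, us_moments = us_moments,
               n_training_trials = n_training_trials,
               training_iti = training_iti, test_interval = test_interval,
               test_cs_moments = test_cs_moments,
               test_us_moments = test_us_moments)
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop("`", nm, "` must be a positive whole number of moments",
           call. = FALSE)
  }
  if (spec$us_moments > spec$cs_moments)
    stop("`us_moments` must not exceed `cs_moments` (the US co-terminates ",
         "with the CS)", call. = FALSE)
  if (spec$test_us_moments > spec$test_cs_moments)
    stop("`test_us_moments` must not exceed `test_cs_moments`",
         call. = FALSE)
  structure(spec, class = "novelty_spec")
}

#' Build the three-stimulus schedule of a novelty-preference condition
#'
#' @param spec A [novelty_spec()].
#' @return An [sop_schedule()] over stimuli `cs`, `us_trained`, `us_novel`.
#'   The novel US appears nowhere before the test.
#' @examples
#' n_moments(build_novelty_schedule(novelty_spec()))  # 36
#' @export
build_novelty_schedule <- function(spec) {
  stopifnot(inherits(spec, "novelty_spec"))
  n_pre <- spec$n_training_trials * spec$cs_moments +
    (spec$n_training_trials - 1) * spec$training_iti + spec$test_interval
  n <- n_pre + spec$test_cs_moments
  pres <- matrix(0, n, 3L,
                 dimnames = list(NULL, c("cs", "us_trained", "us_novel")))
  for (t in seq_len(spec$n_training_trials)) {
    start <- (t - 1) * (spec$cs_moments + spec$training_iti)
    pres[start + seq_len(spec$cs_moments), "cs"] <- 1
    pres[start + (spec$cs_moments - spec$us_moments + 1):spec$cs_moments,
         "us_trained"] <- 1
  }
  pres[n_pre + seq_len(spec$test_cs_moments), "cs"] <- 1
  us_test <- n_pre +
    (spec$test_cs_moments - spec$test_us_moments + 1):spec$test_cs_moments
  pres[us_test, "us_trained"] <- 1
  pres[us_test, "us_novel"] <- 1
  sop_schedule(pres)
}

# ordered pairs on which the novelty paradigm learns: the CS (active
# throughout each trial) predicts each US
.novelty_pairs <- cbind(predictor = c("cs", "cs"),
                        target = c("us_trained", "us_novel"))

#' Run one novelty-preference condition
#'
#' @param spec A [novelty_spec()].
#' @param params An [sop_params()] object.
#' @return An `sop_trace` over the condition's full schedule, with CS->US
#'   learning enabled.
#' @export
run_novelty_condition <- function(spec, params) {
  run_schedule(build_novelty_schedule(spec), params,
               enabled_pairs = .novelty_pairs)
}

#' Novelty-preference score of a completed test
#'
#' The difference in A1 activity between the novel and the trained US at the
#' final test moment (the single moment at which both USs are present), read
#' after the full moment update. Positive values indicate relatively greater
#' novel-US A1 activity, i.e. novelty preference.
#'
#' @param trace An `sop_trace` from [run_novelty_condition()].
#' @return A single numeric score, bounded by the intensity parameter.
#' @export
novelty_preference_score <- function(trace) {
  stopifnot(inherits(trace, "sop_trace"))
  stim <- dimnames(trace$states)[[2L]]
  if (!all(c("us_trained", "us_novel") %in% stim))
    stop("trace does not come from a novelty schedule (needs ",
         "`us_trained` and `us_novel` stimuli)", call. = FALSE)
  pres <- trace$schedule$presence
  last <- nrow(pres)
  if (pres[last, "us_trained"] != 1 || pres[last, "us_novel"] != 1)
    stop("schedule does not end with both USs present at test",
         call. = FALSE)
  trace$states[last, "us_novel", "pA1"] -
    trace$states[last, "us_trained", "pA1"]
}

#' Run the full novelty-preference condition grid
#'
#' Runs every cell of the genotype x training-ITI x test-interval factorial
#' and summarises it three ways: per-cell scores, scores collapsed over the
#' test intervals (unweighted mean), and the test-interval-matched condition
#' scores (short ITI read at the short test interval, long ITI at the long
#' one) that isolate the training-ITI effect from recency carryover at the
#' test. The matched scores are the package's primary contrast; see the
#' methods vignette.
#'
#' @param params_by_genotype Named list of [sop_params()] objects, e.g.
#'   `list(wildtype = sop_params(), knockout = sop_params(pd1 = 0.11))`.
#' @param spec Template [novelty_spec()]; its `training_iti` and
#'   `test_interval` are overridden by `itis` / `test_intervals`.
#' @param itis Training inter-trial intervals (moments).
#' @param test_intervals Intervals between training and test (moments).
#' @return An object of class `novelty_grid`: list with data.frames `cells`
#'   (genotype, training_iti, test_interval, score), `collapsed` (mean score
#'   per genotype x training_iti over test intervals) and `matched`
#'   (score per genotype x training_iti at the matching test interval).
#' @export
run_condition_grid <- function(params_by_genotype, spec = novelty_spec(),
                               itis = c(5, 100),
                               test_intervals = c(5, 100)) {
  stopifnot(is.list(params_by_genotype), length(params_by_genotype) >= 1,
            !is.null(names(params_by_genotype)))
  cells <- expand.grid(genotype = names(params_by_genotype),
                       training_iti = itis, test_interval = test_intervals,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$score <- vapply(seq_len(nrow(cells)), function(i) {
    sp <- spec
    sp$training_iti <- cells$training_iti[i]
    sp$test_interval <- cells$test_interval[i]
    novelty_preference_score(
      run_novelty_condition(sp, params_by_genotype[[cells$genotype[i]]]))
  }, numeric(1))

  collapsed <- aggregate(score ~ genotype + training_iti, data = cells, mean)
  matched <- cells[cells$training_iti == cells$test_interval,
                   c("genotype", "training_iti", "score")]
  if (nrow(matched) == 0L)  # no matching intervals: fall back to collapsed
    matched <- collapsed
  rownames(matched) <- NULL
  structure(list(cells = cells, collapsed = collapsed, matched = matched),
            class = "novelty_grid")
}

#' @export
print.novelty_grid <- function(x, ...) {
  cat("Novelty-preference condition grid\n")
  cat("Per-cell scores (novel-US A1 minus trained-US A1 at test):\n")
  print(x$cells, row.names = FALSE)
  cat("\nMatched condition scores (test interval = training ITI):\n")
  print(x$matched, row.names = FALSE)
  invisible(x)
}

# matched short/long condition scores for one parameter set
.condition_scores <- function(params, spec, short_iti, long_iti) {
  sc <- function(iti) {
    sp <- spec; sp$training_iti <- iti; sp$test_interval <- iti
    novelty_preference_score(run_novelty_condition(sp, params))
  }
  c(short = sc(short_iti), long = sc(long_iti))
}

#' Sweep reductions of the A1-to-A2 decay rate
#'
#' For each reduction fraction `f` on the grid, sets `pd1 = pd1 * (1 - f)`,
#' recomputes the short- and long-ITI novelty-preference condition scores,
#' and flags `f` as qualifying when the reduced model shows strictly less
#' novelty preference than baseline after massed (short-ITI) training and
#' strictly more after spaced (long-ITI) training — the signature dissociation
#' of slowed A1-to-A2 transfer.
#'
#' @param baseline_params [sop_params()] of the unreduced model.
#' @param reductions Grid of reduction fractions in `[0, 1)`.
#' @param spec Template [novelty_spec()].
#' @param short_iti,long_iti The two training ITIs (moments).
#' @return An object of class `pd1_sweep`: list with `profile` (data.frame
#'   `reduction`, `short`, `long`, `qualifies`), `baseline` (named scores),
#'   `window` (two-element vector of the lowest and highest qualifying
#'   reduction, `NA` if none) and `contiguous` (logical). A warning is
#'   issued if the qualifying set is empty or fragmented.
#' @export
pd1_reduction_sweep <- function(baseline_params = sop_params(),
                                reductions = seq(0, 0.70, by = 0.005),
                                spec = novelty_spec(),
                                short_iti = 5, long_iti = 100) {
  if (length(reductions) == 0L)
    stop("`reductions` grid is empty", call. = FALSE)
  if (any(reductions < 0 | reductions >= 1))
    stop("reduction fractions must lie in [0, 1)", call. = FALSE)
  base <- .condition_scores(baseline_params, spec, short_iti, long_iti)
  prof <- t(vapply(reductions, function(f)
    .condition_scores(reduce_pd1(baseline_params, f), spec,
                      short_iti, long_iti), numeric(2)))
  profile <- data.frame(reduction = reductions,
                        short = prof[, "short"], long = prof[, "long"])
  profile$qualifies <- profile$short < base[["short"]] &
    profile$long > base[["long"]]

  q <- which(profile$qualifies)
  if (length(q) == 0L) {
    warning("no reduction on the grid satisfies both conditions; ",
            "qualifying window is empty", call. = FALSE)
    window <- c(lower = NA_real_, upper = NA_real_)
    contiguous <- NA
  } else {
    window <- c(lower = reductions[min(q)], upper = reductions[max(q)])
    contiguous <- all(diff(q) == 1L)
    if (!contiguous)
      warning("qualifying set is fragmented; window endpoints span ",
              "non-qualifying gaps", call. = FALSE)
  }
  structure(list(profile = profile, baseline = base, window = window,
                 contiguous = contiguous),
            class = "pd1_sweep")
}

#' @export
print.pd1_sweep <- function(x, ...) {
  cat("pd1-reduction sweep\n")
  cat(sprintf("  baseline scores: short-ITI %.4f, long-ITI %.4f\n",
              x$baseline[["short"]], x$baseline[["long"]]))
  if (anyNA(x$window)) {
    cat("  qualifying window: empty\n")
  } else {
    cat(sprintf("  qualifying window: %.1f%% - %.1f%% (%s)\n",
                100 * x$window[["lower"]], 100 * x$window[["upper"]],
                if (isTRUE(x$contiguous)) "contiguous" else "fragmented"))
  }
  invisible(x)
}

#' Conditioning strength as a function of CS duration
#'
#' Runs one conditioning trial per duration: a CS of the given length with a
#' brief US co-terminating on its final moments, followed by a short
#' post-trial tail, and returns the final CS->US net associative strength.
#' Because the CS's A1 activity first waxes and then wanes during a
#' prolonged presentation, conditioning is maximal at intermediate CS
#' durations and weaker when the CS is much longer.
#'
#' @param durations CS durations in moments; each must exceed `us_moments`
#'   (the US cannot start at CS onset).
#' @param params An [sop_params()] object.
#' @param us_moments US duration (co-terminating with the CS).
#' @param tail_moments Stimulus-free moments appended after the trial.
#' @return A data.frame with columns `duration` and `v_net`.
#' @export
cs_duration_experiment <- function(durations = c(2, 8, 40),
                                   params = sop_params(),
                                   us_moments = 1, tail_moments = 5) {
  if (length(durations) == 0L) stop("`durations` is empty", call. = FALSE)
  if (any(durations <= us_moments))
    stop("every CS duration must exceed `us_moments`: a CS with no ",
         "moments before US onset is not a conditioning trial",
         call. = FALSE)
  v <- vapply(durations, function(d) {
    n <- d + tail_moments
    pres <- matrix(0, n, 2L, dimnames = list(NULL, c("cs", "us")))
    pres[seq_len(d), "cs"] <- 1
    pres[(d - us_moments + 1):d, "us"] <- 1
    tr <- run_schedule(sop_schedule(pres), params,
                       enabled_pairs = cbind("cs", "us"))
    tr$links$ve["cs", "us"] - tr$links$vi["cs", "us"]
  }, numeric(1))
  data.frame(duration = durations, v_net = v)
}

#' Response to repeated stimulus presentations
#'
#' Presents one stimulus repeatedly and returns the response strength at the
#' onset moment of each presentation. With massed presentations, elements
#' accumulate in A2 and the onset response declines (short-term
#' habituation); with sufficiently spaced presentations the response
#' recovers fully.
#'
#' @param n_presentations Number of presentations (`>= 2`).
#' @param iti_moments Stimulus-free moments between presentations.
#' @param params An [sop_params()] object.
#' @param stim_moments Duration of each presentation.
#' @param w1,w2 Response weights passed to [response_strength()].
#' @return Numeric vector of onset responses, one per presentation.
#' @export
habituation_series <- function(n_presentations, iti_moments,
                               params = sop_params(), stim_moments = 10,
                               w1 = 1, w2 = 0) {
  if (n_presentations < 2)
    stop("need at least two presentations to assess habituation",
         call. = FALSE)
  blocks <- lapply(seq_len(n_presentations), function(p) {
    on <- rep(1, stim_moments)
    if (p < n_presentations) c(on, rep(0, iti_moments)) else on
  })
  pres <- matrix(unlist(blocks), ncol = 1L,
                 dimnames = list(NULL, "stim"))
  tr <- run_schedule(sop_schedule(pres), params)
  onsets <- cumsum(c(1, rep(stim_moments + iti_moments,
                            n_presentations - 1)))
  vapply(onsets, function(m) {
    s <- tr$states[m, "stim", ]
    w1 * s[["pA1"]] + w2 * s[["pA2"]]
  }, numeric(1))
}
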