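#' Mapping from model states to arm exploration times
#'
#' Expected exploration time of an arm is proportional to the response
#' strength of the corresponding stimulus state at test: strongly for A1
#' elements, weakly for A2 elements. The default weights keep the familiar
#' arm's large A2 pool from dominating its small A1 signal, so that a
#' habituated arm is explored less.
#'
#' @param w1 A1 response weight.
#' @param w2 A2 response weight, `0 <= w2 < w1`.
#' @param time_scale Expected exploration seconds per unit response.
#' @return An object of class `response_mapping`.
#' @export
response_mapping <- function(w1 = 1, w2 = 0.1, time_scale = 200) {
  if (!is.numeric(w1) || !is.numeric(w2) || w2 < 0 || w2 >= w1)
    stop("response weights must satisfy w1 > w2 >= 0", call. = FALSE)
  if (!is.numeric(time_scale) || time_scale <= 0)
    stop("`time_scale` must be positive", call. = FALSE)
  structure(list(w1 = w1, w2 = w2, time_scale = time_scale),
            class = "response_mapping")
}

#' Expected arm exploration times of a novelty test
#'
#' @param trace An `sop_trace` from [run_novelty_condition()].
#' @param mapping A [response_mapping()].
#' @return Named numeric vector of expected exploration seconds for the
#'   `novel`, `familiar` (trained/sample) and `start` (CS) arms, read at the
#'   final test moment.
#' @export
map_to_exploration <- function(trace, mapping = response_mapping()) {
  stopifnot(inherits(trace, "sop_trace"))
  if (!inherits(mapping, "response_mapping"))
    stop("`mapping` must be a response_mapping object", call. = FALSE)
  last <- dim(trace$states)[1L]
  resp <- function(stim) {
    s <- trace$states[last, stim, ]
    mapping$time_scale *
      (mapping$w1 * s[["pA1"]] + mapping$w2 * s[["pA2"]])
  }
  c(novel = resp("us_novel"), familiar = resp("us_trained"),
    start = resp("cs"))
}

#' Synthetic cohort specification
#'
#' @param n_per_group Animals per genotype x condition group.
#' @param noise Coefficient of variation of per-animal exploration times
#'   around the model-mapped mean (gamma-distributed).
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 12, noise = 0.3, seed = 1L) {
  if (!is.numeric(n_per_group) || n_per_group < 1 ||
      n_per_group != round(n_per_group))
    stop("`n_per_group` must be a positive whole number", call. = FALSE)
  if (!is.numeric(noise) || noise <= 0)
    stop("`noise` must be positive", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), noise = noise,
                 seed = as.integer(seed)), class = "cohort_spec")
}

# draw gamma times with given mean and coefficient of variation; a zero mean
# stays exactly zero
.rgamma_cv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  shape <- 1 / cv^2
  rgamma(n, shape = shape, scale = mean / shape)
}

#' Generate a synthetic behavioral cohort
#'
#' Simulates the model for every genotype x condition cell, maps the test
#' states to expected arm exploration times, and draws independent
#' per-animal times from gamma distributions with those means. The same seed
#' always reproduces the same table.
#'
#' @param params_by_genotype Named list of [sop_params()] objects.
#' @param spec_cohort A [cohort_spec()].
#' @param paradigm Template [novelty_spec()].
#' @param itis,test_intervals Condition factors (moments).
#' @param mapping A [response_mapping()].
#' @return A `cohort_table` data.frame with one row per animal: `animal_id`,
#'   `genotype`, `training_iti`, `test_interval`, `novel_time`,
#'   `familiar_time`, `start_time` (seconds).
#' @export
generate_cohort <- function(params_by_genotype,
                            spec_cohort = cohort_spec(),
                            paradigm = novelty_spec(),
                            itis = c(5, 100), test_intervals = c(5, 100),
                            mapping = response_mapping()) {
  stopifnot(inherits(spec_cohort, "cohort_spec"))
  conditions <- expand.grid(genotype = names(params_by_genotype),
                            training_iti = itis,
                            test_interval = test_intervals,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- with_preserved_rng({
    set.seed(derive_seed(spec_cohort$seed, "cohort"))
    out <- vector("list", nrow(conditions))
    for (i in seq_len(nrow(conditions))) {
      sp <- paradigm
      sp$training_iti <- conditions$training_iti[i]
      sp$test_interval <- conditions$test_interval[i]
      tr <- run_novelty_condition(
        sp, params_by_genotype[[conditions$genotype[i]]])
      mu <- map_to_exploration(tr, mapping)
      n <- spec_cohort$n_per_group
      out[[i]] <- data.frame(
        genotype = conditions$genotype[i],
        training_iti = conditions$training_iti[i],
        test_interval = conditions$test_interval[i],
        novel_time = .rgamma_cv(n, mu[["novel"]], spec_cohort$noise),
        familiar_time = .rgamma_cv(n, mu[["familiar"]], spec_cohort$noise),
        start_time = .rgamma_cv(n, mu[["start"]], spec_cohort$noise),
        stringsAsFactors = FALSE)
    }
    out
  })
  tab <- do.call(rbind, rows)
  tab <- cbind(animal_id = seq_len(nrow(tab)), tab)
  attr(tab, "seed") <- spec_cohort$seed
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Novelty discrimination ratio
#'
#' `Novel / (Novel + Familiar)` exploration time; 0.5 is chance, values above
#' 0.5 indicate novelty preference. The start arm is excluded.
#'
#' @param novel_time,familiar_time Non-negative exploration times
#'   (vectorised).
#' @return Discrimination ratios in `[0, 1]`.
#' @examples
#' discrimination_ratio(60, 20)  # 0.75
#' @export
discrimination_ratio <- function(novel_time, familiar_time) {
  if (any(novel_time < 0) || any(familiar_time < 0))
    stop("exploration times must be non-negative", call. = FALSE)
  total <- novel_time + familiar_time
  if (any(total == 0))
    stop("discrimination ratio undefined when both times are zero",
         call. = FALSE)
  novel_time / total
}

# one-sided sign-flip test of mean(x) > mu; exact enumeration when feasible
.sign_flip_test <- function(x, mu = 0.5, n_resamples = 10000,
                            exact_limit = 14L) {
  d <- x - mu
  n <- length(d)
  obs <- mean(d)
  if (n <= exact_limit) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- as.vector(signs %*% d) / n
    mean(perm >= obs - 1e-12)
  } else {
    signs <- matrix(sample(c(-1, 1), n * n_resamples, replace = TRUE),
                    nrow = n_resamples)
    perm <- as.vector(signs %*% d) / n
    (sum(perm >= obs - 1e-12) + 1) / (n_resamples + 1)
  }
}

#' Resampling analysis of a behavioral cohort
#'
#' Per genotype x condition group: mean discrimination ratio, bootstrap
#' percentile confidence interval, and a sign-flip test of the mean ratio
#' against chance (0.5; exact enumeration of all sign assignments for small
#' groups, Monte Carlo otherwise). Additionally tests the genotype x
#' training-ITI interaction of the discrimination ratio by permuting
#' genotype labels within training-ITI strata.
#'
#' @param table A `cohort_table` from [generate_cohort()] (or any data.frame
#'   with the same columns).
#' @param n_resamples Bootstrap / permutation resamples.
#' @param seed Integer seed for the resampling.
#' @param conf_level Confidence level of the bootstrap interval.
#' @return A list of class `cohort_analysis` with `groups` (data.frame of
#'   per-group summaries; groups with fewer than 2 animals are flagged and
#'   get `NA` intervals) and `interaction` (observed interaction statistic
#'   and permutation p value; `NA` when fewer than two genotypes or ITIs).
#' @export
analyze_cohort <- function(table, n_resamples = 2000, seed = 1L,
                           conf_level = 0.95) {
  stopifnot(is.data.frame(table))
  needed <- c("genotype", "training_iti", "test_interval",
              "novel_time", "familiar_time")
  if (!all(needed %in% names(table)))
    stop("cohort table lacks columns: ",
         paste(setdiff(needed, names(table)), collapse = ", "),
         call. = FALSE)
  table$dr <- discrimination_ratio(table$novel_time, table$familiar_time)
  key <- interaction(table$genotype, table$training_iti,
                     table$test_interval, drop = TRUE)

  with_preserved_rng({
    set.seed(derive_seed(seed, "analysis"))
    alpha <- (1 - conf_level) / 2
    groups <- do.call(rbind, lapply(split(table, key), function(g) {
      n <- nrow(g)
      m <- mean(g$dr)
      if (n >= 2) {
        boots <- replicate(n_resamples,
                           mean(g$dr[sample.int(n, n, replace = TRUE)]))
        ci <- unname(quantile(boots, c(alpha, 1 - alpha)))
        p <- .sign_flip_test(g$dr, 0.5, n_resamples)
        flag <- FALSE
      } else {
        ci <- c(NA_real_, NA_real_)
        p <- NA_real_
        flag <- TRUE
      }
      data.frame(genotype = g$genotype[1L],
                 training_iti = g$training_iti[1L],
                 test_interval = g$test_interval[1L],
                 n = n, mean_dr = m, ci_lower = ci[1L], ci_upper = ci[2L],
                 p_vs_chance = p, too_small = flag,
                 stringsAsFactors = FALSE)
    }))
    rownames(groups) <- NULL

    interaction_stat <- function(tab) {
      cm <- tapply(tab$dr, list(tab$genotype, tab$training_iti), mean)
      if (any(dim(cm) < 2L) || anyNA(cm)) return(NA_real_)
      (cm[2L, 2L] - cm[1L, 2L]) - (cm[2L, 1L] - cm[1L, 1L])
    }
    obs <- interaction_stat(table)
    inter <- if (is.na(obs)) {
      list(statistic = NA_real_, p_value = NA_real_)
    } else {
      perms <- replicate(n_resamples, {
        shuffled <- table
        for (s in split(seq_len(nrow(table)), table$training_iti))
          shuffled$genotype[s] <- sample(table$genotype[s])
        interaction_stat(shuffled)
      })
      list(statistic = obs,
           p_value = (sum(abs(perms) >= abs(obs) - 1e-12) + 1) /
             (n_resamples + 1))
    }
    structure(list(groups = groups, interaction = inter),
              class = "cohort_analysis")
  })
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis (discrimination ratio vs chance 0.5)\n")
  print(x$groups, row.names = FALSE, digits = 4)
  if (!is.na(x$interaction$statistic))
    cat(sprintf("\ngenotype x training-ITI interaction: %.4f (perm. p = %.4f)\n",
                x$interaction$statistic, x$interaction$p_value))
  invisible(x)
}

#' Recover the A1-to-A2 decay rate from a cohort
#'
#' Grid search over candidate `pd1` values minimising the summed squared
#' difference between the cohort's mean discrimination ratio per condition
#' and the noise-free model-mapped ratio under each candidate.
#'
#' @param table A `cohort_table`.
#' @param known_params [sop_params()] holding the parameters assumed known;
#'   only `pd1` is varied.
#' @param grid Candidate `pd1` values.
#' @param paradigm Template [novelty_spec()].
#' @param mapping A [response_mapping()].
#' @return A list of class `pd1_recovery` with `estimate` (grid argmin) and
#'   `profile` (data.frame `pd1`, `sse`).
#' @export
recover_pd1 <- function(table, known_params = sop_params(),
                        grid = seq(0.05, 0.30, by = 0.005),
                        paradigm = novelty_spec(),
                        mapping = response_mapping()) {
  if (length(grid) == 0L) stop("`grid` is empty", call. = FALSE)
  stopifnot(is.data.frame(table))
  table$dr <- discrimination_ratio(table$novel_time, table$familiar_time)
  obs <- aggregate(dr ~ training_iti + test_interval, data = table, mean)

  model_dr <- function(pd1) {
    p <- sop_params(intensity = known_params$intensity, pd1 = pd1,
                    pd2 = known_params$pd2,
                    l_excit = known_params$l_excit,
                    l_inhib = known_params$l_inhib)
    vapply(seq_len(nrow(obs)), function(i) {
      sp <- paradigm
      sp$training_iti <- obs$training_iti[i]
      sp$test_interval <- obs$test_interval[i]
      mu <- map_to_exploration(run_novelty_condition(sp, p), mapping)
      discrimination_ratio(mu[["novel"]], mu[["familiar"]])
    }, numeric(1))
  }
  sse <- vapply(grid, function(pd1)
    sum((obs$dr - model_dr(pd1))^2), numeric(1))
  structure(list(estimate = grid[which.min(sse)],
                 profile = data.frame(pd1 = grid, sse = sse)),
            class = "pd1_recovery")
}

#' @export
print.pd1_recovery <- function(x, ...) {
  cat(sprintf("pd1 recovery: estimate = %.4g (grid of %d candidates)\n",
              x$estimate, nrow(x$profile)))
  invisible(x)
}
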