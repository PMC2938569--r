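#' @name run_config
#' @title Run configuration
#'
#' @description
#' A run configuration bundles genotype parameter blocks, the paradigm
#' specification, sweep settings, the synthetic-cohort specification, an
#' output directory, the master seed and a log level. [load_config()] reads
#' a YAML file, validates it against the schema below, fills defaults (the
#' wild-type parameter set and the standard paradigm) and rejects unknown
#' keys.
#'
#' ```yaml
#' genotypes:
#'   wildtype: {intensity: 0.2, pd1: 0.2, pd2: 0.04,
#'              l_excit: 0.07, l_inhib: 0.014}
#'   knockout: {pd1: 0.11}
#' paradigm:  {cs_moments: 10, us_moments: 5, n_training_trials: 2,
#'             training_iti: 5, test_interval: 5,
#'             test_cs_moments: 6, test_us_moments: 1}
#' sweep:     {from: 0, to: 0.70, by: 0.005}
#' cohort:    {n_per_group: 12, noise: 0.3, seed: 1}
#' out_dir:   results
#' seed:      1
#' log_level: info
#' ```
NULL

.default_config <- function() {
  list(
    genotypes = list(wildtype = unclass(sop_params()),
                     knockout = unclass(sop_params(pd1 = 0.11))),
    paradigm = unclass(novelty_spec()),
    sweep = list(from = 0, to = 0.70, by = 0.005),
    cohort = list(n_per_group = 12L, noise = 0.3, seed = 1L),
    out_dir = "results",
    seed = 1L,
    log_level = "info"
  )
}

# merge user values over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config section `", path, "` must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", ": ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "), call. = FALSE)
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      .merge_config(defaults[[k]], user[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

#' Load and validate a run configuration
#'
#' @param path Path to a YAML configuration file. An empty file (or a file
#'   containing only comments) yields the all-defaults configuration.
#' @return A validated object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  defaults <- .default_config()
  # genotype blocks are user-named: merge each block against parameter
  # defaults rather than against the default genotype names
  if (!is.null(user$genotypes)) {
    if (!is.list(user$genotypes) || is.null(names(user$genotypes)))
      stop("`genotypes` must be a named mapping", call. = FALSE)
    defaults$genotypes <- lapply(user$genotypes, function(block)
      .merge_config(unclass(sop_params()), block, "genotypes"))
    user$genotypes <- NULL
  }
  cfg <- .merge_config(defaults, user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  cfg$genotypes <- lapply(cfg$genotypes, function(g)
    do.call(sop_params, g[c("intensity", "pd1", "pd2",
                            "l_excit", "l_inhib")]))
  cfg$paradigm <- do.call(novelty_spec, cfg$paradigm)
  sw <- cfg$sweep
  if (sw$from < 0 || sw$to >= 1 || sw$by <= 0 || sw$to <= sw$from)
    stop("sweep settings must satisfy 0 <= from < to < 1 and by > 0",
         call. = FALSE)
  cfg$cohort <- cohort_spec(cfg$cohort$n_per_group, cfg$cohort$noise,
                            cfg$cohort$seed)
  if (!cfg$log_level %in% c("quiet", "info", "debug"))
    stop("`log_level` must be one of quiet, info, debug", call. = FALSE)
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("`seed` must be an integer", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Serialise a configuration back to YAML text
#'
#' `dump_config(load_config(f))` is a normalised, defaults-filled rendering
#' of `f`; loading it again reproduces the same configuration.
#'
#' @param cfg A `run_config`.
#' @return A single YAML string.
#' @export
dump_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  plain <- unclass(cfg)
  plain$genotypes <- lapply(plain$genotypes, unclass)
  plain$paradigm <- unclass(plain$paradigm)
  plain$cohort <- unclass(plain$cohort)
  yaml::as.yaml(plain)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(dump_config(x))
  invisible(x)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each data.frame in `results` as `<name>.csv` (fixed column order,
#' no row names) into `out_dir`, plus a `manifest.json` listing the files,
#' an MD5 hash of the normalised configuration and the master seed. Two runs
#' with identical configuration and results produce byte-identical files.
#'
#' @param results Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional `run_config` whose hash and seed are embedded.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(results, out_dir, config = NULL) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(vapply(results, is.data.frame, logical(1))))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(files = sort(files))
  if (!is.null(config)) {
    stopifnot(inherits(config, "run_config"))
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(dump_config(config), tmp)
    manifest$config_md5 <- unname(tools::md5sum(tmp))
    manifest$seed <- config$seed
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
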