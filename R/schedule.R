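#' Stimulus presentation schedule
#'
#' A schedule is a moment-by-moment binary presence matrix for a set of named
#' stimuli. One row per discrete moment, one column per stimulus; an entry of
#' 1 means the stimulus is present at that moment.
#'
#' @param presence A numeric or logical matrix (moments x stimuli) of 0/1
#'   indicators. Column names give the stimulus names; unnamed columns are
#'   named `stim1`, `stim2`, ...
#' @return An object of class `sop_schedule`.
#' @examples
#' # a single 10-moment presentation of one stimulus
#' sop_schedule(matrix(1, nrow = 10, ncol = 1,
#'                     dimnames = list(NULL, "cs")))
#' @export
sop_schedule <- function(presence) {
  if (is.logical(presence)) presence <- presence * 1
  if (!is.matrix(presence) || !is.numeric(presence))
    stop("`presence` must be a numeric matrix (moments x stimuli)",
         call. = FALSE)
  if (nrow(presence) < 1L)
    stop("a schedule needs at least one moment", call. = FALSE)
  if (ncol(presence) < 1L)
    stop("a schedule needs at least one stimulus", call. = FALSE)
  if (!all(presence %in% c(0, 1)))
    stop("presence indicators must be 0 or 1", call. = FALSE)
  if (is.null(colnames(presence)))
    colnames(presence) <- paste0("stim", seq_len(ncol(presence)))
  if (anyDuplicated(colnames(presence)))
    stop("stimulus names must be unique", call. = FALSE)
  structure(list(presence = presence), class = "sop_schedule")
}

#' @rdname sop_schedule
#' @param x An `sop_schedule`.
#' @export
n_moments <- function(x) UseMethod("n_moments")

#' @export
n_moments.sop_schedule <- function(x) nrow(x$presence)

#' @rdname sop_schedule
#' @export
stimuli <- function(x) UseMethod("stimuli")

#' @export
stimuli.sop_schedule <- function(x) colnames(x$presence)

#' @export
print.sop_schedule <- function(x, ...) {
  cat(sprintf("SOP schedule: %d moments, %d stimuli (%s)\n",
              n_moments(x), length(stimuli(x)),
              paste(stimuli(x), collapse = ", ")))
  on <- colSums(x$presence)
  for (s in stimuli(x))
    cat(sprintf("  %s: present %d moments\n", s, as.integer(on[[s]])))
  invisible(x)
}
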