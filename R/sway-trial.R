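#' A single dyadic sway trial
#'
#' Container for one trial's paired head-position time series. `x` and `y`
#' are the two participants' displacements (mm) along one body axis, sampled
#' at `fs` Hz. Condition labels follow the two-letter visual-interaction
#' code: the first letter is participant x's state, the second participant
#' y's state (`O` = eyes open, `B` = blindfolded), so `"BO"` means x is
#' blindfolded and y sighted.
#'
#' @param x,y Numeric series of equal length (>= 2), in mm.
#' @param fs Sampling rate in Hz (> 0).
#' @param axis Body axis, `"AP"` (anterior-posterior) or `"LR"` (left-right).
#' @param distance Interpersonal distance condition, `"Near"` or `"Far"`.
#' @param condition Visual interaction condition: `"OO"`, `"BO"`, `"OB"`
#'   or `"BB"`.
#' @param pair_id,trial_id Identifiers (any scalar).
#' @return An object of class `sway_trial`.
#' @export
sway_trial <- function(x, y, fs, axis = "AP", distance = "Near",
                       condition = "OO", pair_id = 1L, trial_id = 1L) {
  if (!is.numeric(x) || !is.numeric(y)) stop("x and y must be numeric")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("series must have length >= 2")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  structure(
    list(
      x = as.numeric(x), y = as.numeric(y), fs = fs,
      axis = match_vocab(axis, .AXES, "axis"),
      distance = match_vocab(distance, .DISTANCES, "distance"),
      condition = match_vocab(condition, .CONDITIONS, "condition"),
      pair_id = pair_id, trial_id = trial_id
    ),
    class = "sway_trial"
  )
}

#' @export
print.sway_trial <- function(x, ...) {
  cat(sprintf(
    "<sway_trial> pair %s trial %s | %s / %s / %s | %d samples @ %g Hz (%.1f s)\n",
    x$pair_id, x$trial_id, x$axis, x$distance, x$condition,
    length(x$x), x$fs, length(x$x) / x$fs
  ))
  invisible(x)
}
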