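#' Describe a proximity-labeling experiment layout
#'
#' A design pairs the bait (miniTurboID fusion) runs with the negative-control
#' (GFP-miniTurboID) runs of one label-free MS experiment. The number of
#' trials equals the number of bait runs; the study layout is three bait
#' trials against three control trials.
#'
#' @param bait_runs Character vector of run identifiers for the bait trials.
#' @param control_runs Character vector of run identifiers for the
#'   negative-control trials. Must be disjoint from `bait_runs`.
#'
#' @return An `experiment_design` object: a list with elements `bait_runs`,
#'   `control_runs` and `n_trials`.
#' @examples
#' experiment_design(c("bait_1", "bait_2", "bait_3"),
#'                   c("ctrl_1", "ctrl_2", "ctrl_3"))
#' @export
experiment_design <- function(bait_runs, control_runs) {
  bait_runs <- as.character(bait_runs)
  control_runs <- as.character(control_runs)
  if (length(bait_runs) == 0 || length(control_runs) == 0) {
    abort("`bait_runs` and `control_runs` must both be non-empty.")
  }
  if (anyDuplicated(c(bait_runs, control_runs))) {
    abort("Run identifiers must be unique and bait/control runs disjoint.")
  }
  structure(
    list(
      bait_runs = bait_runs,
      control_runs = control_runs,
      n_trials = length(bait_runs)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", x$n_trials, " bait trial(s) vs ",
      length(x$control_runs), " control trial(s)\n", sep = "")
  cat("  bait:    ", paste(x$bait_runs, collapse = ", "), "\n", sep = "")
  cat("  control: ", paste(x$control_runs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

design_runs <- function(design) c(design$bait_runs, design$control_runs)

assert_design <- function(design) {
  if (!inherits(design, "experiment_design")) {
    abort("`design` must be created with `experiment_design()`.")
  }
  invisible(design)
}
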