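check_threshold <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0) || any(t >= 1))
    stopf("threshold probabilities must lie strictly inside (0, 1)")
}

#' Net benefit of a risk model at a threshold probability
#'
#' `(TP - FP * t / (1 - t)) / n`, in true-positive equivalents per
#' participant, where a participant is test-positive when their
#' predicted risk is at or above the threshold (`p >= t`; ties count as
#' positive).
#'
#' @param y Binary outcome vector (0/1).
#' @param p Predicted risks.
#' @param t Threshold probability in (0, 1) (vectorized).
#' @return Net benefit, one value per threshold.
#' @export
net_benefit <- function(y, p, t) {
  check_threshold(t)
  if (length(y) != length(p)) stopf("y and p must have equal length")
  n <- length(y)
  vapply(t, function(ti) {
    pos <- p >= ti
    tp <- sum(y == 1 & pos)
    fp <- sum(y == 0 & pos)
    (tp - fp * ti / (1 - ti)) / n
  }, numeric(1))
}

#' Net benefit of the treat-all strategy
#'
#' `phi - (1 - phi) * t / (1 - t)`; crosses zero exactly at the
#' prevalence threshold `t = phi`. Treat-none has net benefit 0 at
#' every threshold.
#'
#' @param phi Outcome prevalence.
#' @param t Threshold probability in (0, 1) (vectorized).
#' @return Net benefit of screening everyone.
#' @export
net_benefit_treat_all <- function(phi, t) {
  check_threshold(t)
  stopifnot(phi >= 0, phi <= 1)
  phi - (1 - phi) * t / (1 - t)
}

#' Net reduction in investigations per 100 participants
#'
#' How many confirmatory investigations the model avoids, relative to
#' investigating everyone, without missing additional cases:
#' `(NB_model - NB_all) / (t / (1 - t)) * 100`.
#'
#' @inheritParams net_benefit
#' @return Net investigations avoided per 100 participants, per
#'   threshold; negative when the model is worse than treat-all.
#' @export
net_reduction_per100 <- function(y, p, t) {
  check_threshold(t)
  nb <- net_benefit(y, p, t)
  nb_all <- net_benefit_treat_all(mean(y), t)
  (nb - nb_all) / (t / (1 - t)) * 100
}

#' Decision curve over a threshold grid
#'
#' Tabulates model, treat-all and treat-none net benefit plus the net
#' reduction in investigations per 100 participants over a grid of
#' threshold probabilities. The default grid 0.01-0.60 (step 0.01)
#' covers the clinically discussed 10-50% range with margin.
#'
#' @inheritParams net_benefit
#' @param grid Sorted vector of thresholds inside (0, 1).
#' @return A data frame of class `decision_curve` with columns
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`, `avoided_per100`;
#'   the prevalence is attached as attribute `prevalence`.
#' @export
decision_curve <- function(y, p, grid = seq(0.01, 0.60, by = 0.01)) {
  if (length(grid) == 0L) stopf("threshold grid must be non-empty")
  check_threshold(grid)
  if (is.unsorted(grid)) stopf("threshold grid must be sorted ascending")
  phi <- mean(y)
  nb <- net_benefit(y, p, grid)
  nb_all <- net_benefit_treat_all(phi, grid)
  out <- data.frame(
    threshold = grid,
    nb_model = nb,
    nb_all = nb_all,
    nb_none = 0,
    avoided_per100 = (nb - nb_all) / (grid / (1 - grid)) * 100
  )
  attr(out, "prevalence") <- phi
  class(out) <- c("decision_curve", "data.frame")
  out
}
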