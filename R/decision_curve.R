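#' Decision curve analysis
#'
#' Net benefit of treating patients whose predicted responder probability
#' exceeds a risk threshold t:
#' `NB(t) = TP(t)/N - FP(t)/N * t/(1-t)`, with the standardized net benefit
#' `sNB = NB / prevalence`. Reference curves: treat-none (`NB = 0`) and
#' treat-all (`NB(t) = prevalence - (1 - prevalence) * t/(1-t)`).
#' Classification at a threshold is `score >= t`.
#'
#' @param scores responder scores in `[0, 1]`; map a scaled-rate prediction
#'   with [scaled_to_probability()].
#' @param labels binary responder labels (see [auc_rank()]).
#' @param thresholds threshold grid in `(0, 1)`; `t = 1` is excluded
#'   (division by zero).
#' @return tibble of class `decision_curve`: `threshold`, `model` (one of
#'   `"model"`, `"treat_all"`, `"treat_none"`), `net_benefit`,
#'   `standardized_nb`; prevalence as attribute.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  n <- length(y)
  prev <- mean(y)
  rows <- purrr::map(thresholds, function(t) {
    treat <- scores >= t
    tp <- sum(treat & y == 1)
    fp <- sum(treat & y == 0)
    w <- t / (1 - t)
    nb_model <- tp / n - fp / n * w
    nb_all <- prev - (1 - prev) * w
    tibble::tibble(
      threshold = t,
      model = c("model", "treat_all", "treat_none"),
      net_benefit = c(nb_model, nb_all, 0)
    )
  }) |> purrr::list_rbind()
  rows$standardized_nb <- rows$net_benefit / prev
  attr(rows, "prevalence") <- prev
  class(rows) <- c("decision_curve", class(rows))
  rows
}

#' Map scaled-rate predictions to `[0, 1]` responder scores
#'
#' The response models regress the scaled reduction rate in `[-1, 1]`; for
#' decision curves the prediction is mapped by the invertible affine
#' `(scaled + 1) / 2` (inverse `2 * p - 1`).
#'
#' @param scaled predictions on the `[-1, 1]` scale.
#' @return scores in `[0, 1]`.
#' @export
scaled_to_probability <- function(scaled) {
  pmin(pmax((scaled + 1) / 2, 0), 1)
}

#' @export
autoplot.decision_curve <- function(object, ...) {
  prev <- attr(object, "prevalence")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold,
                               y = .data$standardized_nb,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.2, 1.05)) +
    ggplot2::labs(x = "risk threshold", y = "standardized net benefit",
                  colour = NULL,
                  title = sprintf("Decision curve (prevalence %.2f)", prev)) +
    ggplot2::theme_minimal()
}
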