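#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-sample geometry of a fitted loop
#'
#' @param x A `polar_loop` from [polar_loop()].
#' @param ... Unused.
#' @return Tibble with one row per sample: `individual`, `time`, `x`, `y`
#'   (normalised units), `angle`, `radius`, `angle_unwrapped`, `time_rank`.
#' @export
tidy.polar_loop <- function(x, ...) {
  tibble::as_tibble(x$points)
}

#' One-row summary of a fitted loop
#'
#' @param x A `polar_loop`.
#' @param ... Unused.
#' @return Tibble with `lead_gene`, `lag_gene`, `center_x`, `center_y`,
#'   `radius_variance`, `angle_time_rho`, `n`.
#' @export
glance.polar_loop <- function(x, ...) {
  tibble::tibble(
    lead_gene = x$lead_gene, lag_gene = x$lag_gene,
    center_x = x$center[["x"]], center_y = x$center[["y"]],
    radius_variance = x$radius_variance,
    angle_time_rho = x$angle_time_rho,
    n = nrow(x$points)
  )
}

#' Tidy per-sample prediction results
#'
#' @param x A `stage_prediction` from [evaluate_predictions()] or
#'   [predict_stage()].
#' @param ... Unused.
#' @return The per-sample tibble (`truth`, `predicted`, `correct`, plus any
#'   sample info columns).
#' @export
tidy.stage_prediction <- function(x, ...) {
  x$samples
}

#' One-row summary of a prediction run
#'
#' @param x A `stage_prediction`.
#' @param ... Unused.
#' @return Tibble with `n` and `accuracy`.
#' @export
glance.stage_prediction <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy)
}

#' Summary of a leave-one-individual-out run
#'
#' @param x A `loocv_result` from [loocv()].
#' @param ... Unused.
#' @return Tibble with `n_individuals`, `min`, `median`, `max` accuracy.
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x),
    min = min(x$accuracy),
    median = stats::median(x$accuracy),
    max = max(x$accuracy)
  )
}
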