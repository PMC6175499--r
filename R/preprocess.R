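#' Impute missing time points from other individuals
#'
#' In longitudinal cohorts individual samples are often missing whole time
#' points. For every individual lacking a grid time, each gene's value is
#' imputed as the median of that gene at that time across the individuals that
#' were observed there. Observed values are never altered.
#'
#' @param data Long expression tibble (see [validate_expression_data()]).
#' @param grid Numeric vector of time points every individual should cover.
#'   Defaults to all times observed anywhere in `data`.
#' @return A long expression tibble in which every individual has a sample at
#'   every grid time; imputed rows are flagged in the logical column
#'   `imputed`.
#' @export
impute_missing_timepoints <- function(data, grid = NULL) {
  data <- validate_expression_data(data)
  if (is.null(grid)) grid <- sort(unique(data$time))
  grid <- sort(unique(as.numeric(grid)))

  unobserved <- setdiff(grid, unique(data$time))
  if (length(unobserved) > 0) {
    stop("grid time ", format(unobserved[1]),
         " is observed in no individual", call. = FALSE)
  }

  data <- dplyr::mutate(data, imputed = FALSE)
  medians <- data |>
    dplyr::filter(.data$time %in% grid) |>
    dplyr::summarise(value = stats::median(.data$value), .by = c("gene", "time"))

  full <- tidyr::expand_grid(individual = unique(data$individual), time = grid)
  observed <- dplyr::distinct(data, .data$individual, .data$time)
  gaps <- dplyr::anti_join(full, observed, by = c("individual", "time"))
  if (nrow(gaps) == 0) return(data)

  filled <- gaps |>
    dplyr::left_join(medians, by = "time", relationship = "many-to-many") |>
    dplyr::mutate(imputed = TRUE) |>
    dplyr::select("gene", "individual", "time", "value", "imputed")

  out <- dplyr::bind_rows(data, filled) |>
    dplyr::arrange(.data$gene, .data$individual, .data$time)
  validate_expression_data(out)
  out
}

#' Rescale every time course to its baseline
#'
#' Subtracts the time-0 value from every value of the same gene's series, so
#' all series start at 0. For per-individual data each `(gene, individual)`
#' series is centred independently; for a composite profile
#' (`gene`, `time`, `value`) each gene's series is centred. Centring is
#' idempotent.
#'
#' @param data Long expression tibble or composite profile tibble.
#' @return Same shape as the input, baseline-centred.
#' @export
center_to_baseline <- function(data) {
  data <- tibble::as_tibble(data)
  per_individual <- "individual" %in% names(data)
  groups <- if (per_individual) c("gene", "individual") else "gene"
  stopifnot(all(c(groups, "time", "value") %in% names(data)))
  t0 <- min(data$time)

  centred <- data |>
    dplyr::mutate(
      .baseline = {
        b <- .data$value[.data$time == t0]
        if (length(b) != 1) NA_real_ else b
      },
      .by = dplyr::all_of(groups)
    )
  if (anyNA(centred$.baseline)) {
    bad <- centred[is.na(centred$.baseline), ][1, ]
    if (per_individual) {
      stop(sprintf("individual '%s' has no time-%s sample for gene '%s'",
                   bad$individual, format(t0), bad$gene), call. = FALSE)
    }
    stop(sprintf("gene '%s' has no baseline (time %s) value",
                 bad$gene, format(t0)), call. = FALSE)
  }
  centred |>
    dplyr::mutate(value = .data$value - .data$.baseline) |>
    dplyr::select(-".baseline")
}

#' Composite median profile across individuals
#'
#' Collapses a cohort to one representative time course per gene: the median
#' across individuals at each time point, then centred to the time-0
#' baseline. Fewer than six time points triggers a warning (two variables
#' rising and falling out of phase need at least four samples to be resolved,
#' and six is the working minimum for dataset selection), but the profile is
#' still computed.
#'
#' @param data Long expression tibble. The median at each time point is taken
#'   over the individuals observed there, so the input need not be a complete
#'   grid (a training split usually is not); run
#'   [impute_missing_timepoints()] first when a complete grid is wanted.
#' @return A composite profile tibble with columns `gene`, `time`, `value`
#'   (median log2 expression, baseline-centred).
#' @export
composite_profile <- function(data) {
  data <- validate_expression_data(data)
  times <- sort(unique(data$time))
  if (length(times) < 6) {
    warning(sprintf("only %d time points; loop detection works best with 6 or more",
                    length(times)), call. = FALSE)
  }
  data |>
    dplyr::summarise(value = stats::median(.data$value), .by = c("gene", "time")) |>
    dplyr::arrange(.data$gene, .data$time) |>
    center_to_baseline()
}

#' Select the most dynamic genes of a composite profile
#'
#' Ranks genes by the dispersion of their composite time course and keeps the
#' top fraction, the step that reduces a whole-transcriptome profile to the
#' dynamic subset worth scanning for phase shifts. The number kept is
#' `ceiling(top_fraction * n_genes)`; with the default 0.5% this selects 95 of
#' 18859 genes and 91 of 18197. Ties at the cutoff are broken by gene symbol
#' so the selection is deterministic.
#'
#' @param profile Composite profile tibble (`gene`, `time`, `value`).
#' @param top_fraction Fraction of genes to keep, in (0, 1]. Default 0.005.
#' @param statistic Dispersion statistic: `"stdev"` (population standard
#'   deviation over the time points, the default) or `"range"` (max minus
#'   min).
#' @return Character vector of selected gene symbols, highest dispersion
#'   first.
#' @export
filter_top_dynamic <- function(profile, top_fraction = 0.005,
                               statistic = c("stdev", "range")) {
  statistic <- match.arg(statistic)
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("gene", "time", "value") %in% names(profile)))
  if (!is.numeric(top_fraction) || length(top_fraction) != 1 ||
      top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be a single number in (0, 1]", call. = FALSE)
  }
  n_genes <- dplyr::n_distinct(profile$gene)
  if (n_genes == 0) stop("profile contains no genes", call. = FALSE)

  disp_fun <- switch(statistic,
    stdev = function(x) sqrt(mean((x - mean(x))^2)),
    range = function(x) max(x) - min(x)
  )
  n_keep <- ceiling(top_fraction * n_genes)
  profile |>
    dplyr::summarise(dispersion = disp_fun(.data$value), .by = "gene") |>
    dplyr::arrange(dplyr::desc(.data$dispersion), .data$gene) |>
    dplyr::slice_head(n = n_keep) |>
    dplyr::pull("gene")
}
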