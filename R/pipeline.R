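#' Split samples into training and test sets, stratified by time
#'
#' Draws approximately `fraction` of the (individual, time) samples at every
#' time point into the training set — "randomly but evenly", so every time
#' point is covered on both sides of the split. The per-time training count
#' is `round(fraction * n_t)`, always within one sample of the exact target.
#'
#' @param data Long expression tibble.
#' @param fraction Training fraction in (0, 1). Default 0.5.
#' @param seed Integer seed.
#' @return List with `train` and `test` long expression tibbles.
#' @export
split_stratified_by_time <- function(data, fraction = 0.5, seed = 1) {
  data <- tibble::as_tibble(data)
  stopifnot(fraction > 0, fraction < 1)
  samples <- dplyr::distinct(data, .data$individual, .data$time)
  train_keys <- withr::with_seed(seed, {
    samples |>
      dplyr::group_by(.data$time) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::filter(dplyr::row_number() <= round(fraction * dplyr::n())) |>
      dplyr::ungroup()
  })
  split_by_keys(data, train_keys)
}

#' Split a cohort by individual
#'
#' @param data Long expression tibble.
#' @param test_individuals Individual IDs forming the test set; everyone else
#'   trains.
#' @return List with `train` and `test` long expression tibbles.
#' @export
split_by_individual <- function(data, test_individuals) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(test_individuals, unique(data$individual))
  if (length(missing) > 0) {
    stop("unknown individual(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  list(train = dplyr::filter(data, !.data$individual %in% test_individuals),
       test = dplyr::filter(data, .data$individual %in% test_individuals))
}

split_by_keys <- function(data, train_keys) {
  keyed <- paste(data$individual, data$time, sep = "\r")
  train_id <- paste(train_keys$individual, train_keys$time, sep = "\r")
  list(train = data[keyed %in% train_id, ],
       test = data[!keyed %in% train_id, ])
}

#' Screen a longitudinal cohort for phase-shifted looping gene pairs
#'
#' The full discovery pipeline: impute missing time points, centre every
#' series to baseline, split into training and test samples, build the
#' composite median profile of the training set, keep the most dynamic
#' genes, convert them to SAX words, enumerate quarter-period phase-shifted
#' pairs, and score each candidate by its held-out prediction accuracy and
#' its angle-time correlation. Candidates are ranked by accuracy, then by
#' correlation.
#'
#' @param data Long expression tibble.
#' @param top_fraction,dispersion_statistic Passed to [filter_top_dynamic()].
#' @param alphabet_size,word_length,shift_symbols Passed to
#'   [sax_transform()].
#' @param max_distance Passed to [find_phase_shifted_pairs()].
#' @param k Neighbours for the holdout scoring.
#' @param split Either `list(random_fraction = f)` for a time-stratified
#'   random split or `list(by_individual = ids)` holding out whole
#'   individuals. Default a stratified 50% split.
#' @param stage_map,excluded_times Passed to [predict_stage()].
#' @param grid Time grid for imputation; default all observed times.
#' @param grid_resolution Polar centre search resolution.
#' @param seed Integer seed (drives the random split).
#' @param verbose Log each stage's input/output counts. Default `TRUE`.
#' @return Object of class `loop_screen`: tibble with `lead_gene`,
#'   `lag_gene`, `match_distance`, `holdout_accuracy`, `angle_time_rho`,
#'   ranked best first. Attributes carry the filtered gene list and the
#'   split.
#' @export
find_loops <- function(data, top_fraction = 0.005,
                       dispersion_statistic = c("stdev", "range"),
                       alphabet_size = 4, word_length = NULL,
                       shift_symbols = NULL, max_distance = 0, k = 3,
                       split = list(random_fraction = 0.5),
                       stage_map = NULL, excluded_times = NULL, grid = NULL,
                       grid_resolution = 101, seed = 1, verbose = TRUE) {
  dispersion_statistic <- match.arg(dispersion_statistic)
  say <- function(...) if (verbose) message("find_loops: ", sprintf(...))
  data <- validate_expression_data(data)
  if (!is.null(excluded_times)) {
    data <- dplyr::filter(data, !.data$time %in% excluded_times)
  }
  say("%d genes x %d samples in", dplyr::n_distinct(data$gene),
      nrow(dplyr::distinct(data, .data$individual, .data$time)))

  data <- impute_missing_timepoints(data, grid = grid)
  say("imputed %d missing sample value(s)", sum(data$imputed))
  data <- center_to_baseline(dplyr::select(data, -"imputed"))

  if (length(names(split)) != 1 ||
      !names(split) %in% c("random_fraction", "by_individual")) {
    stop("split must be list(random_fraction = f) or list(by_individual = ids)",
         call. = FALSE)
  }
  parts <- if (names(split) == "random_fraction") {
    split_stratified_by_time(data, split$random_fraction, seed = seed)
  } else {
    split_by_individual(data, split$by_individual)
  }
  say("split: %d training / %d test samples",
      nrow(dplyr::distinct(parts$train, .data$individual, .data$time)),
      nrow(dplyr::distinct(parts$test, .data$individual, .data$time)))

  profile <- composite_profile(parts$train)
  keep <- filter_top_dynamic(profile, top_fraction, dispersion_statistic)
  say("filtered to %d dynamic gene(s)", length(keep))

  words <- sax_transform(dplyr::filter(profile, .data$gene %in% keep),
                         alphabet_size = alphabet_size,
                         word_length = word_length,
                         shift_symbols = shift_symbols)
  candidates <- find_phase_shifted_pairs(words, max_distance = max_distance)
  say("%d phase-shifted candidate pair(s)", nrow(candidates))

  scored <- candidates |>
    dplyr::mutate(
      holdout_accuracy = purrr::map2_dbl(.data$lead_gene, .data$lag_gene,
        function(a, b) {
          predict_stage(parts$train, parts$test, a, b, k = k,
                        stage_map = stage_map)$accuracy
        }),
      angle_time_rho = purrr::map2_dbl(.data$lead_gene, .data$lag_gene,
        function(a, b) {
          tryCatch(polar_loop(parts$train, a, b,
                              grid_resolution = grid_resolution)$angle_time_rho,
                   error = function(e) NA_real_)
        })
    ) |>
    dplyr::arrange(dplyr::desc(.data$holdout_accuracy),
                   dplyr::desc(.data$angle_time_rho),
                   .data$lead_gene, .data$lag_gene)

  structure(scored, class = c("loop_screen", class(scored)),
            filtered_genes = keep, train = parts$train, test = parts$test,
            seed = seed)
}

#' @export
print.loop_screen <- function(x, ...) {
  cat(sprintf("<loop_screen> %d candidate pair(s) from %d filtered gene(s)\n",
              nrow(x), length(attr(x, "filtered_genes"))))
  NextMethod()
}
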