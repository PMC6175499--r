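#' K-nearest-neighbour prediction on the two-gene plane
#'
#' Labels each test point by majority vote of its `k` nearest training points
#' under Euclidean distance in the raw two-gene expression space. Distance
#' ties are resolved by training-point input order (stable sort); a tied vote
#' is resolved in favour of the tied label whose nearest representative is
#' closest (which is the single nearest neighbour's label whenever that label
#' is among the tied winners). Both rules make predictions deterministic.
#'
#' @param train Data frame with numeric `x`, `y` and a `label` column.
#' @param test Data frame with numeric `x`, `y`.
#' @param k Number of neighbours. Default 3.
#' @param return_neighbors If `TRUE`, also return each test point's neighbour
#'   labels as a list-column.
#' @return Character vector of predicted labels, or (with
#'   `return_neighbors = TRUE`) a tibble with `predicted` and `neighbors`.
#' @export
knn_predict <- function(train, test, k = 3, return_neighbors = FALSE) {
  train <- tibble::as_tibble(train)
  test <- tibble::as_tibble(test)
  stopifnot(all(c("x", "y", "label") %in% names(train)),
            all(c("x", "y") %in% names(test)))
  if (nrow(train) < k) {
    stop(sprintf("training set has %d point(s) but k = %d", nrow(train), k),
         call. = FALSE)
  }
  labels <- as.character(train$label)

  one <- function(px, py) {
    d <- sqrt((train$x - px)^2 + (train$y - py)^2)
    nn <- order(d)[seq_len(k)]          # stable: distance ties keep input order
    labs <- labels[nn]
    counts <- table(labs)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) {
      pred <- winners
    } else {
      pred <- winners[which.min(match(winners, labs))]
    }
    list(pred = pred, labs = labs)
  }

  res <- purrr::map2(test$x, test$y, one)
  predicted <- vapply(res, `[[`, character(1), "pred")
  if (return_neighbors) {
    tibble::tibble(predicted = predicted,
                   neighbors = purrr::map(res, "labs"))
  } else {
    predicted
  }
}

#' Stage map for a 0-28 day vaccination time course
#'
#' Maps sampling days to perturbation stages: day 3 is the early response,
#' day 7 the middle, day 10 the late response, while days 0, 14 and 28 are
#' interchangeable baseline ("base") because expression has returned to
#' pre-perturbation levels by two weeks.
#'
#' @return Named character vector mapping time (as character) to stage label.
#' @export
stage_map_vaccination <- function() {
  c(`0` = "base", `3` = "early", `7` = "middle", `10` = "late",
    `14` = "base", `28` = "base")
}

# Map a vector of time-like labels through a stage map; error on gaps.
apply_stage_map <- function(labels, stage_map) {
  key <- as.character(labels)
  # numeric labels: normalise "7.0" and "7" to the same key
  num <- suppressWarnings(as.numeric(key))
  key[!is.na(num)] <- format(num[!is.na(num)], trim = TRUE, scientific = FALSE,
                             drop0trailing = TRUE)
  unmapped <- setdiff(unique(key), names(stage_map))
  if (length(unmapped) > 0) {
    stop("no stage mapping for time ", unmapped[1], call. = FALSE)
  }
  unname(stage_map[key])
}

#' Score predictions against truth, optionally through a stage map
#'
#' Computes per-sample correctness, the confusion matrix and overall accuracy.
#' When a stage map is supplied both true and predicted labels are mapped
#' first, so times that belong to the same stage (for instance baseline days
#' 0, 14 and 28) count as interchangeable.
#'
#' @param truth Vector of true labels (times or stages).
#' @param predicted Vector of predicted labels, same length.
#' @param stage_map Optional named character vector (see
#'   [stage_map_vaccination()]); `NULL` compares labels as given.
#' @param info Optional data frame (for example `individual`, `time`) bound
#'   alongside the per-sample results.
#' @return Object of class `stage_prediction`: list with `samples` (tibble of
#'   `truth`, `predicted`, `correct`), `confusion` (table, truth in rows),
#'   `accuracy`, `n`.
#' @export
evaluate_predictions <- function(truth, predicted, stage_map = NULL, info = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ", call. = FALSE)
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (!is.null(stage_map)) {
    truth <- apply_stage_map(truth, stage_map)
    predicted <- apply_stage_map(predicted, stage_map)
  }
  lev <- sort(unique(c(truth, predicted)))
  confusion <- table(truth = factor(truth, lev), predicted = factor(predicted, lev))
  samples <- tibble::tibble(truth = truth, predicted = predicted,
                            correct = truth == predicted)
  if (!is.null(info)) samples <- dplyr::bind_cols(tibble::as_tibble(info), samples)
  structure(
    list(samples = samples, confusion = confusion,
         accuracy = mean(samples$correct), n = length(truth)),
    class = "stage_prediction"
  )
}

#' @export
print.stage_prediction <- function(x, ...) {
  cat(sprintf("<stage_prediction> %d samples, accuracy %.3f\n", x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Predict time or stage of test samples from a gene-pair loop
#'
#' Trains the k-nearest-neighbour classifier on the training samples'
#' coordinates in the pair's two-gene plane (labels are the sampling times)
#' and scores its predictions on the test samples. With a stage map, times
#' are collapsed to stages before scoring.
#'
#' @param train,test Long expression tibbles containing both genes.
#' @param lead_gene,lag_gene The gene pair defining the plane.
#' @param k Neighbours for [knn_predict()]. Default 3.
#' @param stage_map Optional stage map for [evaluate_predictions()].
#' @param excluded_times Times dropped from both sets before training and
#'   scoring (for instance a final time point far past resolution).
#' @return A `stage_prediction` object whose `samples` tibble carries
#'   `individual` and `time`.
#' @export
predict_stage <- function(train, test, lead_gene, lag_gene, k = 3,
                          stage_map = NULL, excluded_times = NULL) {
  if (!is.null(excluded_times)) {
    train <- dplyr::filter(train, !.data$time %in% excluded_times)
    test <- dplyr::filter(test, !.data$time %in% excluded_times)
  }
  tr <- pair_coordinates(train, lead_gene, lag_gene) |>
    dplyr::mutate(label = format_time_label(.data$time))
  te <- pair_coordinates(test, lead_gene, lag_gene)
  predicted <- knn_predict(tr, te, k = k)
  evaluate_predictions(format_time_label(te$time), predicted,
                       stage_map = stage_map,
                       info = dplyr::select(te, "individual", "time"))
}

format_time_label <- function(time) {
  format(time, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

#' Leave-one-individual-out cross-validation of a gene-pair loop
#'
#' For each individual: train the classifier on all other individuals and
#' score the held-out individual's samples. A tight accuracy range across
#' individuals indicates the loop generalises and no individual is an
#' outlier.
#'
#' @param data Long expression tibble with at least 2 individuals.
#' @param lead_gene,lag_gene The gene pair.
#' @param k,stage_map,excluded_times As in [predict_stage()].
#' @return Object of class `loocv_result`: tibble with one row per individual
#'   (`individual`, `n`, `accuracy`) plus summary attributes; see
#'   [glance.loocv_result()].
#' @export
loocv <- function(data, lead_gene, lag_gene, k = 3, stage_map = NULL,
                  excluded_times = NULL) {
  data <- tibble::as_tibble(data)
  individuals <- unique(data$individual)
  if (length(individuals) < 2) {
    stop("leave-one-individual-out needs at least 2 individuals", call. = FALSE)
  }
  rows <- purrr::map(individuals, function(ind) {
    pred <- predict_stage(dplyr::filter(data, .data$individual != ind),
                          dplyr::filter(data, .data$individual == ind),
                          lead_gene, lag_gene, k = k, stage_map = stage_map,
                          excluded_times = excluded_times)
    tibble::tibble(individual = ind, n = pred$n, accuracy = pred$accuracy)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("loocv_result", class(out)),
            lead_gene = lead_gene, lag_gene = lag_gene)
}

#' Sensitivity of loop predictions to measurement noise
#'
#' Estimates each gene's per-time-point standard deviation from the training
#' cohort, then repeatedly adds zero-mean Gaussian noise with those standard
#' deviations to the test coordinates and re-predicts. Reports the noiseless
#' accuracy alongside the mean accuracy over replicates, measuring how robust
#' the loop map is to out-of-sample measurement noise.
#'
#' @param train,test Long expression tibbles.
#' @param lead_gene,lag_gene The gene pair.
#' @param k,stage_map,excluded_times As in [predict_stage()].
#' @param n_reps Noise replicates. Default 100.
#' @param noise_scale Multiplier on the estimated standard deviations
#'   (0 disables noise entirely). Default 1.
#' @param seed Integer seed making the replicates reproducible.
#' @return List with `noiseless_accuracy`, `noisy_accuracy` (mean over
#'   replicates), and `rep_accuracies`.
#' @export
noise_sensitivity <- function(train, test, lead_gene, lag_gene, k = 3,
                              stage_map = NULL, excluded_times = NULL,
                              n_reps = 100, noise_scale = 1, seed = 1) {
  if (!is.null(excluded_times)) {
    train <- dplyr::filter(train, !.data$time %in% excluded_times)
    test <- dplyr::filter(test, !.data$time %in% excluded_times)
  }
  tr <- pair_coordinates(train, lead_gene, lag_gene) |>
    dplyr::mutate(label = format_time_label(.data$time))
  te <- pair_coordinates(test, lead_gene, lag_gene)

  base_eval <- evaluate_predictions(format_time_label(te$time),
                                    knn_predict(tr, te, k = k),
                                    stage_map = stage_map)

  sds <- train |>
    dplyr::filter(.data$gene %in% c(lead_gene, lag_gene)) |>
    dplyr::summarise(sd = stats::sd(.data$value), .by = c("gene", "time")) |>
    dplyr::mutate(sd = dplyr::coalesce(.data$sd, 0))
  sd_of <- function(g, t) {
    s <- sds$sd[sds$gene == g][match(t, sds$time[sds$gene == g])]
    dplyr::coalesce(s, 0)
  }
  sd_x <- sd_of(lead_gene, te$time) * noise_scale
  sd_y <- sd_of(lag_gene, te$time) * noise_scale

  rep_accuracies <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      noisy <- dplyr::mutate(te,
        x = .data$x + stats::rnorm(dplyr::n(), 0, sd_x),
        y = .data$y + stats::rnorm(dplyr::n(), 0, sd_y))
      evaluate_predictions(format_time_label(te$time),
                           knn_predict(tr, noisy, k = k),
                           stage_map = stage_map)$accuracy
    }, numeric(1))
  })
  list(noiseless_accuracy = base_eval$accuracy,
       noisy_accuracy = mean(rep_accuracies),
       rep_accuracies = rep_accuracies)
}

#' Compare loop-pair accuracy against randomly sampled gene pairs
#'
#' Computes the held-out prediction accuracy of every candidate loop pair and
#' of `n_random` gene pairs sampled uniformly (without replacement) from the
#' non-candidate pairs of `genes`, then compares the two accuracy
#' distributions with a two-sample Kolmogorov-Smirnov test. Candidate pairs
#' separating cleanly from random pairs is the evidence that loop structure,
#' not chance, drives prediction.
#'
#' @param train,test Long expression tibbles (a fixed holdout split; every
#'   pair is scored on the same split).
#' @param genes Pool of gene symbols to draw random pairs from.
#' @param candidates Tibble with `lead_gene`, `lag_gene` (for example from
#'   [find_phase_shifted_pairs()]); at least 2 rows.
#' @param n_random Number of random non-candidate pairs (>= 10). Default 50.
#' @param k,stage_map,excluded_times As in [predict_stage()].
#' @param seed Integer seed for the random pair draw.
#' @param exact Use the exact KS p-value computation instead of the
#'   asymptotic formula. Default `FALSE`.
#' @return List with `candidate_accuracy`, `random_accuracy`,
#'   `random_pairs`, `ks_statistic`, `p_value`.
#' @export
random_pair_null <- function(train, test, genes, candidates, n_random = 50,
                             k = 3, stage_map = NULL, excluded_times = NULL,
                             seed = 1, exact = FALSE) {
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) < 2) stop("need at least 2 candidate pairs", call. = FALSE)
  if (n_random < 10) stop("n_random must be at least 10", call. = FALSE)

  genes <- sort(unique(genes))
  all_pairs <- t(utils::combn(genes, 2))
  cand_key <- c(paste(candidates$lead_gene, candidates$lag_gene, sep = "\r"),
                paste(candidates$lag_gene, candidates$lead_gene, sep = "\r"))
  pool <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2], sep = "\r") %in% cand_key), ,
                    drop = FALSE]
  if (nrow(pool) < n_random) {
    stop(sprintf("only %d non-candidate pairs available but n_random = %d",
                 nrow(pool), n_random), call. = FALSE)
  }
  picked <- withr::with_seed(seed, pool[sample.int(nrow(pool), n_random), , drop = FALSE])

  acc <- function(lead, lag) {
    predict_stage(train, test, lead, lag, k = k, stage_map = stage_map,
                  excluded_times = excluded_times)$accuracy
  }
  candidate_accuracy <- purrr::map2_dbl(candidates$lead_gene,
                                        candidates$lag_gene, acc)
  random_accuracy <- purrr::map2_dbl(picked[, 1], picked[, 2], acc)

  ks <- suppressWarnings(stats::ks.test(candidate_accuracy, random_accuracy,
                                        exact = exact))
  list(candidate_accuracy = candidate_accuracy,
       random_accuracy = random_accuracy,
       random_pairs = tibble::tibble(lead_gene = picked[, 1], lag_gene = picked[, 2]),
       ks_statistic = unname(ks$statistic),
       p_value = ks$p.value)
}
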