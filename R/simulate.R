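#' Simulate a longitudinal cohort with planted looping gene pairs
#'
#' Generates a multi-individual expression time course emulating the
#' structure of a self-resolving inflammatory response: a background of
#' static genes plus planted gene pairs whose pulse-shaped profiles rise from
#' baseline, peak and return, with the lag partner delayed by a quarter of
#' the time points (so the pair traces a loop). Pulses are raised-cosine
#' windows on the time-*rank* axis: sampling grids in this field are uneven,
#' and rank-based pulses make the planted lag an exact whole number of
#' samples, aligning with the one-symbol-per-time-point SAX words. The pulse
#' support is kept inside the grid so the lag partner's value multiset equals
#' the lead's — at zero noise their SAX words are then exact shifted copies
#' and recovery is guaranteed. Successive planted pairs cycle through
#' different pulse peaks/widths so distinct pairs are symbolically
#' distinguishable.
#'
#' Per-individual values are the shared pulse plus a per-gene individual
#' offset (`individual_sd`) plus i.i.d. Gaussian noise (`noise_sd`);
#' background genes get small-amplitude Gaussian noise (`background_sd`)
#' around a baseline of 0. Optionally a fraction of whole (individual, time)
#' samples is deleted (never emptying a time point entirely).
#'
#' @param n_individuals Individuals in the cohort. Default 12.
#' @param n_background_genes Static background genes. Default 500.
#' @param n_planted_pairs Planted looping pairs. Default 3.
#' @param times Sampling grid; default the 9-point 0-48 h inflammation grid
#'   `c(0, 2, 2.5, 3, 3.5, 4, 14, 24, 48)`.
#' @param lag_fraction Lag between pair members as a fraction of the number
#'   of time points; default 0.25 (a 90-degree phase shift). The lag in
#'   samples is `round(lag_fraction * T)` and must round to 1..T-1.
#' @param pulse_amplitude Peak height of the pulse in log2 units. Default 2.
#' @param noise_sd I.i.d. Gaussian noise on planted-gene values. Default 0.2.
#' @param individual_sd Sd of the per-gene, per-individual additive offset.
#'   Default 0.1.
#' @param background_sd Sd of background-gene noise. Default 0.05.
#' @param missing_fraction Fraction of (individual, time) samples deleted.
#'   Default 0.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return List with `data` (long expression tibble) and `truth` (list with
#'   `pairs`, a tibble of `lead_gene`, `lag_gene`, `peak_rank`, `half_width`,
#'   and `lag_samples`).
#' @export
simulate_loops <- function(n_individuals = 12, n_background_genes = 500,
                           n_planted_pairs = 3,
                           times = c(0, 2, 2.5, 3, 3.5, 4, 14, 24, 48),
                           lag_fraction = 0.25, pulse_amplitude = 2,
                           noise_sd = 0.2, individual_sd = 0.1,
                           background_sd = 0.05, missing_fraction = 0,
                           seed = 1) {
  stopifnot(n_individuals >= 1, n_background_genes >= 1, n_planted_pairs >= 1,
            pulse_amplitude > 0, noise_sd >= 0, individual_sd >= 0,
            background_sd >= 0, missing_fraction >= 0, missing_fraction < 1)
  times <- sort(unique(times))
  t_len <- length(times)
  if (t_len < 2) stop("need at least 2 time points", call. = FALSE)
  lag <- round(lag_fraction * t_len)
  if (lag < 1 || lag >= t_len) {
    stop(sprintf("lag of %d samples (lag_fraction %g over %d time points) is ",
                 lag, lag_fraction, t_len),
         "degenerate; it must round to 1..T-1", call. = FALSE)
  }

  shapes <- pulse_shapes(t_len, lag)
  ranks <- seq_len(t_len) - 1L

  withr::with_seed(seed, {
    individuals <- sprintf("I%02d", seq_len(n_individuals))
    bg_genes <- sprintf("BG%04d", seq_len(n_background_genes))

    pairs <- purrr::map(seq_len(n_planted_pairs), function(j) {
      sh <- shapes[[((j - 1) %% length(shapes)) + 1]]
      tibble::tibble(
        lead_gene = sprintf("LOOP%02d_LEAD", j),
        lag_gene = sprintf("LOOP%02d_LAG", j),
        peak_rank = sh[["peak"]], half_width = sh[["width"]],
        lag_samples = lag
      )
    }) |> dplyr::bind_rows()

    planted <- purrr::pmap(pairs, function(lead_gene, lag_gene, peak_rank,
                                           half_width, lag_samples) {
      lead_pulse <- hann_pulse(ranks, peak_rank, half_width) * pulse_amplitude
      lag_pulse <- hann_pulse(ranks, peak_rank + lag_samples, half_width) *
        pulse_amplitude
      tibble::tibble(
        gene = rep(c(lead_gene, lag_gene), each = t_len),
        time = rep(times, 2),
        pulse = c(lead_pulse, lag_pulse)
      )
    }) |> dplyr::bind_rows()

    planted_data <- tidyr::expand_grid(individual = individuals,
                                       planted) |>
      dplyr::mutate(
        offset = rep(stats::rnorm(dplyr::n() / t_len, 0, individual_sd),
                     each = t_len),
        value = .data$pulse + .data$offset + stats::rnorm(dplyr::n(), 0, noise_sd)
      ) |>
      dplyr::select("gene", "individual", "time", "value")

    background_data <- tidyr::expand_grid(gene = bg_genes,
                                          individual = individuals,
                                          time = times) |>
      dplyr::mutate(value = stats::rnorm(dplyr::n(), 0, background_sd))

    data <- dplyr::bind_rows(planted_data, background_data) |>
      dplyr::arrange(.data$gene, .data$individual, .data$time)

    if (missing_fraction > 0) {
      samples <- tidyr::expand_grid(individual = individuals, time = times)
      n_drop <- floor(missing_fraction * nrow(samples))
      drop <- samples[sample.int(nrow(samples), n_drop), ]
      # never delete every individual at a time point (imputation needs one)
      drop <- drop |>
        dplyr::group_by(.data$time) |>
        dplyr::filter(dplyr::row_number() <= n_individuals - 1L) |>
        dplyr::ungroup()
      data <- dplyr::anti_join(data, drop, by = c("individual", "time"))
    }

    validate_expression_data(data)
    list(data = data, truth = list(pairs = pairs))
  })
}

# Raised-cosine pulse on the rank axis: cos^2(pi (r - peak) / (2 width))
# inside |r - peak| < width, exactly 0 outside.
hann_pulse <- function(rank, peak, width) {
  v <- numeric(length(rank))
  inside <- abs(rank - peak) < width
  v[inside] <- cos(pi * (rank[inside] - peak) / (2 * width))^2
  v
}

# Admissible (peak, width) variants: pulse zero at rank 0, lead support
# within ranks 1..(T-1-lag) so the lag partner fits inside the grid, and the
# widest admissible width, because narrow pulses leave long zero plateaus
# whose z-scores sit almost exactly on a quartile breakpoint, making the SAX
# symbols flip under the slightest noise. With more planted pairs than
# admissible wide shapes, shapes repeat across pairs (repeated-shape genes
# from different pairs are then genuinely phase-shifted too).
pulse_shapes <- function(t_len, lag) {
  hi <- t_len - 1L - lag
  if (hi < 1) stop("grid too short for the requested lag", call. = FALSE)
  p0 <- max(1L, floor((1 + hi) / 2))
  w0 <- max(1L, min(p0, hi - p0 + 1L))
  cand <- list(c(peak = p0, width = w0),
               c(peak = p0 + 1L, width = w0),
               c(peak = p0 - 1L, width = w0))
  ok <- purrr::keep(cand, function(s) {
    s[["peak"]] - s[["width"]] >= 0 && s[["peak"]] + s[["width"]] <= hi + 1
  })
  if (length(ok) == 0) list(c(peak = p0, width = w0)) else ok
}

#' Score recovered candidate pairs against the planted truth
#'
#' Recall is the fraction of planted pairs recovered in either orientation;
#' precision is the fraction of candidates that are planted pairs. An empty
#' candidate list gives precision 0 with `precision_defined = FALSE`.
#'
#' @param candidates Tibble with `lead_gene`, `lag_gene`.
#' @param truth Truth object from [simulate_loops()] (or its `pairs` tibble).
#' @return List with `recall`, `precision`, `n_candidates`, `n_planted`,
#'   `precision_defined`.
#' @export
score_recovery <- function(candidates, truth) {
  pairs <- if (is.data.frame(truth)) truth else truth$pairs
  candidates <- tibble::as_tibble(candidates)
  n_planted <- nrow(pairs)
  n_candidates <- nrow(candidates)
  if (n_candidates == 0) {
    return(list(recall = 0, precision = 0, n_candidates = 0,
                n_planted = n_planted, precision_defined = FALSE))
  }
  cand_key <- paste(candidates$lead_gene, candidates$lag_gene, sep = "\r")
  fwd <- paste(pairs$lead_gene, pairs$lag_gene, sep = "\r")
  rev <- paste(pairs$lag_gene, pairs$lead_gene, sep = "\r")
  recovered <- fwd %in% cand_key | rev %in% cand_key
  hits <- sum(cand_key %in% c(fwd, rev))
  list(recall = mean(recovered),
       precision = hits / n_candidates,
       n_candidates = n_candidates,
       n_planted = n_planted,
       precision_defined = TRUE)
}
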