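#' Find the centre of a two-dimensional point cloud
#'
#' The loop centre is defined as the point about which the radii of all
#' samples vary least. Both dimensions are first normalised to the unit range
#' so neither gene's expression scale dominates, then a regular grid of
#' candidate centres over the bounding box is scanned and the grid point with
#' the smallest population variance of Euclidean radii is kept (ties broken
#' by smallest x, then y). A refinement pass re-scans a finer grid around the
#' winning cell.
#'
#' @param points Data frame with numeric columns `x` and `y` (at least 3
#'   non-collinear points).
#' @param grid_resolution Candidate centres per axis. Default 101.
#' @param refine Run the fine-grid refinement pass. Default `TRUE`.
#' @return List with `center` (named vector, normalised units),
#'   `radius_variance`, and `normalization` (per-axis `min` and `range` used,
#'   so callers can map between original and normalised coordinates).
#' @export
find_center <- function(points, grid_resolution = 101, refine = TRUE) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  x <- points$x
  y <- points$y
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)

  rx <- range(x)
  ry <- range(y)
  if (diff(rx) <= 1e-12 && diff(ry) <= 1e-12) {
    stop("all points are identical", call. = FALSE)
  }
  if (diff(rx) <= 1e-12 || diff(ry) <= 1e-12) {
    stop("points are collinear; no loop centre exists", call. = FALSE)
  }
  xn <- (x - rx[1]) / diff(rx)
  yn <- (y - ry[1]) / diff(ry)

  # collinearity: smallest singular value of the centred coordinates ~ 0
  m <- cbind(xn - mean(xn), yn - mean(yn))
  sv <- svd(m, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * max(sv[1], 1e-12)) {
    stop("points are collinear; no loop centre exists", call. = FALSE)
  }

  scan <- function(cx_range, cy_range, g) {
    cx <- seq(cx_range[1], cx_range[2], length.out = g)
    cy <- seq(cy_range[1], cy_range[2], length.out = g)
    # grid ordered by x then y so which.min ties resolve to smallest (x, y)
    grid <- tidyr::expand_grid(cx = cx, cy = cy)
    rv <- purrr::map2_dbl(grid$cx, grid$cy, function(a, b) {
      r <- sqrt((xn - a)^2 + (yn - b)^2)
      mean((r - mean(r))^2)
    })
    best <- which.min(rv)
    list(center = c(x = grid$cx[best], y = grid$cy[best]),
         radius_variance = rv[best],
         step = c(diff(cx_range) / (g - 1), diff(cy_range) / (g - 1)))
  }

  fit <- scan(c(0, 1), c(0, 1), grid_resolution)
  if (refine) {
    cx <- fit$center[["x"]]
    cy <- fit$center[["y"]]
    fine <- scan(c(cx - fit$step[1], cx + fit$step[1]),
                 c(cy - fit$step[2], cy + fit$step[2]),
                 grid_resolution)
    if (fine$radius_variance < fit$radius_variance) fit <- fine
  }
  list(center = fit$center,
       radius_variance = fit$radius_variance,
       normalization = list(min = c(x = rx[1], y = ry[1]),
                            range = c(x = diff(rx), y = diff(ry))))
}

#' Transform points to polar coordinates about a centre
#'
#' Angles are measured counterclockwise from the positive x-axis, in degrees
#' in `[0, 360)`, then re-zeroed so that the centroid of the baseline
#' (earliest-time) samples sits at 0 degrees — the loop is read as starting at
#' the unperturbed state. A point falling exactly on the centre has no
#' defined angle; it gets radius 0 and inherits the angle of the previous
#' time point (with a warning).
#'
#' @param points Data frame with columns `x`, `y` and (for baseline
#'   re-zeroing and degenerate-point handling) `time`.
#' @param center Length-2 numeric `(x, y)`, typically from [find_center()]
#'   on the same (normalised) coordinates.
#' @param baseline_time Time whose samples define 0 degrees; default the
#'   smallest time present, or no re-zeroing when `points` has no `time`.
#' @return Tibble of the input plus `angle` (degrees in `[0, 360)`) and
#'   `radius`; the rotation applied is stored in attribute `baseline_angle`.
#' @export
to_polar <- function(points, center, baseline_time = NULL) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y") %in% names(points)), length(center) == 2)
  cx <- center[[1]]
  cy <- center[[2]]
  dx <- points$x - cx
  dy <- points$y - cy
  radius <- sqrt(dx^2 + dy^2)
  angle <- (atan2(dy, dx) * 180 / pi) %% 360

  degenerate <- radius <= 1e-12
  if (any(degenerate)) {
    warning(sum(degenerate), " point(s) coincide with the centre; assigned the ",
            "previous time point's angle", call. = FALSE)
    if ("time" %in% names(points)) {
      ord <- order(points$time)
      prev_angle <- 0
      for (i in ord) {
        if (degenerate[i]) angle[i] <- prev_angle else prev_angle <- angle[i]
      }
    } else {
      angle[degenerate] <- 0
    }
  }

  baseline_angle <- 0
  if ("time" %in% names(points)) {
    if (is.null(baseline_time)) baseline_time <- min(points$time)
    base <- points$time == baseline_time
    if (!any(base)) stop("no samples at baseline time ", format(baseline_time),
                         call. = FALSE)
    baseline_angle <- (atan2(mean(dy[base]), mean(dx[base])) * 180 / pi) %% 360
    angle <- (angle - baseline_angle) %% 360
  }
  out <- dplyr::mutate(points, angle = angle, radius = radius)
  attr(out, "baseline_angle") <- baseline_angle
  out
}

#' Invert a polar transformation
#'
#' Reconstructs Cartesian coordinates from `angle` / `radius` produced by
#' [to_polar()], undoing the baseline rotation.
#'
#' @param polar Tibble with `angle` and `radius` columns.
#' @param center Length-2 centre used in the forward transform.
#' @param baseline_angle Rotation that was applied (attribute
#'   `baseline_angle` of the [to_polar()] result). Default 0.
#' @return Tibble with columns `x`, `y`.
#' @export
from_polar <- function(polar, center, baseline_angle = 0) {
  theta <- (polar$angle + baseline_angle) * pi / 180
  tibble::tibble(x = center[[1]] + polar$radius * cos(theta),
                 y = center[[2]] + polar$radius * sin(theta))
}

#' Unwrap loop angles along time and correlate with time rank
#'
#' A loop traversed once crosses the 0/360 seam, so raw angles are not
#' monotone in time. Walking the time ranks in order, each sample's angle is
#' shifted by the multiple of 360 degrees that places it within 180 degrees
#' of the previous rank's mean angle (baseline-rank angles are read in
#' (-180, 180], around the 0-degree baseline centroid). A sample more than
#' 180 degrees below the previous rank therefore gains a turn — the
#' signature of crossing the seam rather than genuinely moving backwards —
#' and samples jittered across the seam within one rank stay together. The
#' unwrapped angle is then correlated (Pearson) with the time *rank*: the
#' sampling grids of longitudinal studies are uneven, and an ordinal scale
#' keeps late sparse samples from dominating the fit.
#'
#' @param angle Numeric vector of angles in degrees `[0, 360)`.
#' @param time Numeric vector of sample times, same length.
#' @return List with `rho` (Pearson correlation of unwrapped angle versus
#'   time rank), `angle_unwrapped`, and `time_rank`.
#' @export
unwrap_and_correlate <- function(angle, time) {
  stopifnot(length(angle) == length(time))
  if (length(angle) < 3) stop("need at least 3 samples", call. = FALSE)
  ranks <- match(time, sort(unique(time))) - 1L
  if (length(unique(ranks)) < 2) stop("all samples share one time", call. = FALSE)

  unwrapped <- angle
  base <- ranks == 0
  unwrapped[base] <- angle[base] - 360 * (angle[base] > 180)
  prev_mean <- mean(unwrapped[base])
  for (r in seq_len(max(ranks))) {
    sel <- ranks == r
    turns <- ceiling((prev_mean - 180 - angle[sel]) / 360)
    unwrapped[sel] <- angle[sel] + 360 * turns
    prev_mean <- mean(unwrapped[sel])
  }
  list(rho = stats::cor(unwrapped, ranks),
       angle_unwrapped = unwrapped,
       time_rank = ranks)
}

#' Fit the polar geometry of a candidate gene-pair loop
#'
#' End-to-end polar analysis of one ordered gene pair: gathers each sample's
#' `(lead, lag)` expression coordinates, normalises both axes to the unit
#' range, finds the minimum-radius-variance centre, converts to polar
#' coordinates with the baseline samples at 0 degrees, unwraps the angles and
#' correlates them with time rank. A tight loop traversed once gives
#' `angle_time_rho` near 1.
#'
#' @param data Long expression tibble.
#' @param lead_gene,lag_gene Gene symbols of the pair (lead peaks first).
#' @param grid_resolution Passed to [find_center()].
#' @return An object of class `polar_loop`: list with `lead_gene`,
#'   `lag_gene`, `center`, `radius_variance`, `angle_time_rho`,
#'   `baseline_angle`, and `points` (per-sample tibble with `individual`,
#'   `time`, `x`, `y` in normalised units, `angle`, `radius`,
#'   `angle_unwrapped`, `time_rank`).
#' @export
polar_loop <- function(data, lead_gene, lag_gene, grid_resolution = 101) {
  pts <- pair_coordinates(data, lead_gene, lag_gene)
  fit <- find_center(pts, grid_resolution = grid_resolution)
  norm <- fit$normalization
  pts_n <- dplyr::mutate(pts,
    x = (.data$x - norm$min[["x"]]) / norm$range[["x"]],
    y = (.data$y - norm$min[["y"]]) / norm$range[["y"]])
  polar <- to_polar(pts_n, fit$center)
  uw <- unwrap_and_correlate(polar$angle, polar$time)
  points <- dplyr::mutate(polar,
                          angle_unwrapped = uw$angle_unwrapped,
                          time_rank = uw$time_rank)
  structure(
    list(lead_gene = lead_gene, lag_gene = lag_gene,
         center = fit$center,
         radius_variance = fit$radius_variance,
         angle_time_rho = uw$rho,
         baseline_angle = attr(polar, "baseline_angle"),
         points = points),
    class = "polar_loop"
  )
}

#' @export
print.polar_loop <- function(x, ...) {
  cat(sprintf("<polar_loop> %s (lead) vs %s (lag)\n", x$lead_gene, x$lag_gene))
  cat(sprintf("  centre (%.3f, %.3f), radius variance %.4g\n",
              x$center[["x"]], x$center[["y"]], x$radius_variance))
  cat(sprintf("  angle-time Pearson rho %.3f over %d samples\n",
              x$angle_time_rho, nrow(x$points)))
  invisible(x)
}

# Per-sample (lead, lag) coordinates of one gene pair, wide format.
pair_coordinates <- function(data, lead_gene, lag_gene) {
  data <- tibble::as_tibble(data)
  for (g in c(lead_gene, lag_gene)) {
    if (!g %in% data$gene) stop("gene '", g, "' not present in data", call. = FALSE)
  }
  data |>
    dplyr::filter(.data$gene %in% c(lead_gene, lag_gene)) |>
    dplyr::select("gene", "individual", "time", "value") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "value") |>
    dplyr::transmute(.data$individual, .data$time,
                     x = .data[[lead_gene]], y = .data[[lag_gene]])
}
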