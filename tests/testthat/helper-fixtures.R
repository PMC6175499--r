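# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive (loops, direct formulas) so they stay independent of the
# vectorised implementation paths they check.

# small rectangular long tibble: genes x (individual, time)
make_expression <- function(genes, individuals, times, values) {
  grid <- tidyr::expand_grid(gene = genes, individual = individuals, time = times)
  dplyr::mutate(grid, value = values)
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# brute-force KNN: explicit loops, stable order(), same tie rules restated
oracle_knn <- function(train, test, k) {
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train))) {
      d[j] <- sqrt((test$x[i] - train$x[j])^2 + (test$y[i] - train$y[j])^2)
    }
    nn <- order(d)[1:k]
    labs <- as.character(train$label)[nn]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    pick <- winners[1]
    best_pos <- Inf
    for (w in winners) {
      pos <- which(labs == w)[1]
      if (pos < best_pos) {
        best_pos <- pos
        pick <- w
      }
    }
    out[i] <- pick
  }
  out
}

# naive SAX from scratch: fresh breakpoints, per-value interval scan
oracle_sax_word <- function(x, a = 4) {
  z <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  breaks <- c(-Inf, stats::qnorm(seq_len(a - 1) / a), Inf)
  word <- character(length(z))
  for (i in seq_along(z)) {
    for (s in seq_len(a)) {
      if (z[i] >= breaks[s] && z[i] < breaks[s + 1]) word[i] <- letters[s]
    }
  }
  paste(word, collapse = "")
}

# two-sample KS statistic as the sup-difference of empirical CDFs
oracle_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# whole-transcriptome-sized composite profile with random dynamics
random_profile <- function(n_genes, n_times = 9, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    gene = rep(sprintf("G%05d", seq_len(n_genes)), each = n_times),
    time = rep(seq_len(n_times) - 1, n_genes),
    value = stats::rnorm(n_genes * n_times)
  ))
}

# exhaustive fine-grid centre search over normalised [0,1]^2
oracle_center <- function(xn, yn, g = 201) {
  best <- c(NA, NA)
  best_v <- Inf
  for (cx in seq(0, 1, length.out = g)) {
    for (cy in seq(0, 1, length.out = g)) {
      r <- sqrt((xn - cx)^2 + (yn - cy)^2)
      v <- mean((r - mean(r))^2)
      if (v < best_v) {
        best_v <- v
        best <- c(cx, cy)
      }
    }
  }
  list(center = best, radius_variance = best_v)
}
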