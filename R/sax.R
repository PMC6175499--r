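#' Z-normalise a time series
#'
#' Centres to mean 0 and scales to population standard deviation 1 (divide by
#' `sqrt(mean((x - mean(x))^2))`). Symbol assignment against standard-normal
#' breakpoints is only meaningful on this scale. A constant series has no
#' shape to discretise and raises an error.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of the same length with mean 0 and population sd 1.
#' @export
#' @examples
#' znormalize(c(1, 2, 3))
znormalize <- function(x) {
  if (length(x) < 2) stop("series must have at least 2 values", call. = FALSE)
  if (anyNA(x)) stop("series contains NA", call. = FALSE)
  s <- sqrt(mean((x - mean(x))^2))
  if (s <= 1e-12) stop("zero variance: constant series cannot be normalised",
                       call. = FALSE)
  (x - mean(x)) / s
}

#' Standard-normal breakpoints for an alphabet
#'
#' The `a - 1` interior quantiles of N(0, 1) that cut the real line into `a`
#' equiprobable regions, one per symbol.
#'
#' @param alphabet_size Integer in 2..20.
#' @return Numeric vector of length `alphabet_size - 1`.
#' @export
sax_breakpoints <- function(alphabet_size) {
  if (alphabet_size < 2 || alphabet_size > 20) {
    stop("alphabet_size must be between 2 and 20", call. = FALSE)
  }
  stats::qnorm(seq_len(alphabet_size - 1) / alphabet_size)
}

#' Convert a time series to its SAX word
#'
#' Symbolic aggregate approximation: the series is z-normalised and each value
#' is replaced by the letter of the standard-normal equiprobable region it
#' falls in (`a` = lowest). Regions are lower-inclusive: a value equal to a
#' breakpoint takes the higher symbol, so 0 with a 4-letter alphabet maps to
#' `"c"`. When `word_length` is shorter than the series, piecewise aggregate
#' approximation (means over contiguous, near-equal-length blocks) reduces the
#' series first; the default keeps one symbol per time point, appropriate for
#' the short (6-9 point) grids of longitudinal expression studies.
#'
#' @param x Numeric vector (one gene's time course).
#' @param alphabet_size Number of symbols, 2..20. Default 4.
#' @param word_length Output word length; default `length(x)`.
#' @return A single string of `word_length` letters.
#' @export
#' @examples
#' to_sax(c(1, 2, 3))        # "acd"
to_sax <- function(x, alphabet_size = 4, word_length = length(x)) {
  z <- znormalize(x)
  if (word_length < 1 || word_length > length(z)) {
    stop("word_length must be in 1..length(x)", call. = FALSE)
  }
  if (word_length < length(z)) {
    blocks <- as.integer(cut(seq_along(z), breaks = word_length, labels = FALSE))
    z <- as.numeric(tapply(z, blocks, mean))
  }
  breaks <- sax_breakpoints(alphabet_size)
  # lower-inclusive intervals [b_{i-1}, b_i): count of breakpoints <= value
  idx <- vapply(z, function(v) sum(v >= breaks), integer(1)) + 1L
  paste(letters[idx], collapse = "")
}

#' Build the quarter-period search pattern of a SAX word
#'
#' A gene pair 90 degrees out of phase traces a circle, and on the symbolic
#' scale that phase difference is a shift of `T/4` symbols (rounded down, so a
#' 9-point series shifts by 2). The search pattern is the word shifted right
#' by `shift_symbols`, with leading wildcards (`?`) in the vacated positions
#' and the trailing symbols discarded: a time course is not assumed periodic,
#' so no wrap-around is fabricated.
#'
#' @param word SAX word string.
#' @param shift_symbols Number of positions to shift; default
#'   `floor(nchar(word) / 4)`.
#' @return Pattern string of the same length, beginning with `shift_symbols`
#'   wildcards.
#' @export
#' @examples
#' make_search_pattern("abcdd", 1)   # "?abcd"
make_search_pattern <- function(word, shift_symbols = floor(nchar(word) / 4)) {
  n <- nchar(word)
  if (shift_symbols < 1 || shift_symbols >= n) {
    stop("shift_symbols must be in 1..(word length - 1)", call. = FALSE)
  }
  paste0(strrep("?", shift_symbols), substr(word, 1, n - shift_symbols))
}

#' Hamming distance between a word and a wildcard pattern
#'
#' Counts positions where the pattern symbol is not the wildcard `?` and
#' differs from the word's symbol.
#'
#' @param word SAX word string.
#' @param pattern Pattern string of equal length, possibly with `?` wildcards.
#' @return Non-negative integer mismatch count.
#' @export
pattern_distance <- function(word, pattern) {
  if (nchar(word) != nchar(pattern)) {
    stop("word and pattern lengths differ", call. = FALSE)
  }
  w <- strsplit(word, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  sum(p != "?" & w != p)
}

#' SAX words and search patterns for every gene of a composite profile
#'
#' @param profile Composite profile tibble (`gene`, `time`, `value`).
#' @param alphabet_size Symbols in the SAX alphabet. Default 4.
#' @param word_length Word length; default one symbol per time point.
#' @param shift_symbols Search-pattern shift; default `floor(word_length / 4)`.
#' @return Tibble with columns `gene`, `word`, `search_pattern`.
#' @export
sax_transform <- function(profile, alphabet_size = 4, word_length = NULL,
                          shift_symbols = NULL) {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("gene", "time", "value") %in% names(profile)))
  profile <- dplyr::arrange(profile, .data$gene, .data$time)
  series <- split(profile$value, profile$gene)
  t_len <- length(unique(profile$time))
  if (is.null(word_length)) word_length <- t_len
  if (is.null(shift_symbols)) shift_symbols <- floor(word_length / 4)

  words <- vapply(series, to_sax, character(1),
                  alphabet_size = alphabet_size, word_length = word_length)
  tibble::tibble(
    gene = names(series),
    word = unname(words),
    search_pattern = vapply(unname(words), make_search_pattern, character(1),
                            shift_symbols = shift_symbols)
  )
}

#' Enumerate phase-shifted candidate gene pairs
#'
#' For every ordered pair of genes, the lead gene's shifted search pattern is
#' compared against the lag gene's word; a pair whose mismatch count is at
#' most `max_distance` is a loop candidate (lead peaks first, lag follows a
#' quarter period later). The exhaustive scan is cheap because it runs on the
#' filtered dynamic subset (around a hundred genes).
#'
#' @param words Tibble from [sax_transform()] (`gene`, `word`,
#'   `search_pattern`).
#' @param max_distance Largest allowed mismatch count over the compared
#'   (non-wildcard) positions. Default 0, exact match.
#' @return Tibble `lead_gene`, `lag_gene`, `match_distance`, sorted by
#'   distance then gene symbols.
#' @export
find_phase_shifted_pairs <- function(words, max_distance = 0) {
  words <- tibble::as_tibble(words)
  stopifnot(all(c("gene", "word", "search_pattern") %in% names(words)))
  if (nrow(words) < 2) stop("need at least 2 genes", call. = FALSE)

  pairs <- tidyr::expand_grid(lead = seq_len(nrow(words)),
                              lag = seq_len(nrow(words))) |>
    dplyr::filter(.data$lead != .data$lag)
  dist <- purrr::map2_int(pairs$lead, pairs$lag, function(i, j) {
    as.integer(pattern_distance(words$word[j], words$search_pattern[i]))
  })
  tibble::tibble(
    lead_gene = words$gene[pairs$lead],
    lag_gene = words$gene[pairs$lag],
    match_distance = dist
  ) |>
    dplyr::filter(.data$match_distance <= max_distance) |>
    dplyr::arrange(.data$match_distance, .data$lead_gene, .data$lag_gene)
}
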