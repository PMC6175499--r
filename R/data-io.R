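#' Validate a long-format longitudinal expression tibble
#'
#' Every user-facing function in loopstage exchanges longitudinal expression
#' data as a long tibble with columns `gene` (character), `individual`
#' (character), `time` (numeric, non-negative) and `value` (numeric, log2
#' expression). A sample is one `(individual, time)` combination; individuals
#' may miss some time points (whole samples absent), but within each observed
#' sample every gene must appear exactly once.
#'
#' @param data A data frame to validate.
#' @return `data`, invisibly, coerced to a tibble, if all invariants hold.
#' @export
validate_expression_data <- function(data) {
  data <- tibble::as_tibble(data)
  required <- c("gene", "individual", "time", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("expression data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) == 0) stop("expression data is empty", call. = FALSE)
  if (!is.numeric(data$time)) stop("`time` must be numeric", call. = FALSE)
  if (!is.numeric(data$value)) stop("`value` must be numeric", call. = FALSE)
  if (any(data$time < 0)) stop("time values must be non-negative", call. = FALSE)

  keys <- paste(data$gene, data$individual, data$time, sep = "\r")
  if (anyDuplicated(keys)) {
    first <- data[which(duplicated(keys))[1], ]
    stop(sprintf("duplicate entry for gene '%s' in sample %s:%s",
                 first$gene, first$individual, format(first$time)),
         call. = FALSE)
  }
  # rectangular over observed samples: every gene present in every sample
  n_genes <- dplyr::n_distinct(data$gene)
  n_samples <- dplyr::n_distinct(paste(data$individual, data$time, sep = "\r"))
  if (nrow(data) != n_genes * n_samples) {
    stop("expression data is not rectangular: each observed (individual, time) ",
         "sample must contain every gene exactly once", call. = FALSE)
  }
  invisible(data)
}

#' Read a longitudinal expression table
#'
#' Reads a genes-by-samples TSV in which the first column is `gene` and every
#' other column header is `individualID:time` (for example `D1:2.5`). Values
#' are log2 expression. Returns the long tibble format described in
#' [validate_expression_data()].
#'
#' @param path Path to a tab-separated file.
#' @param time_unit Unit of the time encoded in the column headers,
#'   `"hours"` or `"days"`. Stored as the `time_unit` attribute.
#' @return A long expression tibble with attribute `time_unit`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tA:0\tA:2", "IL1A\t1.5\t3.25"), tf)
#' read_expression_tsv(tf, "hours")
read_expression_tsv <- function(path, time_unit = c("hours", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  n_comment <- 0
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1], "#")) {
    n_comment <- n_comment + 1
  }
  lines <- lines[seq_along(lines) > n_comment]
  if (length(lines) == 0) {
    stop("expression table must have a gene column and at least one sample column",
         call. = FALSE)
  }
  # header parsed by hand: readr would mangle duplicated sample columns
  # before the duplicate check can see them
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) {
    stop("expression table must have a gene column and at least one sample column",
         call. = FALSE)
  }
  sample_headers <- header[-1]
  raw <- readr::read_tsv(I(lines), skip = 1, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    stop("expression table is empty: no gene rows", call. = FALSE)
  }
  if (ncol(raw) != length(header)) {
    stop("expression table body does not match its header", call. = FALSE)
  }
  names(raw) <- c("gene", sprintf(".s%d", seq_along(sample_headers)))

  parsed <- strsplit(sample_headers, ":", fixed = TRUE)
  bad <- lengths(parsed) != 2
  if (any(bad)) {
    stop("sample column header(s) not of the form individual:time: ",
         paste(sample_headers[bad], collapse = ", "), call. = FALSE)
  }
  individual <- vapply(parsed, `[`, character(1), 1)
  time <- suppressWarnings(as.numeric(vapply(parsed, `[`, character(1), 2)))
  if (anyNA(time)) {
    stop("non-numeric time in sample header(s): ",
         paste(sample_headers[is.na(time)], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste(individual, time, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (individual, time) sample column: ",
         sample_headers[which(dup)[1]], call. = FALSE)
  }
  if (anyDuplicated(raw$gene)) {
    stop("duplicate gene row: ", raw$gene[which(duplicated(raw$gene))[1]],
         call. = FALSE)
  }

  for (j in seq_along(sample_headers)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad_row <- which(is.na(col) & !is.na(raw[[j + 1]]) | is.na(raw[[j + 1]]))
    if (length(bad_row) > 0) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   raw[[j + 1]][bad_row[1]], raw$gene[bad_row[1]],
                   sample_headers[j]), call. = FALSE)
    }
    raw[[j + 1]] <- col
  }

  out <- tidyr::pivot_longer(raw, -"gene", names_to = "sample", values_to = "value")
  key <- tibble::tibble(sample = sprintf(".s%d", seq_along(sample_headers)),
                        individual = individual, time = time)
  out <- dplyr::left_join(out, key, by = "sample")
  out <- dplyr::select(out, "gene", "individual", "time", "value")
  out <- dplyr::arrange(out, match(.data$gene, raw$gene),
                        match(paste(.data$individual, .data$time),
                              paste(individual, time)))
  validate_expression_data(out)
  attr(out, "time_unit") <- time_unit
  out
}

#' Write a longitudinal expression table
#'
#' Inverse of [read_expression_tsv()]: writes the `gene` / `individual:time`
#' TSV dialect.
#'
#' @param data Long expression tibble.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` comment
#'   lines (provenance such as the generating seed); [read_expression_tsv()]
#'   skips them.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(data, path, comments = NULL) {
  validate_expression_data(data)
  wide <- data |>
    dplyr::mutate(sample = paste0(.data$individual, ":", format(.data$time,
                  trim = TRUE, scientific = FALSE, drop0trailing = TRUE))) |>
    dplyr::select("gene", "sample", "value") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "value")
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(wide, path, progress = FALSE, append = TRUE,
                     col_names = TRUE)
  } else {
    readr::write_tsv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Collapse probe-level measurements to gene level
#'
#' Microarray platforms measure each gene with one or more probes. This takes
#' a probe-level long tibble (`probe_id`, `individual`, `time`, `value`) and a
#' probe annotation (`probe_id`, `gene`) and collapses multiple probes per
#' gene by the per-sample median, the convention used when mapping platform
#' files to gene symbols. Probes without a gene annotation are dropped and
#' their count reported via a message. Gene symbols are compared exactly as
#' given (case-sensitive). Probes annotated to more than one gene are not
#' supported and raise an error.
#'
#' @param probe_data Long tibble `probe_id`, `individual`, `time`, `value`.
#' @param probe_map Tibble with columns `probe_id` and `gene`; rows with `NA`
#'   or empty `gene` are treated as unmapped.
#' @return A long expression tibble (one row per gene and sample).
#' @export
collapse_probes <- function(probe_data, probe_map) {
  probe_data <- tibble::as_tibble(probe_data)
  probe_map <- tibble::as_tibble(probe_map)
  stopifnot(all(c("probe_id", "individual", "time", "value") %in% names(probe_data)),
            all(c("probe_id", "gene") %in% names(probe_map)))

  probe_map <- dplyr::filter(probe_map, !is.na(.data$gene), .data$gene != "")
  if (anyDuplicated(probe_map$probe_id)) {
    multi <- probe_map$probe_id[duplicated(probe_map$probe_id)][1]
    stop("probe '", multi, "' maps to multiple genes; multi-mapped probes are ",
         "not supported", call. = FALSE)
  }
  mapped <- dplyr::inner_join(probe_data, probe_map, by = "probe_id")
  if (nrow(mapped) == 0) stop("no mapped probes", call. = FALSE)

  n_probes <- dplyr::n_distinct(probe_data$probe_id)
  n_mapped <- dplyr::n_distinct(mapped$probe_id)
  if (n_mapped < n_probes) {
    message(sprintf("collapse_probes: dropped %d unmapped probe(s) of %d",
                    n_probes - n_mapped, n_probes))
  }

  out <- mapped |>
    dplyr::summarise(value = stats::median(.data$value),
                     .by = c("gene", "individual", "time")) |>
    dplyr::arrange(.data$gene, .data$individual, .data$time)
  validate_expression_data(out)
  out
}

#' Read a local GEO series matrix plus platform annotation into probe-level data
#'
#' Parses a GEO series-matrix file (the block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`) and a platform
#' (GPL) annotation table from local files — no network access. Series-matrix
#' files identify samples only by GSM accession, so the caller supplies
#' `sample_info` mapping each accession to an individual and a time.
#'
#' @param series_path Local series-matrix text file.
#' @param annotation_path Local tab-separated platform annotation table
#'   (comment lines starting with `#` are skipped).
#' @param probe_col,symbol_col Names of the probe-identifier and gene-symbol
#'   columns in the annotation table.
#' @param sample_info Tibble with columns `sample` (GSM accession matching the
#'   series-matrix columns), `individual`, `time`.
#' @return A list with `probe_data` (long probe tibble) and `probe_map`
#'   (`probe_id`, `gene`), ready for [collapse_probes()].
#' @export
read_geo_series_matrix <- function(series_path, annotation_path,
                                   probe_col = "ID", symbol_col = "Gene Symbol",
                                   sample_info) {
  if (!file.exists(series_path)) stop("file not found: ", series_path, call. = FALSE)
  if (!file.exists(annotation_path)) stop("file not found: ", annotation_path, call. = FALSE)
  sample_info <- tibble::as_tibble(sample_info)
  stopifnot(all(c("sample", "individual", "time") %in% names(sample_info)))

  lines <- readLines(series_path)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1) {
    stop("could not locate the series matrix table block", call. = FALSE)
  }
  tab <- readr::read_tsv(I(lines[(begin + 1):(end - 1)]),
                         col_types = readr::cols(.default = readr::col_double(),
                                                 ID_REF = readr::col_character()),
                         progress = FALSE)
  names(tab) <- gsub('^"|"$', "", names(tab))
  names(tab)[1] <- "probe_id"

  missing_samples <- setdiff(names(tab)[-1], sample_info$sample)
  if (length(missing_samples) > 0) {
    stop("sample_info lacks entries for: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  probe_data <- tab |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample", values_to = "value") |>
    dplyr::left_join(sample_info, by = "sample") |>
    dplyr::select("probe_id", "individual", "time", "value")

  ann <- readr::read_tsv(annotation_path, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c(probe_col, symbol_col) %in% names(ann))) {
    stop("annotation table lacks column(s): ",
         paste(setdiff(c(probe_col, symbol_col), names(ann)), collapse = ", "),
         call. = FALSE)
  }
  probe_map <- tibble::tibble(probe_id = ann[[probe_col]], gene = ann[[symbol_col]])
  list(probe_data = probe_data, probe_map = probe_map)
}
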