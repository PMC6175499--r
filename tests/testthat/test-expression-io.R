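test_that("a well-formed TSV round-trips through read and write", {
  tf <- write_tsv_lines(c(
    "gene\tD1:0\tD1:2\tD2:0\tD2:2",
    "IL1A\t1.5\t3.25\t1.0\t2.75",
    "TNIP3\t0.5\t0.75\t0.25\t1.5",
    "GAPDH\t5\t5\t5\t5"
  ))
  ds <- read_expression_tsv(tf, "hours")
  expect_equal(sort(unique(ds$gene)), c("GAPDH", "IL1A", "TNIP3"))
  expect_equal(dplyr::n_distinct(paste(ds$individual, ds$time)), 4)
  expect_equal(attr(ds, "time_unit"), "hours")
  expect_equal(ds$value[ds$gene == "IL1A" & ds$individual == "D1" & ds$time == 2],
               3.25)

  out <- tempfile(fileext = ".tsv")
  write_expression_tsv(ds, out)
  back <- read_expression_tsv(out, "hours")
  expect_equal(dplyr::arrange(back, gene, individual, time),
               dplyr::arrange(ds, gene, individual, time),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("synthetic data survives a write/read round trip to 6 decimals", {
  sim <- simulate_loops(n_individuals = 3, n_background_genes = 5,
                        n_planted_pairs = 1, seed = 11)
  out <- tempfile(fileext = ".tsv")
  write_expression_tsv(sim$data, out)
  back <- read_expression_tsv(out, "hours")
  merged <- dplyr::inner_join(sim$data, back,
                              by = c("gene", "individual", "time"))
  expect_equal(nrow(merged), nrow(sim$data))
  expect_true(all(abs(merged$value.x - merged$value.y) < 5e-7))
})

test_that("malformed tables are rejected with informative errors", {
  dup_gene <- write_tsv_lines(c("gene\tA:0\tA:1", "IL1A\t1\t2", "IL1A\t3\t4"))
  expect_error(read_expression_tsv(dup_gene, "hours"), "IL1A")

  dup_sample <- write_tsv_lines(c("gene\tA:0\tA:0", "G1\t1\t2"))
  expect_error(read_expression_tsv(dup_sample, "hours"), "duplicate")

  bad_cell <- write_tsv_lines(c("gene\tA:0\tA:1", "G1\t1\tx"))
  expect_error(read_expression_tsv(bad_cell, "hours"), "G1.*A:1")

  bad_header <- write_tsv_lines(c("gene\tA:0\tB", "G1\t1\t2"))
  expect_error(read_expression_tsv(bad_header, "hours"), "individual:time")
})

test_that("validate_expression_data enforces rectangularity and uniqueness", {
  ok <- make_expression(c("G1", "G2"), c("A", "B"), c(0, 1), 1:8)
  expect_silent(validate_expression_data(ok))
  # dropping one gene from one sample (not the whole sample) is malformed
  expect_error(validate_expression_data(ok[-1, ]), "rectangular")
  expect_error(validate_expression_data(dplyr::bind_rows(ok, ok[1, ])),
               "duplicate")
  neg <- dplyr::mutate(ok, time = time - 5)
  expect_error(validate_expression_data(neg), "non-negative")
})

test_that("collapse_probes takes per-sample medians over a gene's probes", {
  pd <- tibble::tibble(
    probe_id = rep(c("p1", "p2", "p3", "q1"), each = 2),
    individual = "A",
    time = rep(c(0, 1), 4),
    value = c(1, 1, 3, 2, 9, 9, 7, 7)
  )
  map <- tibble::tibble(probe_id = c("p1", "p2", "p3", "q1"),
                        gene = c("GENEA", "GENEA", "GENEA", "GENEB"))
  out <- collapse_probes(pd, map)
  # odd-count median: (1, 3, 9) -> 3 at t=0; (1, 2, 9) -> 2 at t=1
  expect_equal(out$value[out$gene == "GENEA" & out$time == 0], 3)
  expect_equal(out$value[out$gene == "GENEA" & out$time == 1], 2)
  expect_equal(out$value[out$gene == "GENEB"], c(7, 7))

  # even count -> mean of the two central values
  map2 <- dplyr::filter(map, probe_id != "p3")
  out2 <- collapse_probes(dplyr::filter(pd, probe_id != "p3"), map2)
  expect_equal(out2$value[out2$gene == "GENEA" & out2$time == 0], 2)

  # one probe per gene: identity, and idempotence on gene-level data
  single <- collapse_probes(dplyr::filter(pd, probe_id %in% c("p1", "q1")),
                            dplyr::filter(map, probe_id %in% c("p1", "q1")))
  expect_equal(sort(single$value), c(1, 1, 7, 7))
  again <- collapse_probes(dplyr::rename(single, probe_id = gene),
                           tibble::tibble(probe_id = c("GENEA", "GENEB"),
                                          gene = c("GENEA", "GENEB")))
  expect_equal(again, single)
})

test_that("collapse_probes drops unmapped probes and rejects bad mappings", {
  pd <- tibble::tibble(probe_id = c("p1", "p2"), individual = "A",
                       time = 0, value = c(1, 2))
  map <- tibble::tibble(probe_id = c("p1", "p2"), gene = c("G1", NA))
  expect_message(out <- collapse_probes(pd, map), "1 unmapped")
  expect_equal(dplyr::n_distinct(out$gene), 1)

  expect_error(collapse_probes(pd, tibble::tibble(probe_id = "p9", gene = "G")),
               "no mapped probes")
  multi <- tibble::tibble(probe_id = c("p1", "p1"), gene = c("G1", "G2"))
  expect_error(collapse_probes(pd, multi), "multiple genes")
})

test_that("output gene count equals the number of distinct mapped symbols", {
  set.seed(7)
  n_probe <- 20
  pd <- tidyr::expand_grid(probe_id = sprintf("p%02d", 1:n_probe),
                           individual = c("A", "B"), time = c(0, 1, 2)) |>
    dplyr::mutate(value = stats::rnorm(dplyr::n()))
  map <- tibble::tibble(probe_id = sprintf("p%02d", 1:n_probe),
                        gene = sample(c("G1", "G2", "G3", "G4", NA),
                                      n_probe, replace = TRUE))
  out <- suppressMessages(collapse_probes(pd, map))
  expect_equal(dplyr::n_distinct(out$gene),
               dplyr::n_distinct(stats::na.omit(map$gene)))
})

test_that("the GEO series-matrix reader builds probe data from local files", {
  series <- write_tsv_lines(c(
    "!Series_title\t\"toy\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"\t\"GSM3\"\t\"GSM4\"",
    "\"p1\"\t1.0\t2.0\t1.5\t2.5",
    "\"p2\"\t3.0\t4.0\t3.5\t4.5",
    "\"p3\"\t0.5\t0.5\t0.5\t0.5",
    "!series_matrix_table_end"
  ))
  gpl <- write_tsv_lines(c(
    "# platform annotation",
    "ID\tGene Symbol",
    "p1\tIL1A",
    "p2\tIL1A",
    "p3\tTNIP3"
  ))
  info <- tibble::tibble(sample = paste0("GSM", 1:4),
                         individual = c("A", "A", "B", "B"),
                         time = c(0, 2, 0, 2))
  pm <- read_geo_series_matrix(series, gpl, sample_info = info)
  expect_equal(nrow(pm$probe_data), 12)
  ds <- collapse_probes(pm$probe_data, pm$probe_map)
  # p1, p2 -> IL1A medians
  expect_equal(ds$value[ds$gene == "IL1A" & ds$individual == "A" & ds$time == 0], 2)
  expect_equal(sort(unique(ds$gene)), c("IL1A", "TNIP3"))

  expect_error(read_geo_series_matrix(series, gpl,
                                      sample_info = info[1:2, ]), "GSM3")
})
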