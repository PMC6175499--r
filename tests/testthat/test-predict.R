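test_that("knn follows majority vote with deterministic tie handling", {
  # unanimous co-located neighbours
  train <- tibble::tibble(x = c(0, 0, 0), y = c(0, 0, 0), label = "t=4h")
  expect_equal(knn_predict(train, tibble::tibble(x = 0, y = 0)), "t=4h")

  # hand-computed distances: neighbours A, A, B -> A
  train2 <- tibble::tibble(x = c(0, 1, 0, 5), y = c(0, 0, 1, 5),
                           label = c("A", "A", "B", "B"))
  expect_equal(knn_predict(train2, tibble::tibble(x = 0.1, y = 0.1)), "A")

  # majority beats the single nearest neighbour: votes B = 2 vs A = 1
  train3 <- tibble::tibble(x = c(0, 1, 1.1), y = c(0, 0, 0),
                           label = c("A", "B", "B"))
  expect_equal(knn_predict(train3, tibble::tibble(x = 0.05, y = 0)), "B")

  # a 1-1 vote tie at k = 2 goes to the nearest neighbour's label
  train4 <- tibble::tibble(x = c(0, 1), y = c(0, 0), label = c("A", "B"))
  expect_equal(knn_predict(train4, tibble::tibble(x = 0.2, y = 0), k = 2), "A")

  expect_error(knn_predict(train4, tibble::tibble(x = 0, y = 0), k = 3),
               "k = 3")

  nb <- knn_predict(train2, tibble::tibble(x = 0.1, y = 0.1),
                    return_neighbors = TRUE)
  expect_equal(nb$neighbors[[1]], c("A", "A", "B"))
})

test_that("knn matches the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:60) {
    n_train <- sample(5:50, 1)
    n_labels <- sample(2:5, 1)
    k <- sample(1:min(7, n_train), 1)
    train <- tibble::tibble(x = stats::rnorm(n_train), y = stats::rnorm(n_train),
                            label = sample(LETTERS[1:n_labels], n_train,
                                           replace = TRUE))
    test <- tibble::tibble(x = stats::rnorm(8), y = stats::rnorm(8))
    expect_equal(knn_predict(train, test, k = k), oracle_knn(train, test, k))
  }
})

test_that("evaluation maps times through the stage map before scoring", {
  perfect <- evaluate_predictions(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_equal(sum(perfect$confusion), 3)

  # baseline days are interchangeable: 0 vs 14 and 14 vs 28 both count
  res <- evaluate_predictions(c(0, 3, 7, 14), c(14, 3, 7, 28),
                              stage_map = stage_map_vaccination())
  expect_equal(res$accuracy, 1)

  nine <- evaluate_predictions(c(rep("x", 9), "y"), rep("x", 10))
  expect_equal(nine$accuracy, 0.9)

  expect_error(evaluate_predictions(c(0, 60), c(0, 0),
                                    stage_map = stage_map_vaccination()),
               "60")
  expect_error(evaluate_predictions(c("a"), c("a", "b")), "lengths differ")
})

test_that("accuracy is invariant under bijective relabeling", {
  set.seed(32)
  truth <- sample(letters[1:4], 30, replace = TRUE)
  pred <- sample(letters[1:4], 30, replace = TRUE)
  base <- evaluate_predictions(truth, pred)$accuracy
  perm <- stats::setNames(letters[c(3, 1, 4, 2)], letters[1:4])
  expect_equal(evaluate_predictions(perm[truth], perm[pred])$accuracy, base)
})

test_that("confusion matrix entries sum to the sample count", {
  set.seed(33)
  truth <- sample(c(0, 3, 7, 10, 14), 40, replace = TRUE)
  pred <- sample(c(0, 3, 7, 10, 14), 40, replace = TRUE)
  res <- evaluate_predictions(truth, pred, stage_map = stage_map_vaccination())
  expect_equal(sum(res$confusion), 40)
  expect_gte(res$accuracy, 0)
  expect_lte(res$accuracy, 1)
  expect_equal(glance(res)$accuracy, res$accuracy)
})

test_that("loocv scores each held-out individual and needs at least two", {
  # two identical individuals on a clean loop: both perfectly predicted
  sim <- simulate_loops(n_individuals = 2, n_background_genes = 2,
                        n_planted_pairs = 1, noise_sd = 0, individual_sd = 0,
                        seed = 34)
  data <- center_to_baseline(sim$data)
  # the last time point has returned to baseline and coincides with time 0 in
  # the pair plane, so it is excluded (as a resolved end point would be)
  res <- loocv(data, "LOOP01_LEAD", "LOOP01_LAG", excluded_times = 48)
  expect_equal(nrow(res), 2)
  expect_true(all(res$accuracy == 1))

  one <- dplyr::filter(data, individual == "I01")
  expect_error(loocv(one, "LOOP01_LEAD", "LOOP01_LAG"), "at least 2")
})

test_that("loocv on a low-noise planted loop has high median accuracy", {
  sim <- simulate_loops(n_individuals = 6, n_background_genes = 2,
                        n_planted_pairs = 1, noise_sd = 0.05,
                        individual_sd = 0.02, seed = 35)
  data <- center_to_baseline(sim$data)
  res <- loocv(data, "LOOP01_LEAD", "LOOP01_LAG", excluded_times = 48)
  s <- glance(res)
  expect_gte(s$median, 0.9)
  expect_equal(s$n_individuals, 6)
})

test_that("loocv with shuffled time labels falls to chance", {
  sim <- simulate_loops(n_individuals = 6, n_background_genes = 2,
                        n_planted_pairs = 1, noise_sd = 0.05, seed = 36)
  data <- center_to_baseline(sim$data)
  shuffled <- withr::with_seed(99, {
    data |>
      dplyr::group_by(gene, individual) |>
      dplyr::mutate(value = value[sample.int(dplyr::n())]) |>
      dplyr::ungroup()
  })
  s <- glance(loocv(shuffled, "LOOP01_LEAD", "LOOP01_LAG"))
  expect_lte(s$median, 3 / 9)   # chance is 1/9 over nine time labels
})

test_that("noise sensitivity at scale 0 reproduces the noiseless accuracy", {
  sim <- simulate_loops(n_individuals = 8, n_background_genes = 2,
                        n_planted_pairs = 1, noise_sd = 0.15, seed = 37)
  parts <- split_by_individual(center_to_baseline(sim$data),
                               c("I07", "I08"))
  res0 <- noise_sensitivity(parts$train, parts$test, "LOOP01_LEAD",
                            "LOOP01_LAG", n_reps = 5, noise_scale = 0,
                            seed = 1)
  expect_equal(res0$noisy_accuracy, res0$noiseless_accuracy)
  expect_true(all(res0$rep_accuracies == res0$noiseless_accuracy))
})

test_that("moderate noise barely moves accuracy; huge noise collapses it", {
  sim <- simulate_loops(n_individuals = 8, n_background_genes = 2,
                        n_planted_pairs = 1, noise_sd = 0.1, seed = 38)
  parts <- split_by_individual(center_to_baseline(sim$data),
                               c("I07", "I08"))
  mild <- noise_sensitivity(parts$train, parts$test, "LOOP01_LEAD",
                            "LOOP01_LAG", n_reps = 50, noise_scale = 1,
                            seed = 7)
  expect_lte(abs(mild$noisy_accuracy - mild$noiseless_accuracy), 0.25)

  # sd far beyond the signal amplitude: accuracy approaches the majority-class
  # rate (all 9 time labels equally frequent -> about 1/9)
  wild <- noise_sensitivity(parts$train, parts$test, "LOOP01_LEAD",
                            "LOOP01_LAG", n_reps = 50, noise_scale = 100,
                            seed = 7)
  expect_lte(wild$noisy_accuracy, 0.3)
})

test_that("random pair null separates planted loops from random pairs", {
  sim <- simulate_loops(n_individuals = 10, n_background_genes = 30,
                        n_planted_pairs = 3, noise_sd = 0.1, seed = 39)
  data <- center_to_baseline(sim$data)
  parts <- split_stratified_by_time(data, 0.5, seed = 3)
  candidates <- sim$truth$pairs
  null <- random_pair_null(parts$train, parts$test,
                           genes = unique(data$gene),
                           candidates = candidates, n_random = 30, seed = 3)
  expect_gte(null$ks_statistic, 0.5)
  expect_lt(null$p_value, 0.05)
  # oracle: direct empirical-CDF sup-difference
  expect_equal(null$ks_statistic,
               oracle_ks_stat(null$candidate_accuracy, null$random_accuracy),
               tolerance = 1e-12)
  # planted accuracies stochastically dominate random ones
  w <- stats::wilcox.test(null$candidate_accuracy, null$random_accuracy,
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 0.05)
})

test_that("KS endpoints: identical samples give 0, disjoint supports give 1", {
  x <- c(0.2, 0.5, 0.9)
  expect_equal(oracle_ks_stat(x, x), 0)
  expect_equal(suppressWarnings(stats::ks.test(x, x)$statistic[[1]]), 0)
  lo <- c(0.0, 0.1, 0.2)
  hi <- c(0.8, 0.9, 1.0)
  expect_equal(oracle_ks_stat(hi, lo), 1)
  expect_equal(stats::ks.test(hi, lo)$statistic[[1]], 1)
})

test_that("random pair null validates its inputs", {
  sim <- simulate_loops(n_individuals = 4, n_background_genes = 4,
                        n_planted_pairs = 1, seed = 40)
  data <- center_to_baseline(sim$data)
  parts <- split_stratified_by_time(data, 0.5, seed = 1)
  one_pair <- sim$truth$pairs
  expect_error(random_pair_null(parts$train, parts$test, unique(data$gene),
                                one_pair, n_random = 10),
               "at least 2")
  two <- dplyr::bind_rows(one_pair,
                          tibble::tibble(lead_gene = "BG0001",
                                         lag_gene = "BG0002"))
  expect_error(random_pair_null(parts$train, parts$test, unique(data$gene),
                                two, n_random = 5), "at least 10")
  expect_error(random_pair_null(parts$train, parts$test,
                                unique(data$gene)[1:4], two, n_random = 10),
               "non-candidate")
})
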