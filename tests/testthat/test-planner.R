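test_that("the optimal path picks the sequenceable window set", {
  # windows A=[0.5,10.5], B=[5.5,15.5], C=[12.5,20.5]: {A, C} is the only
  # feasible pair (brute force over all subsets and orders agrees)
  clusters <- abc_clusters()
  dag <- build_dag(clusters, tic_model(), tic_threshold = 1e3,
                   bin_width = 1, min_duration = 1)
  p <- longest_path(dag)
  expect_equal(p$score, 2L)
  expect_equal(p$windows$feature_id, c("A", "C"))
  expect_equal(brute_force_optimum(clusters, tic_model(), abc_config()), 2L)

  # a single feasible window gives a path of score 1 holding that window
  dag1 <- build_dag(clusters[1], tic_model(), tic_threshold = 1e3,
                    bin_width = 1, min_duration = 1)
  p1 <- longest_path(dag1)
  expect_equal(p1$score, 1L)
  expect_equal(p1$windows$feature_id, "A")

  # no window above threshold: empty path of score 0
  dag0 <- build_dag(clusters, tic_model(), tic_threshold = 1e9,
                    bin_width = 1, min_duration = 1)
  expect_equal(longest_path(dag0)$score, 0L)
})

test_that("iterative exclusion schedules the remaining features next", {
  clusters <- abc_clusters()
  paths <- plan_quiet(clusters, tic_model(), abc_config(num_paths = 2L))
  expect_length(paths, 2L)
  expect_equal(paths[[1]]$windows$feature_id, c("A", "C"))
  expect_equal(paths[[2]]$windows$feature_id, "B")
  expect_equal(attr(paths, "scores"), c(2L, 1L))
  expect_equal(vapply(paths, `[[`, integer(1), "index"), 0:1)

  # early stop once features are exhausted
  paths5 <- plan_quiet(clusters[1], tic_model(), abc_config(num_paths = 5L))
  expect_length(paths5, 1L)

  # nothing feasible: empty list
  none <- plan_quiet(clusters, tic_model(),
                     abc_config(num_paths = 3L, tic_threshold = 1e9))
  expect_length(none, 0L)
})

test_that("planner output discretizes onto a valid binary schedule", {
  clusters <- abc_clusters()
  paths <- plan_quiet(clusters, tic_model(), abc_config(num_paths = 2L))
  sm <- to_schedule_matrix(paths, bin_width = 1)
  expect_equal(sm$objective, 3L)

  # single window spanning bins 3..5
  p <- new_path(0L, data.frame(feature_id = "X", iso_mz = 100,
                               rt_start = 3, rt_end = 6,
                               accumulated_intensity = 1, predicted_tic = 1,
                               charge = 0L))
  sm1 <- to_schedule_matrix(p, bin_width = 1)
  expect_equal(sort(sm1$assignments$bin), c(3, 4, 5))
  expect_equal(sm1$objective, 1L)

  # two windows overlapping in a bin violate the one-feature-per-time rule
  bad <- structure(list(index = 0L, windows = data.frame(
    feature_id = c("X", "Y"), iso_mz = c(1, 2), rt_start = c(0, 3),
    rt_end = c(4, 6), accumulated_intensity = c(1, 1),
    predicted_tic = c(1, 1), charge = c(0L, 0L)), score = 2L),
    class = "ms2_path")
  expect_error(to_schedule_matrix(bad, bin_width = 1), "constraint \\(4\\)")

  # a feature acquired in two separate intervals violates contiguity
  split_f <- structure(list(index = 0L, windows = data.frame(
    feature_id = c("X", "X"), iso_mz = c(1, 1), rt_start = c(0, 8),
    rt_end = c(2, 10), accumulated_intensity = c(1, 1),
    predicted_tic = c(1, 1), charge = c(0L, 0L)), score = 2L),
    class = "ms2_path")
  expect_error(to_schedule_matrix(split_f, bin_width = 1),
               "constraint \\(3\\)")
})

test_that("the exhaustive oracle matches the DP on random instances", {
  for (seed in 101:115) {
    inst <- random_small_instance(seed)
    dag <- build_dag(inst$clusters, tic_model(),
                     tic_threshold = inst$config$tic_threshold,
                     bin_width = 2, min_duration = 2)
    lp <- longest_path(dag)
    bf <- brute_force_optimum(inst$clusters, tic_model(), inst$config)
    expect_equal(lp$score, bf,
                 info = sprintf("seed %d: DP %d vs oracle %d", seed,
                                lp$score, bf))
  }
})

test_that("oracle degenerate cases and limits behave", {
  expect_equal(brute_force_optimum(list(), tic_model(), abc_config()), 0L)
  one <- abc_clusters()[1]
  expect_equal(brute_force_optimum(one, tic_model(), abc_config()), 1L)
  many <- replicate(9, abc_clusters()[[1]], simplify = FALSE)
  expect_error(brute_force_optimum(many, tic_model(), abc_config()),
               "too many clusters")
})

test_that("planning is deterministic: identical inputs give identical tables", {
  inst <- random_small_instance(77)
  f1 <- tempfile(); f2 <- tempfile()
  write_paths(plan_quiet(inst$clusters, tic_model(), inst$config), f1)
  write_paths(plan_quiet(inst$clusters, tic_model(), inst$config), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("per-iteration scores never increase and features never repeat", {
  for (seed in 301:306) {
    inst <- random_small_instance(seed)
    paths <- plan_quiet(inst$clusters, tic_model(), inst$config)
    scores <- attr(paths, "scores")
    if (length(scores) > 1L) expect_true(all(diff(scores) <= 0))
    feats <- unlist(lapply(paths, function(p) p$windows$feature_id))
    expect_equal(length(feats), length(unique(feats)))
    expect_equal(length(feats), sum(scores))
  }
})
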