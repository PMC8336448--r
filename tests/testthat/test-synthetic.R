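test_that("noiseless features trace symmetric Gaussians with the stated apex", {
  spec <- synthetic_run_spec(n_features = 1, rt_range = 200,
                             scan_interval = 0.5, peak_width_sigma = 3,
                             noise_sigma = 0, seed = 4)
  run <- generate_run(spec)
  expect_equal(nrow(run$truth), 1L)
  h <- run$truth$intensity_sample
  rt0 <- run$truth$rt
  sig <- run$signals
  expect_equal(sig$intensity,
               h * exp(-(sig$rt - rt0)^2 / (2 * 3^2)))
  expect_true(all(abs(sig$rt - rt0) <= 9))
  # apex height is attained up to grid discretization
  expect_gt(max(sig$intensity), h * exp(-(0.25)^2 / 18))
})

test_that("generation is deterministic in the seed", {
  s1 <- synthetic_run_spec(n_features = 8, n_background = 2, seed = 10)
  s2 <- synthetic_run_spec(n_features = 8, n_background = 2, seed = 11)
  a <- generate_run(s1); b <- generate_run(s1); c <- generate_run(s2)
  expect_identical(a$signals, b$signals)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$signals, c$signals))
})

test_that("background features are counted and flagged in the truth table", {
  run <- generate_run(synthetic_run_spec(n_features = 10, n_background = 3,
                                         seed = 2))
  expect_equal(nrow(run$truth), 13L)
  expect_equal(sum(run$truth$intensity_blank > 0), 3L)
  expect_true(all(run$truth$intensity_blank %in%
                    c(0, run$truth$intensity_sample)))
})

test_that("top-N DDA honours dynamic exclusion", {
  run <- generate_run(synthetic_run_spec(n_features = 1, rt_range = 100,
                                         noise_sigma = 0, seed = 5))
  # exclusion longer than the run: exactly one fragmentation event
  res <- simulate_dda(run$signals, run$truth,
                      dda_config(top_n = 1, exclusion_window = 1000))
  expect_equal(res$n_acquisitions, 1L)

  # two co-eluting features, top-1, no exclusion: the stronger one wins
  # every shared scan
  sig <- data.frame(mz = rep(c(100, 200), each = 3),
                    rt = rep(c(1, 2, 3), 2),
                    intensity = c(10, 10, 10, 20, 20, 20))
  truth <- data.frame(feature_id = c("lo", "hi"), mz = c(100, 200),
                      rt = 2, intensity_sample = c(10, 20),
                      intensity_blank = 0, charge = 0L)
  res2 <- simulate_dda(sig, truth, dda_config(top_n = 1,
                                              exclusion_window = 0))
  expect_equal(res2$n_acquisitions[res2$feature_id == "hi"], 3L)
  expect_equal(res2$n_acquisitions[res2$feature_id == "lo"], 0L)

  # replicates of deterministic dynamics are additive
  res5 <- simulate_dda(sig, truth, dda_config(top_n = 1,
                                              exclusion_window = 0,
                                              n_replicates = 5))
  expect_equal(res5$n_acquisitions, res2$n_acquisitions * 5L)
})

test_that("disjoint well-separated features are fully covered by one path", {
  # 20 features spaced far apart: the first path takes them all
  rt0 <- seq(30, 30 * 20, by = 30)
  clusters <- lapply(seq_along(rt0), function(i) {
    t <- seq(rt0[i] - 6, rt0[i] + 6, by = 0.5)
    make_cluster(sprintf("F%02d", i), 100 + i, t,
                 1e5 * exp(-(t - rt0[i])^2 / (2 * 2^2)))
  })
  paths <- plan_quiet(clusters, tic_model(),
                      planner_config(tic_threshold = 1e3, num_paths = 3L,
                                     bin_width = 0.5, min_duration = 0.5))
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$score, 20L)
})

test_that("cumulative planner coverage grows strictly until exhaustion", {
  run <- crowded_run(8, n_features = 30)
  cl <- assign_quiet(run$signals, run$truth,
                     cluster_tolerance(mz_tol = 0.01, rt_tol = 6))
  paths <- plan_quiet(cl, tic_model(),
                      planner_config(tic_threshold = 1e3, num_paths = 6L))
  cum <- cumsum(attr(paths, "scores"))
  expect_true(all(diff(cum) > 0))
  expect_lte(max(cum), 30)
})
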