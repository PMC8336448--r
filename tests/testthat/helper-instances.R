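# Fixtures are built in code: hand-specified clusters for exact expected
# values, and seeded random planning instances small enough for the
# exhaustive oracle.

# a cluster with explicit member scan points
make_cluster <- function(feature_id, mz, rt, intensity, charge = 0L) {
  o <- order(rt)
  structure(list(feature_id = feature_id, mz = mz,
                 rt = if (length(rt)) rt[o][which.max(intensity[o])] else NA_real_,
                 intensity_sample = if (length(intensity)) max(intensity) else 0,
                 charge = charge,
                 members = data.frame(mz = rep(mz, length(rt)), rt = rt[o],
                                      intensity = intensity[o])),
            class = "ms2_cluster")
}

# three co-eluting clusters whose only feasible windows (at bin_width 1,
# identity TIC model, threshold 1e3) are A = [0.5, 10.5], B = [5.5, 15.5],
# C = [12.5, 20.5]: A and C are sequenceable, every pairing with B
# overlaps; the sub-windows hold fewer than two scan points and integrate
# to zero
abc_clusters <- function(h = 1e4) {
  list(make_cluster("A", 100, c(0, 5, 10), c(h, h, h)),
       make_cluster("B", 200, c(5, 10, 15), c(h, h, h)),
       make_cluster("C", 300, c(12, 16, 20), c(h, h, h)))
}

abc_config <- function(num_paths = 1L, tic_threshold = 1e3) {
  planner_config(tic_threshold = tic_threshold, num_paths = num_paths,
                 bin_width = 1, min_duration = 1)
}

# seeded random planning instance within the exhaustive-oracle limits:
# <= 6 clusters, <= 8 bins per cluster, heavy co-elution, random threshold
random_small_instance <- function(seed) {
  spec <- ms2plan:::with_seed(seed, {
    synthetic_run_spec(
      n_features = sample(1:6, 1L),
      rt_range = 48,
      scan_interval = 2,
      peak_width_sigma = stats::runif(1, 1.2, 2.2),
      height_range = c(5e3, 5e5),
      noise_sigma = 0.1,
      seed = seed + 1000L)
  })
  run <- generate_run(spec)
  clusters <- suppressMessages(assign_signals(
    run$signals, run$truth, cluster_tolerance(mz_tol = 0.01, rt_tol = 8)))
  threshold <- ms2plan:::with_seed(seed + 2000L, 10 ^ stats::runif(1, 2.5, 4.5))
  list(clusters = clusters,
       config = planner_config(tic_threshold = threshold, bin_width = 2,
                               min_duration = 2, num_paths = 6L))
}

# co-elution-heavy medium run for redundancy / coverage comparisons
crowded_run <- function(seed, n_features = 60) {
  generate_run(synthetic_run_spec(
    n_features = n_features, rt_range = 240, scan_interval = 0.5,
    peak_width_sigma = 2, height_range = c(1e4, 1e6),
    noise_sigma = 0.05, seed = seed))
}

plan_quiet <- function(...) suppressMessages(plan_paths(...))
assign_quiet <- function(...) suppressMessages(assign_signals(...))
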