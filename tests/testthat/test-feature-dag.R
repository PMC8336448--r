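test_that("retention-time binning is half-open and anchored at the first member", {
  cl <- make_cluster("F1", 100, c(10.0, 10.4, 10.5, 11.0), c(10, 20, 30, 40))
  b <- bin_cluster(cl, 0.5)
  expect_equal(nrow(b), 3L)
  expect_equal(b$n_members, c(2L, 1L, 1L))  # {10.0, 10.4}, {10.5}, {11.0}
  expect_equal(b$intensity, c(30, 30, 40))
  expect_equal(b$rt, c(10.25, 10.75, 11.25))  # bin midpoints

  single <- make_cluster("F2", 100, 5, 123)
  bs <- bin_cluster(single, 1)
  expect_equal(bs$intensity, 123)

  empty <- make_cluster("F3", 100, numeric(0), numeric(0))
  expect_equal(nrow(bin_cluster(empty, 1)), 0L)
  expect_error(bin_cluster(cl, 0), "bin_width")
})

test_that("weight-1 edges are gated by the TIC threshold and durations", {
  # windows run between bin midpoints, so the members at the first scan sit
  # below the window; the two interior points give integral 0.5*(I+I)/2
  A <- make_cluster("A", 100, c(10, 10.5, 11), rep(3000, 3))  # integral 1500
  B <- make_cluster("B", 200, c(20, 20.5, 21), rep(4000, 3))  # integral 2000
  dag <- build_dag(list(A, B), tic_model(), tic_threshold = 1000,
                   bin_width = 1, min_duration = 1)
  expect_equal(nrow(dag$edges1), 2L)
  expect_setequal(dag$edges1$feature_id, c("A", "B"))
  expect_equal(dag$edges1$accumulated_intensity[dag$edges1$feature_id == "A"],
               1500)

  # weight-0 cross edges only run forward in RT between different clusters
  nodes <- dag$nodes
  out_A <- nodes$node_id[nodes$role == "out" & !is.na(nodes$cluster) &
                           nodes$cluster == 1]
  in_A <- nodes$node_id[nodes$role == "in" & !is.na(nodes$cluster) &
                          nodes$cluster == 1]
  in_B <- nodes$node_id[nodes$role == "in" & !is.na(nodes$cluster) &
                          nodes$cluster == 2]
  out_B <- nodes$node_id[nodes$role == "out" & !is.na(nodes$cluster) &
                           nodes$cluster == 2]
  e0 <- dag$edges0
  expect_true(all(paste(rep(out_A, each = 2), rep(in_B, 2)) %in%
                    paste(e0$from_node, e0$to_node)))
  expect_false(any(e0$from_node %in% out_B & e0$to_node %in% in_A))

  # raising the threshold above A's predicted TIC removes only A's edge
  dag2 <- build_dag(list(A, B), tic_model(), tic_threshold = 1600,
                    bin_width = 1, min_duration = 1)
  expect_equal(dag2$edges1$feature_id, "B")

  # a cluster mapping below threshold contributes no weight-1 edge at all
  dag3 <- build_dag(list(A), tic_model(), tic_threshold = 1e6,
                    bin_width = 1, min_duration = 1)
  expect_equal(nrow(dag3$edges1), 0L)

  # degenerate input: only the virtual source and sink remain
  dag4 <- build_dag(list(), tic_model(), tic_threshold = 1000, bin_width = 1,
                    min_duration = 1)
  expect_equal(nrow(dag4$nodes), 2L)
  expect_equal(nrow(dag4$edges1), 0L)
})

test_that("the DAG is acyclic and its edges respect the topological order", {
  for (seed in c(5, 6, 7)) {
    inst <- random_small_instance(seed)
    dag <- build_dag(inst$clusters, tic_model(),
                     tic_threshold = inst$config$tic_threshold,
                     bin_width = 2, min_duration = 2)
    pos <- integer(max(dag$nodes$node_id))
    pos[dag$topological_order] <- seq_along(dag$topological_order)
    if (nrow(dag$edges1) > 0) {
      expect_true(all(pos[dag$edges1$from_node] < pos[dag$edges1$to_node]))
    }
    expect_true(all(pos[dag$edges0$from_node] < pos[dag$edges0$to_node]))
    # constraint encoding: every admitted window predicts TIC >= threshold
    expect_true(all(dag$edges1$predicted_tic >= inst$config$tic_threshold))
  }
})

test_that("the weight-1 edge set shrinks monotonically with the threshold", {
  inst <- random_small_instance(21)
  key <- function(th) {
    d <- build_dag(inst$clusters, tic_model(), tic_threshold = th,
                   bin_width = 2, min_duration = 2)
    paste(d$edges1$cluster, d$edges1$bin_a, d$edges1$bin_b)
  }
  thresholds <- 10 ^ seq(2, 6, by = 0.5)
  sets <- lapply(thresholds, key)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("a cluster is never scored twice even when another nests inside it", {
  # wide cluster A with feasible windows before and after narrow cluster B:
  # counting weight-1 edges alone would allow the path A, B, A (score 3)
  A <- make_cluster("A", 100, seq(0, 30, by = 2), rep(1e4, 16))
  B <- make_cluster("B", 200, c(14, 16, 18), rep(1e4, 3))
  cfg <- planner_config(tic_threshold = 1e3, bin_width = 2, min_duration = 2)
  dag <- build_dag(list(A, B), tic_model(), tic_threshold = 1e3,
                   bin_width = 2, min_duration = 2)
  # the relaxed sweep alone would propose A, B, A
  w <- dag$edges1[ms2plan:::.lp_prune(dag$edges1), , drop = FALSE]
  sweep_path <- w$feature_id[ms2plan:::.lp_sweep(w, 0)]
  expect_equal(sum(sweep_path == "A"), 2L)
  p <- longest_path(dag)
  expect_equal(p$score, 2L)
  expect_setequal(p$windows$feature_id, c("A", "B"))
  expect_equal(p$score,
               brute_force_optimum(list(A, B), tic_model(), cfg,
                                   limits = list(max_clusters = 8,
                                                 max_bins = 16)))
})
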