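## Step (ii): the feature DAG. Raw signals of each cluster are binned on
## retention time; each non-empty bin becomes a node, split into an in-node
## and an out-node. A weight-1 edge in(a) -> out(b) inside a cluster is a
## feasible acquisition window (predicted MS2 TIC above threshold); a
## weight-0 edge out(u) -> in(v) between different clusters is a transition
## to a feature later in RT. Node splitting means a path that enters a
## cluster must acquire it exactly once before leaving.

#' Bin a cluster's raw signals on retention time
#'
#' Bins are half-open intervals `[t0 + k*w, t0 + (k+1)*w)` anchored at the
#' RT of the cluster's first member. Only non-empty bins yield nodes. A
#' node's intensity is the sum of the member intensities inside its bin;
#' its representative RT is the bin midpoint.
#'
#' @param cluster An `ms2_cluster`.
#' @param bin_width Bin width in seconds (> 0).
#' @return A data frame with one row per non-empty bin: `bin_index`
#'   (0-based), `rt` (bin midpoint, seconds), `intensity`, `n_members`.
#'   Zero rows for an empty cluster.
#' @export
bin_cluster <- function(cluster, bin_width) {
  if (!is_number(bin_width) || bin_width <= 0)
    stop_input("bin_width must be > 0")
  members <- if (inherits(cluster, "ms2_cluster")) cluster$members else cluster
  empty <- data.frame(bin_index = integer(0), rt = numeric(0),
                      intensity = numeric(0), n_members = integer(0))
  if (is.null(members) || nrow(members) == 0L) return(empty)
  rt <- sort(members$rt)
  t0 <- rt[1L]
  ## tiny nudge keeps members sitting exactly on a bin boundary in the
  ## upper (half-open) bin despite floating-point division
  k <- as.integer(floor((sort(members$rt) - t0) / bin_width + 1e-9))
  o <- order(members$rt)
  intensity <- vapply(split(members$intensity[o], k), sum, numeric(1))
  counts <- vapply(split(k, k), length, integer(1))
  ks <- as.integer(names(intensity))
  out <- data.frame(bin_index = ks, rt = t0 + (ks + 0.5) * bin_width,
                    intensity = unname(intensity),
                    n_members = unname(counts))
  out[order(out$bin_index), , drop = FALSE]
}

.median_scan_interval <- function(clusters) {
  rts <- sort(unique(unlist(lapply(clusters, function(cl) cl$members$rt),
                            use.names = FALSE)))
  if (length(rts) < 2L) return(1)
  stats::median(diff(rts))
}

#' Build the feature DAG
#'
#' For every cluster, bins its signals ([bin_cluster()]) and adds a
#' weight-1 edge `in(a) -> out(b)` for every ordered bin pair with
#' `min_duration <= rt_b - rt_a <= max_duration` whose predicted MS2 TIC
#' over the padded window `[rt_a - delta, rt_b + delta]` reaches
#' `tic_threshold`. Between different clusters, a weight-0 edge
#' `out(u) -> in(v)` exists whenever `rt_v >= rt_u + transition_gap`. A
#' virtual source (weight-0 edges to all in-nodes) and sink (from all
#' out-nodes) make the longest-path search single-source/single-sink.
#'
#' On large runs the cross-cluster weight-0 edge set is quadratic; it is
#' materialized only when its size is at most `max_zero_edges` (the edge
#' rule itself — cluster inequality plus the RT gap — is always stored and
#' is what the path search uses, so planning does not depend on
#' materialization).
#'
#' @param clusters `ms2_clusters` list from [assign_signals()].
#' @param model A [tic_model()]; its `delta` is the window padding.
#' @param tic_threshold Minimum predicted MS2 TIC for a window (> 0).
#'   Default 1e3.
#' @param bin_width Bin width in seconds; default: the median inter-scan
#'   interval of the raw signals.
#' @param min_duration,max_duration Window duration bounds in seconds;
#'   defaults: one scan interval and `Inf`.
#' @param transition_gap Minimum RT gap between leaving one cluster and
#'   entering the next (instrument overhead); default 0.
#' @param max_zero_edges Materialization cap for cross-cluster weight-0
#'   edges.
#' @return An object of class `feature_dag` with fields `nodes`, `edges1`,
#'   `edges0` (or `NULL` when over the cap), `clusters_meta`, `params`,
#'   `model`, `topological_order`.
#' @export
build_dag <- function(clusters, model = tic_model(), tic_threshold = 1e3,
                      bin_width = NULL, min_duration = NULL,
                      max_duration = Inf, transition_gap = 0,
                      max_zero_edges = 2e5) {
  stopifnot(inherits(model, "tic_model"))
  if (!is_number(tic_threshold) || tic_threshold <= 0)
    stop_input("tic_threshold must be > 0")
  if (transition_gap < 0) stop_input("transition_gap must be >= 0")
  scan_int <- .median_scan_interval(clusters)
  bin_width <- bin_width %||% scan_int
  min_duration <- min_duration %||% scan_int
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  if (min_duration <= 0 || min_duration > max_duration)
    stop_input("need 0 < min_duration <= max_duration")
  delta <- model$delta

  nc <- length(clusters)
  bins <- vector("list", nc)
  edges <- vector("list", nc)
  for (ci in seq_len(nc)) {
    cl <- clusters[[ci]]
    b <- bin_cluster(cl, bin_width)
    bins[[ci]] <- b
    k <- nrow(b)
    if (k < 2L) next
    ## prefix trapezoid over the member scan points, so the padded-window
    ## integral of any bin pair is a difference of two prefix values
    o <- order(cl$members$rt)
    mrt <- cl$members$rt[o]
    mI <- cl$members$intensity[o]
    C <- c(0, cumsum(diff(mrt) * (mI[-length(mI)] + mI[-1L]) / 2))
    r <- b$rt
    lo <- findInterval(r - delta, mrt, left.open = TRUE) + 1L
    hi <- findInterval(r + delta, mrt)
    A <- rep(seq_len(k), times = k)
    B <- rep(seq_len(k), each = k)
    dur <- r[B] - r[A]
    keep <- B > A & dur >= min_duration * (1 - 1e-9) &
      dur <= max_duration * (1 + 1e-9)
    A <- A[keep]; B <- B[keep]
    if (length(A) == 0L) next
    integral <- ifelse(hi[B] - lo[A] >= 1L, C[pmax(hi[B], 1L)] - C[lo[A]], 0)
    integral <- pmax(integral, 0)
    ptic <- predict_tic(model, integral)
    ok <- ptic >= tic_threshold
    if (!any(ok)) next
    edges[[ci]] <- data.frame(
      cluster = ci, bin_a = b$bin_index[A[ok]], bin_b = b$bin_index[B[ok]],
      rt_start = r[A[ok]], rt_end = r[B[ok]],
      accumulated_intensity = integral[ok], predicted_tic = ptic[ok])
  }

  ## nodes: source (id 1), sink (id 2), then an in/out pair per bin
  n_bins <- vapply(bins, nrow, integer(1))
  total_bins <- sum(n_bins)
  node_cluster <- rep(seq_len(nc), n_bins)
  node_bin <- unlist(lapply(bins, `[[`, "bin_index"), use.names = FALSE) %||% integer(0)
  node_rt <- unlist(lapply(bins, `[[`, "rt"), use.names = FALSE) %||% numeric(0)
  node_int <- unlist(lapply(bins, `[[`, "intensity"), use.names = FALSE) %||% numeric(0)
  in_id <- if (total_bins > 0L) 2L + 2L * seq_len(total_bins) - 1L else integer(0)
  out_id <- in_id + 1L
  nodes <- rbind(
    data.frame(node_id = 1:2, cluster = NA_integer_, bin_index = NA_integer_,
               rt = c(-Inf, Inf), intensity = 0,
               role = c("source", "sink")),
    data.frame(node_id = c(in_id, out_id),
               cluster = c(node_cluster, node_cluster),
               bin_index = c(node_bin, node_bin), rt = c(node_rt, node_rt),
               intensity = c(node_int, node_int),
               role = rep(c("in", "out"), each = total_bins))
  )
  rownames(nodes) <- NULL

  ## map (cluster, bin) -> node ids for edge endpoints
  key <- paste(node_cluster, node_bin)
  edges1 <- rbind_rows(edges)
  if (is.null(edges1)) {
    edges1 <- data.frame(cluster = integer(0), bin_a = integer(0),
                         bin_b = integer(0), rt_start = numeric(0),
                         rt_end = numeric(0),
                         accumulated_intensity = numeric(0),
                         predicted_tic = numeric(0))
  }
  edges1$from_node <- in_id[match(paste(edges1$cluster, edges1$bin_a), key)]
  edges1$to_node <- out_id[match(paste(edges1$cluster, edges1$bin_b), key)]
  edges1$feature_id <- vapply(clusters, `[[`, character(1), "feature_id")[edges1$cluster] %||% character(0)

  ## weight-0 edges: source -> every in-node, every out-node -> sink, and
  ## cross-cluster out -> in with rt_in >= rt_out + gap (materialized only
  ## below the cap)
  edges0 <- data.frame(from_node = c(rep(1L, total_bins), out_id),
                       to_node = c(in_id, rep(2L, total_bins)))
  cross_count <- 0
  materialized <- TRUE
  if (total_bins > 0L) {
    in_ord <- order(node_rt)
    in_rt_sorted <- node_rt[in_ord]
    n_after <- length(in_rt_sorted) -
      findInterval(node_rt + transition_gap, in_rt_sorted, left.open = TRUE)
    ## same-cluster in-nodes that satisfy the gap must not be counted
    same_cl <- numeric(total_bins)
    for (idx in split(seq_len(total_bins), node_cluster)) {
      rts <- sort(node_rt[idx])
      same_cl[idx] <- length(rts) -
        findInterval(node_rt[idx] + transition_gap, rts, left.open = TRUE)
    }
    cross_count <- sum(n_after - same_cl)
    if (cross_count <= max_zero_edges && total_bins <= 5000L) {
      cross <- vector("list", total_bins)
      for (i in seq_len(total_bins)) {
        sel <- which(node_rt >= node_rt[i] + transition_gap &
                       node_cluster != node_cluster[i])
        if (length(sel) > 0L) {
          cross[[i]] <- data.frame(from_node = out_id[i], to_node = in_id[sel])
        }
      }
      cross <- rbind_rows(cross)
      if (!is.null(cross)) edges0 <- rbind(edges0, cross)
    } else {
      materialized <- FALSE
    }
  }

  ## topological order: increasing RT; at equal RT out-nodes precede
  ## in-nodes (weight-0 edges may join them at gap 0)
  role_rank <- c(source = 0L, out = 1L, `in` = 2L, sink = 3L)
  topo <- nodes$node_id[order(nodes$rt, role_rank[nodes$role])]

  dag <- structure(list(
    nodes = nodes, edges1 = edges1,
    edges0 = if (materialized) edges0 else NULL,
    zero_edges_materialized = materialized,
    clusters_meta = data.frame(
      cluster = seq_len(nc),
      feature_id = vapply(clusters, `[[`, character(1), "feature_id") %||% character(0),
      mz = vapply(clusters, `[[`, numeric(1), "mz") %||% numeric(0),
      charge = vapply(clusters, function(cl) as.integer(cl$charge %||% 0L),
                      integer(1)) %||% integer(0),
      n_bins = n_bins %||% integer(0),
      stringsAsFactors = FALSE),
    params = list(bin_width = bin_width, min_duration = min_duration,
                  max_duration = max_duration,
                  transition_gap = transition_gap,
                  tic_threshold = tic_threshold, delta = delta),
    model = model,
    topological_order = topo), class = "feature_dag")
  .check_dag_acyclic(dag)
  dag
}

## every edge must run forward in the topological order; violation would
## mean the construction invariant is broken
.check_dag_acyclic <- function(dag) {
  pos <- integer(max(dag$nodes$node_id))
  pos[dag$topological_order] <- seq_along(dag$topological_order)
  bad1 <- nrow(dag$edges1) > 0L &&
    any(pos[dag$edges1$from_node] >= pos[dag$edges1$to_node])
  bad0 <- !is.null(dag$edges0) && nrow(dag$edges0) > 0L &&
    any(pos[dag$edges0$from_node] >= pos[dag$edges0$to_node])
  if (bad1 || bad0) {
    stop("internal invariant violated: feature DAG edge against topological order")
  }
  invisible(TRUE)
}

#' @export
print.feature_dag <- function(x, ...) {
  cat(sprintf("<feature_dag> %d cluster(s), %d node(s), %d weight-1 edge(s)\n",
              nrow(x$clusters_meta), nrow(x$nodes), nrow(x$edges1)))
  cat(sprintf("  tic_threshold = %g, bin_width = %g s, gap = %g s, weight-0 edges %s\n",
              x$params$tic_threshold, x$params$bin_width,
              x$params$transition_gap,
              if (x$zero_edges_materialized) "materialized" else "implicit"))
  invisible(x)
}
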