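## Steps (iii)-(iv): dynamic programming over the DAG's topological order
## to find the acquisition path traversing the most weight-1 edges, then
## iterative whole-feature exclusion to schedule further injections.
##
## The search runs over the weight-1 edges (candidate windows) directly:
## sorting windows by RT is a topological order of the split-node DAG, and
## the weight-0 transitions are relaxed in aggregate with running prefix
## maxima instead of edge by edge, which keeps planning near-linear in the
## number of windows. A path may in principle re-enter a cluster through a
## third one whose window nests between two of its own (the transition
## edges cannot see path history); when the fast sweep returns such a path
## the solver switches to an exact pass with a bitmask over the few
## clusters for which re-entry is geometrically possible, so the reported
## score always counts distinct features.

#' Planner configuration
#'
#' @param tic_threshold Minimum predicted MS2 TIC for an acquisition
#'   window (> 0). Default 1e3.
#' @param num_paths Number of targeted injections to plan (>= 1).
#' @param bin_width,min_duration,max_duration,transition_gap DAG
#'   construction parameters, see [build_dag()].
#' @return An object of class `planner_config`.
#' @export
planner_config <- function(tic_threshold = 1e3, num_paths = 1L,
                           bin_width = NULL, min_duration = NULL,
                           max_duration = Inf, transition_gap = 0) {
  if (!is_number(tic_threshold) || tic_threshold <= 0)
    stop_input("tic_threshold must be > 0")
  num_paths <- as.integer(num_paths)
  if (is.na(num_paths) || num_paths < 1L)
    stop_input("num_paths must be >= 1")
  structure(list(tic_threshold = tic_threshold, num_paths = num_paths,
                 bin_width = bin_width, min_duration = min_duration,
                 max_duration = max_duration,
                 transition_gap = transition_gap),
            class = "planner_config")
}

## ---- path search over candidate windows -------------------------------

## strict "state (i, m) beats state (j, mm)": more windows, then larger
## accumulated intensity, then lexicographically earlier rt_start
## sequence, then smaller window index (states are identified by a window
## and the bitmask of masked clusters their path has used)
.lp_seq <- function(i, m, pw, pm, starts) {
  out <- numeric(0)
  while (i > 0L) {
    out <- c(starts[i], out)
    nm <- pm[i, m + 1L]
    i <- pw[i, m + 1L]
    m <- nm
  }
  out
}

.lp_better <- function(i, m, j, mm, sc, ac, pw, pm, starts) {
  if (sc[i, m + 1L] != sc[j, mm + 1L]) {
    return(sc[i, m + 1L] > sc[j, mm + 1L])
  }
  if (ac[i, m + 1L] != ac[j, mm + 1L]) {
    return(ac[i, m + 1L] > ac[j, mm + 1L])
  }
  si <- .lp_seq(i, m, pw, pm, starts)
  sj <- .lp_seq(j, mm, pw, pm, starts)
  for (k in seq_along(si)) {
    if (si[k] != sj[k]) return(si[k] < sj[k])
  }
  i < j
}

## containment dominance inside a cluster: a window strictly containing
## another window of the same cluster can be replaced by it in any path
## without lowering the score, so only minimal windows are searched
.lp_prune <- function(w) {
  keep <- logical(nrow(w))
  for (idx in split(seq_len(nrow(w)), w$cluster)) {
    o <- idx[order(-w$rt_start[idx], w$rt_end[idx])]
    min_end <- Inf
    for (i in o) {
      if (w$rt_end[i] < min_end) {
        keep[i] <- TRUE
        min_end <- w$rt_end[i]
      }
    }
  }
  keep
}

## Sweep DP over windows in rt_start order. Transitions into a window are
## relaxed in aggregate: a running "best state / best state of another
## cluster" pair per bitmask, fed by a pointer over windows ordered by
## rt_end (+gap). `dclusters` lists clusters whose repeats are excluded
## exactly via the bitmask (each may be used at most once along a path);
## all other clusters are only kept distinct from their immediate
## predecessor. With `dclusters` empty this is the plain relaxed sweep.
.lp_sweep <- function(w, gap, dclusters = integer(0)) {
  n <- nrow(w)
  nb <- length(dclusters)
  M <- bitwShiftL(1L, nb)
  ord <- order(w$rt_start, w$rt_end, -w$accumulated_intensity, w$cluster)
  start <- w$rt_start[ord]; end <- w$rt_end[ord]
  acc <- w$accumulated_intensity[ord]; cl <- w$cluster[ord]
  bit <- integer(n)
  for (k in seq_len(nb)) bit[cl == dclusters[k]] <- bitwShiftL(1L, k - 1L)
  by_end <- order(end)
  sc <- matrix(-Inf, n, M); ac <- matrix(0, n, M)
  pw <- matrix(0L, n, M); pm <- matrix(0L, n, M)
  ## per mask: best state and best state from another cluster than b1's
  b1 <- integer(M); b2 <- integer(M)
  j <- 1L
  for (i in seq_len(n)) {
    while (j <= n && end[by_end[j]] + gap <= start[i]) {
      k <- by_end[j]
      for (m in which(sc[k, ] > -Inf) - 1L) {
        mi <- m + 1L
        if (b1[mi] == 0L) {
          b1[mi] <- k
        } else if (.lp_better(k, m, b1[mi], m, sc, ac, pw, pm, start)) {
          if (cl[k] != cl[b1[mi]]) b2[mi] <- b1[mi]
          b1[mi] <- k
        } else if (cl[k] != cl[b1[mi]] &&
                   (b2[mi] == 0L ||
                      .lp_better(k, m, b2[mi], m, sc, ac, pw, pm, start))) {
          b2[mi] <- k
        }
      }
      j <- j + 1L
    }
    b <- bit[i]
    for (m in seq_len(M) - 1L) {
      if (b > 0L && bitwAnd(m, b) == 0L) next
      mp <- m - b
      cand <- if (b1[mp + 1L] != 0L && cl[b1[mp + 1L]] != cl[i]) {
        b1[mp + 1L]
      } else {
        b2[mp + 1L]
      }
      if (cand != 0L) {
        sc[i, m + 1L] <- sc[cand, mp + 1L] + 1
        ac[i, m + 1L] <- ac[cand, mp + 1L] + acc[i]
        pw[i, m + 1L] <- cand; pm[i, m + 1L] <- mp
      } else if (m == b) {
        sc[i, m + 1L] <- 1; ac[i, m + 1L] <- acc[i]
      }
    }
  }
  top <- which(sc == max(sc), arr.ind = TRUE)
  bi <- top[1L, 1L]; bm <- top[1L, 2L] - 1L
  if (nrow(top) > 1L) {
    for (r in seq_len(nrow(top))[-1L]) {
      if (.lp_better(top[r, 1L], top[r, 2L] - 1L, bi, bm,
                     sc, ac, pw, pm, start)) {
        bi <- top[r, 1L]; bm <- top[r, 2L] - 1L
      }
    }
  }
  chain <- integer(0)
  i <- bi; m <- bm
  while (i > 0L) {
    chain <- c(i, chain)
    nm <- pm[i, m + 1L]
    i <- pw[i, m + 1L]
    m <- nm
  }
  ord[chain]
}

## Exact subset DP over clusters (small instances). State: for every
## cluster subset, the minimal RT at which all its members can have been
## acquired in some order (earliest completion is the right state by the
## usual exchange argument). The optimum is the largest subset with a
## finite completion time. Exponential in the number of clusters, so only
## used when that number is small.
.lp_exact_subsets <- function(w, gap) {
  cls <- sort(unique(w$cluster))
  nc <- length(cls)
  cidx <- match(w$cluster, cls)
  per <- vector("list", nc)
  for (c in seq_len(nc)) {
    idx <- which(cidx == c)
    o <- idx[order(w$rt_start[idx], w$rt_end[idx])]
    ends <- w$rt_end[o]
    sufmin <- integer(length(o))  # position of min end within o[p..len]
    bestp <- length(o)
    for (p in rev(seq_along(o))) {
      if (ends[p] <= ends[bestp]) bestp <- p
      sufmin[p] <- bestp
    }
    per[[c]] <- list(rows = o, starts = w$rt_start[o], ends = ends,
                     sufmin = sufmin)
  }
  M <- bitwShiftL(1L, nc)
  f <- rep(Inf, M)
  f[1L] <- -Inf
  from_c <- integer(M); from_w <- integer(M)
  for (m in seq_len(M - 1L)) {
    mi <- m + 1L
    for (c in seq_len(nc)) {
      b <- bitwShiftL(1L, c - 1L)
      if (bitwAnd(m, b) == 0L) next
      prev <- f[m - b + 1L]
      if (prev == Inf) next
      P <- per[[c]]
      pos <- findInterval(prev + gap, P$starts, left.open = TRUE) + 1L
      if (pos > length(P$starts)) next
      k <- P$sufmin[pos]
      e <- P$ends[k]
      if (e < f[mi] || (e == f[mi] && c < from_c[mi])) {
        f[mi] <- e; from_c[mi] <- c; from_w[mi] <- P$rows[k]
      }
    }
  }
  pc <- integer(M)
  for (m in seq_len(M - 1L)) {
    pc[m + 1L] <- pc[bitwShiftR(m, 1L) + 1L] + m %% 2L
  }
  ok <- which(f < Inf)
  best <- ok[order(-pc[ok], f[ok], ok)][1L]
  sel <- integer(0)
  m <- best - 1L
  while (m > 0L) {
    sel <- c(from_w[m + 1L], sel)
    m <- m - bitwShiftL(1L, from_c[m + 1L] - 1L)
  }
  sel[order(w$rt_start[sel])]
}

## earliest-finish greedy over all windows, one per cluster: the classic
## interval-scheduling heuristic, used only as a large-instance fallback
.lp_greedy <- function(w, gap) {
  o <- order(w$rt_end, w$rt_start, -w$accumulated_intensity)
  used <- integer(0)
  sel <- integer(0)
  last_end <- -Inf
  for (i in o) {
    if (w$rt_start[i] >= last_end + gap && !(w$cluster[i] %in% used)) {
      sel <- c(sel, i)
      used <- c(used, w$cluster[i])
      last_end <- w$rt_end[i]
    }
  }
  sel[order(w$rt_start[sel])]
}

## Solve for the maximum number of distinct clusters acquirable in one
## pass. Small instances (clusters <= exact_cap) are solved exactly by
## the subset DP. Larger ones use the relaxed sweep; when its path revisits
## a cluster, the revisited clusters are masked exactly and the sweep
## re-runs (lazy mask growth) -- a duplicate-free result is provably
## optimal because the relaxation only over-counts. If the mask set grows
## beyond budget the solver falls back to the better of the repaired sweep
## path and an earliest-finish greedy, with a message.
.lp_solve <- function(windows, gap, exact_cap = 13L) {
  if (nrow(windows) == 0L) return(integer(0))
  windows$row <- seq_len(nrow(windows))
  w <- windows[.lp_prune(windows), , drop = FALSE]
  if (length(unique(w$cluster)) <= exact_cap) {
    return(w$row[.lp_exact_subsets(w, gap)])
  }
  dcl <- integer(0)
  repeat {
    sel <- .lp_sweep(w, gap, dcl)
    dup <- unique(w$cluster[sel][duplicated(w$cluster[sel])])
    if (length(dup) == 0L) break
    dcl <- union(dcl, dup)
    if (nrow(w) * 2^length(dcl) > 2e6) {
      repaired <- sel[!duplicated(w$cluster[sel])]
      greedy <- .lp_greedy(w, gap)
      sel <- if (length(greedy) >= length(repaired)) greedy else repaired
      message("path search: heavily interleaved instance; using the best ",
              "feasible path found (", length(sel), " features) without an ",
              "optimality certificate")
      break
    }
  }
  w$row[sel]
}

## ---- exported planner operations --------------------------------------

#' Find the optimal acquisition path in a feature DAG
#'
#' Returns the source-to-sink path maximizing the number of weight-1 edges
#' of distinct clusters (distinct features fragmented above the TIC
#' threshold). Small instances are solved exactly by a subset DP over
#' clusters, with ties resolved toward earlier-finishing schedules; large
#' instances use a relaxed sweep DP over the topological order (ties
#' toward larger accumulated intensity, then the lexicographically
#' earliest window-start sequence) with exact lazy masking of any cluster
#' the relaxed path revisits. Either way the result is deterministic. The
#' search prunes windows strictly containing another window of the same
#' cluster, which leaves the optimal score unchanged.
#'
#' @param dag A [build_dag()] result.
#' @param exclude Character vector of feature_ids whose clusters are
#'   removed before the search (used by the iteration in [plan_paths()]).
#' @param index Path index to stamp on the result.
#' @return An `ms2_path` ([new_path()]); empty with score 0 when no
#'   feasible window exists.
#' @export
longest_path <- function(dag, exclude = NULL, index = 0L) {
  stopifnot(inherits(dag, "feature_dag"))
  w <- dag$edges1
  if (!is.null(exclude)) w <- w[!w$feature_id %in% exclude, , drop = FALSE]
  rows <- .lp_solve(w, dag$params$transition_gap)
  if (length(rows) == 0L) return(new_path(index))
  sel <- w[rows, , drop = FALSE]
  meta <- dag$clusters_meta[match(sel$cluster, dag$clusters_meta$cluster), ]
  windows <- data.frame(
    feature_id = meta$feature_id, iso_mz = meta$mz,
    rt_start = sel$rt_start, rt_end = sel$rt_end,
    accumulated_intensity = sel$accumulated_intensity,
    predicted_tic = sel$predicted_tic, charge = meta$charge,
    stringsAsFactors = FALSE)
  windows <- windows[order(windows$rt_start), , drop = FALSE]
  rownames(windows) <- NULL
  new_path(index, windows)
}

#' Plan multiple acquisition paths by iterative feature exclusion
#'
#' Builds the feature DAG once, finds the optimal path, removes every
#' feature it acquires, and repeats on the remainder until `num_paths`
#' paths are planned or a search returns score 0 (all remaining features
#' infeasible). Feature sets across paths are therefore pairwise disjoint
#' and per-iteration scores are nonincreasing.
#'
#' @param clusters `ms2_clusters` from [assign_signals()].
#' @param model A [tic_model()].
#' @param config A [planner_config()].
#' @return List of `ms2_path` objects with indices `0..k` (possibly
#'   empty), with attribute `scores` (integer vector of per-iteration
#'   scores).
#' @export
plan_paths <- function(clusters, model = tic_model(),
                       config = planner_config()) {
  stopifnot(inherits(config, "planner_config"))
  dag <- build_dag(clusters, model,
                   tic_threshold = config$tic_threshold,
                   bin_width = config$bin_width,
                   min_duration = config$min_duration,
                   max_duration = config$max_duration,
                   transition_gap = config$transition_gap)
  paths <- list()
  excluded <- character(0)
  for (k in seq_len(config$num_paths) - 1L) {
    p <- longest_path(dag, exclude = excluded, index = k)
    if (p$score == 0L) break
    message(sprintf("plan_paths: iteration %d acquires %d feature(s)",
                    k, p$score))
    paths[[length(paths) + 1L]] <- p
    excluded <- c(excluded, p$windows$feature_id)
  }
  structure(paths, scores = vapply(paths, `[[`, integer(1), "score"))
}

#' Discretize paths onto the binary schedule matrix
#'
#' Bridges the continuous-time planner output back to the binary indicator
#' formulation it solves: features in rows, RT bins in columns, one binary
#' matrix slice per path. A bin belongs to a window when the window covers
#' the bin midpoint, so RT-disjoint windows can never collide in a bin.
#' For each path it verifies that every feature's acquisitions form one
#' contiguous bin run, that no bin holds more than one feature, and that
#' entries are binary; a violation raises a validation error naming the
#' violated constraint. Windows of different paths may overlap freely
#' (they are separate injections).
#'
#' @param paths Path or list of paths.
#' @param bin_width Discretization bin width in seconds (> 0); must not
#'   exceed the shortest window duration, or a window would cover no bin
#'   midpoint.
#' @return An object of class `schedule_matrix`: `features`, `n_bins`,
#'   `time_bins` (bin start times), `assignments` (data frame
#'   `path_index`, `bin`, `feature_id`) and `objective`, the number of
#'   distinct features acquired at least once.
#' @export
to_schedule_matrix <- function(paths, bin_width) {
  if (!is_number(bin_width) || bin_width <= 0)
    stop_input("bin_width must be > 0")
  paths <- as_path_list(paths)
  rows <- list()
  for (p in paths) {
    w <- p$windows
    if (nrow(w) == 0L) next
    ## bin k (midpoint (k + 0.5) * w) is assigned when the window covers
    ## its midpoint: [s, e) with s <= mid < e
    eps <- 1e-9 * bin_width
    k_lo <- ceiling((w$rt_start - eps) / bin_width - 0.5)
    k_hi <- ceiling((w$rt_end - eps) / bin_width - 0.5) - 1
    if (any(k_hi < k_lo)) {
      stop_input("to_schedule_matrix: bin_width ", bin_width,
                 " is coarser than the shortest window; no bin midpoint covered")
    }
    asg <- do.call(rbind, lapply(seq_len(nrow(w)), function(i) {
      data.frame(path_index = p$index, bin = seq(k_lo[i], k_hi[i]),
                 feature_id = w$feature_id[i], stringsAsFactors = FALSE)
    }))
    if (anyDuplicated(paste(asg$feature_id, asg$bin))) {
      stop_validation("schedule violates constraint (5): non-binary entry ",
                      "for a (time, feature) pair in path ", p$index)
    }
    for (fid in unique(asg$feature_id)) {
      b <- sort(asg$bin[asg$feature_id == fid])
      if (length(b) > 1L && any(diff(b) != 1)) {
        stop_validation("schedule violates constraint (3): feature ", fid,
                        " acquired in separate intervals in path ", p$index)
      }
    }
    dup_bin <- asg$bin[duplicated(asg$bin)]
    if (length(dup_bin) > 0L) {
      stop_validation("schedule violates constraint (4): more than one ",
                      "feature in bin ", dup_bin[1L], " of path ", p$index)
    }
    rows[[length(rows) + 1L]] <- asg
  }
  assignments <- rbind_rows(rows)
  if (is.null(assignments)) {
    assignments <- data.frame(path_index = integer(0), bin = numeric(0),
                              feature_id = character(0))
  }
  features <- unique(unlist(lapply(paths, function(p) p$windows$feature_id),
                            use.names = FALSE)) %||% character(0)
  n_bins <- if (nrow(assignments) > 0L) max(assignments$bin) + 1L else 0L
  structure(list(features = features, bin_width = bin_width,
                 n_bins = n_bins,
                 time_bins = seq_len(n_bins) * bin_width - bin_width,
                 assignments = assignments,
                 objective = length(unique(assignments$feature_id))),
            class = "schedule_matrix")
}

#' Exhaustive optimum for small planning instances
#'
#' Test oracle: enumerates every ordering of every cluster subset and, for
#' a fixed ordering, selects windows greedily by earliest finishing time
#' (optimal for a fixed order by an exchange argument). Windows are
#' enumerated with a direct double loop over bin pairs using
#' [integrate_intensity()] and [predict_tic()], independent of the
#' vectorized DAG construction. Exponential in the number of clusters, so
#' instances beyond `limits` are refused.
#'
#' @param clusters `ms2_clusters`.
#' @param model A [tic_model()].
#' @param config A [planner_config()] (only the DAG/threshold parameters
#'   are used).
#' @param limits List with `max_clusters` (default 8) and `max_bins`
#'   (default 12).
#' @return Integer: the maximum number of distinct features acquirable in
#'   one path.
#' @export
brute_force_optimum <- function(clusters, model = tic_model(),
                                config = planner_config(),
                                limits = list(max_clusters = 8L,
                                              max_bins = 12L)) {
  if (length(clusters) > (limits$max_clusters %||% 8L)) {
    stop_input("brute_force_optimum: too many clusters (limit ",
               limits$max_clusters %||% 8L, ")")
  }
  scan_int <- .median_scan_interval(clusters)
  bw <- config$bin_width %||% scan_int
  min_dur <- config$min_duration %||% scan_int
  max_dur <- config$max_duration %||% Inf
  gap <- config$transition_gap %||% 0
  delta <- model$delta

  cl_windows <- list()
  for (cl in clusters) {
    b <- bin_cluster(cl, bw)
    if (nrow(b) > (limits$max_bins %||% 12L)) {
      stop_input("brute_force_optimum: cluster with too many bins (limit ",
                 limits$max_bins %||% 12L, ")")
    }
    if (nrow(b) < 2L) next
    wins <- NULL
    for (a in seq_len(nrow(b) - 1L)) {
      for (bb in (a + 1L):nrow(b)) {
        dur <- b$rt[bb] - b$rt[a]
        if (dur < min_dur * (1 - 1e-9) || dur > max_dur * (1 + 1e-9)) next
        integral <- integrate_intensity(cl, b$rt[a], b$rt[bb], delta)
        if (predict_tic(model, integral) >= config$tic_threshold) {
          wins <- rbind(wins, data.frame(start = b$rt[a], end = b$rt[bb]))
        }
      }
    }
    if (!is.null(wins)) {
      cl_windows[[length(cl_windows) + 1L]] <- wins[order(wins$end), ,
                                                    drop = FALSE]
    }
  }
  nc <- length(cl_windows)
  if (nc == 0L) return(0L)

  best <- 0L
  recurse <- function(used, t_end) {
    depth <- sum(used)
    if (depth > best) best <<- depth
    if (depth + sum(!used) <= best) return()
    for (c in which(!used)) {
      wins <- cl_windows[[c]]
      ok <- wins$start >= t_end + gap
      if (any(ok)) {
        used[c] <- TRUE
        recurse(used, wins$end[which(ok)[1L]])
        used[c] <- FALSE
      }
    }
  }
  recurse(rep(FALSE, nc), -Inf)
  best
}

#' @export
print.schedule_matrix <- function(x, ...) {
  cat(sprintf("<schedule_matrix> %d feature(s), %d bin(s) of %g s, objective %d\n",
              length(x$features), x$n_bins, x$bin_width, x$objective))
  invisible(x)
}
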