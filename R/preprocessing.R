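## Step (i) of the pipeline: drop features that are also present in the
## background/control sample, then map every raw MS1 scan point to the
## cluster of its nearest apex.

#' Clustering tolerance
#'
#' The nearest-neighbor assignment of raw signals to apexes needs a scale:
#' a signal is eligible for an apex only if it lies within `mz_tol` in m/z
#' AND `rt_tol` in retention time of it. Distances are measured as
#' Chebyshev distance in tolerance-scaled coordinates,
#' `d = max(|dmz|/mz_tol, |drt|/rt_tol)`, with a hard cutoff at 1.
#'
#' Defaults (0.01 Th, 5 s) suit high-resolution instruments with
#' chromatographic peaks a few seconds wide.
#'
#' @param mz_tol m/z tolerance in Th (> 0).
#' @param rt_tol RT tolerance in seconds (> 0).
#' @return An object of class `cluster_tolerance`.
#' @export
cluster_tolerance <- function(mz_tol = 0.01, rt_tol = 5) {
  if (!is_number(mz_tol) || mz_tol <= 0) stop_input("mz_tol must be > 0")
  if (!is_number(rt_tol) || rt_tol <= 0) stop_input("rt_tol must be > 0")
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol),
            class = "cluster_tolerance")
}

#' Discard features detected in the background/control sample
#'
#' A feature is retained if it has no blank-channel signal
#' (`intensity_blank == 0`) or if its sample-to-blank intensity ratio is at
#' least `min_ratio`. Everything else is treated as background (solvent,
#' carry-over, plasticizers) and removed before planning, so such features
#' never consume acquisition time. Input order is preserved; a message
#' reports how many features were discarded.
#'
#' @param apexes Apex table as returned by [read_apexes()].
#' @param min_ratio Minimum sample/blank intensity ratio (> 0) for a
#'   feature with blank signal to survive. Default 3.
#' @return The filtered apex table (possibly empty).
#' @export
filter_background <- function(apexes, min_ratio = 3) {
  if (!is_number(min_ratio) || min_ratio <= 0)
    stop_input("min_ratio must be > 0")
  if (nrow(apexes) == 0L) return(apexes)
  keep <- apexes$intensity_blank == 0 |
    apexes$intensity_sample / apexes$intensity_blank >= min_ratio
  if (any(!keep)) {
    message(sprintf("filter_background: discarded %d background feature(s)",
                    sum(!keep)))
  }
  out <- apexes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign raw MS1 signals to apex-centered clusters
#'
#' Each scan point is assigned to at most one cluster: the apex minimizing
#' the tolerance-scaled Chebyshev distance
#' `d = max(|mz_s - mz_a| / mz_tol, |rt_s - rt_a| / rt_tol)`, provided
#' `d <= 1`. Signals farther than the tolerance from every apex remain
#' unassigned (their count is reported as an attribute and a message). Ties
#' are broken by smaller `|dmz|`, then by feature_id, so the assignment is
#' deterministic. Every apex yields a cluster, possibly with an empty
#' member list.
#'
#' @param signals Raw-signal data frame (`mz`, `rt`, `intensity`).
#' @param apexes Apex table (must be non-empty), typically after
#'   [filter_background()].
#' @param tol A [cluster_tolerance()].
#' @return A list of `ms2_cluster` objects (class `ms2_clusters`), one per
#'   apex and in apex order. Each cluster carries the apex fields and a
#'   `members` data frame sorted by RT. Attribute `unassigned` holds the
#'   number of unassigned signals.
#' @export
assign_signals <- function(signals, apexes, tol = cluster_tolerance()) {
  stopifnot(inherits(tol, "cluster_tolerance"))
  if (is.null(apexes) || nrow(apexes) == 0L)
    stop_input("assign_signals: apex list is empty")
  ns <- nrow(signals)
  ord <- order(signals$rt, signals$mz)
  sig <- signals[ord, , drop = FALSE]

  ## candidate (signal, apex) pairs: for each apex, the RT-sorted slice of
  ## signals within rt_tol, narrowed by the m/z tolerance
  cand_sig <- integer(0); cand_apex <- integer(0)
  cand_d <- numeric(0); cand_admz <- numeric(0)
  if (ns > 0L) {
    lo <- findInterval(apexes$rt - tol$rt_tol, sig$rt, left.open = TRUE) + 1L
    hi <- findInterval(apexes$rt + tol$rt_tol, sig$rt)
    parts <- vector("list", nrow(apexes))
    for (a in seq_len(nrow(apexes))) {
      if (lo[a] > hi[a]) next
      idx <- lo[a]:hi[a]
      admz <- abs(sig$mz[idx] - apexes$mz[a])
      sel <- admz <= tol$mz_tol
      if (!any(sel)) next
      idx <- idx[sel]; admz <- admz[sel]
      d <- pmax(admz / tol$mz_tol, abs(sig$rt[idx] - apexes$rt[a]) / tol$rt_tol)
      parts[[a]] <- list(s = idx, a = rep.int(a, length(idx)), d = d,
                         admz = admz)
    }
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) > 0L) {
      cand_sig <- unlist(lapply(parts, `[[`, "s"), use.names = FALSE)
      cand_apex <- unlist(lapply(parts, `[[`, "a"), use.names = FALSE)
      cand_d <- unlist(lapply(parts, `[[`, "d"), use.names = FALSE)
      cand_admz <- unlist(lapply(parts, `[[`, "admz"), use.names = FALSE)
    }
  }

  ## per signal keep the nearest apex (d, then |dmz|, then feature_id)
  assignment <- rep.int(NA_integer_, ns)
  if (length(cand_sig) > 0L) {
    o <- order(cand_sig, cand_d, cand_admz, apexes$feature_id[cand_apex])
    keep <- !duplicated(cand_sig[o])
    assignment[cand_sig[o][keep]] <- cand_apex[o][keep]
  }

  unassigned <- if (ns > 0L) sum(is.na(assignment)) else 0L
  if (unassigned > 0L) {
    message(sprintf("assign_signals: %d signal(s) outside tolerance of every apex",
                    unassigned))
  }

  clusters <- vector("list", nrow(apexes))
  for (a in seq_len(nrow(apexes))) {
    members <- sig[which(assignment == a), c("mz", "rt", "intensity"),
                   drop = FALSE]
    rownames(members) <- NULL
    clusters[[a]] <- structure(
      list(feature_id = apexes$feature_id[a], mz = apexes$mz[a],
           rt = apexes$rt[a], intensity_sample = apexes$intensity_sample[a],
           charge = apexes$charge[a] %||% 0L, members = members),
      class = "ms2_cluster")
  }
  structure(clusters, class = c("ms2_clusters", "list"),
            unassigned = unassigned, n_signals = ns)
}

#' @export
print.ms2_clusters <- function(x, ...) {
  nm <- vapply(x, function(cl) nrow(cl$members), integer(1))
  cat(sprintf("<ms2_clusters> %d cluster(s), %d assigned signal(s), %d unassigned\n",
              length(x), sum(nm), attr(x, "unassigned") %||% 0L))
  invisible(x)
}
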