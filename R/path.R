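## The acquisition-path container: an ordered set of non-overlapping
## m/z-RT windows, one per distinct feature, for a single targeted run.

.empty_windows <- function() {
  data.frame(feature_id = character(0), iso_mz = numeric(0),
             rt_start = numeric(0), rt_end = numeric(0),
             accumulated_intensity = numeric(0), predicted_tic = numeric(0),
             charge = integer(0), stringsAsFactors = FALSE)
}

#' Construct an acquisition path
#'
#' A path is the schedule for one targeted MS2 injection: acquisition
#' windows strictly ordered in retention time, pairwise non-overlapping,
#' with pairwise-distinct feature identifiers. Its score is the number of
#' windows, i.e. the number of distinct features fragmented.
#'
#' @param index Non-negative integer; 0 is the first planned injection.
#' @param windows Data frame with columns `feature_id`, `iso_mz`,
#'   `rt_start`, `rt_end`, `accumulated_intensity`, `predicted_tic`,
#'   `charge` (RT in seconds). May have zero rows.
#' @return An object of class `ms2_path` with fields `index`, `windows`
#'   and `score`.
#' @export
new_path <- function(index, windows = .empty_windows()) {
  windows <- as.data.frame(windows, stringsAsFactors = FALSE)
  p <- structure(list(index = as.integer(index), windows = windows,
                      score = nrow(windows)),
                 class = "ms2_path")
  validate_path(p)
  p
}

#' Validate path invariants
#'
#' Checks that windows are ordered and non-overlapping in RT (touching
#' boundaries are allowed), each window has `rt_start < rt_end` and
#' non-negative accumulated intensity, and feature identifiers are
#' distinct. Raises a validation error otherwise.
#'
#' @param p An `ms2_path`.
#' @return Invisibly, `p`.
#' @export
validate_path <- function(p) {
  stopifnot(inherits(p, "ms2_path"))
  w <- p$windows
  if (p$index < 0L) stop_validation("path index must be >= 0")
  if (p$score != nrow(w)) stop_validation("path score must equal window count")
  if (nrow(w) == 0L) return(invisible(p))
  if (any(w$rt_start >= w$rt_end)) {
    stop_validation("path ", p$index, ": window with rt_start >= rt_end")
  }
  if (any(w$accumulated_intensity < 0)) {
    stop_validation("path ", p$index, ": negative accumulated_intensity")
  }
  if (is.unsorted(w$rt_start)) {
    stop_validation("path ", p$index, ": windows not ordered by rt_start")
  }
  if (nrow(w) > 1L && any(w$rt_start[-1L] < w$rt_end[-nrow(w)])) {
    stop_validation("path ", p$index, ": overlapping windows")
  }
  if (anyDuplicated(w$feature_id)) {
    stop_validation("path ", p$index, ": duplicate feature_id ",
                    w$feature_id[duplicated(w$feature_id)][1L])
  }
  invisible(p)
}

as_path_list <- function(paths) {
  if (inherits(paths, "ms2_path")) return(list(paths))
  if (!is.list(paths) || !all(vapply(paths, inherits, logical(1), "ms2_path")))
    stop_input("expected an ms2_path or a list of ms2_path objects")
  paths
}

#' @export
print.ms2_path <- function(x, ...) {
  cat(sprintf("<ms2_path> index %d, score %d (windows: %d)\n",
              x$index, x$score, nrow(x$windows)))
  if (nrow(x$windows) > 0L) {
    rng <- range(x$windows$rt_start, x$windows$rt_end)
    cat(sprintf("  RT span %.1f-%.1f s\n", rng[1L], rng[2L]))
  }
  invisible(x)
}
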