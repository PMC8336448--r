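## The TIC model: a linear map from the integrated MS1 intensity of an
## m/z-RT window to the expected MS2 total ion current. The planner only
## admits acquisition windows whose predicted TIC clears a user threshold,
## its proxy for fragmentation-spectrum quality.

#' Linear MS2-TIC prediction model
#'
#' `predicted_tic = max(0, slope * integral + intercept)`, where the
#' integral is the trapezoidal integral of raw MS1 intensity over the
#' acquisition window padded by `delta` seconds on each side (the padding
#' absorbs small run-to-run retention-time shifts).
#'
#' The default is the identity model (slope 1, intercept 0): thresholding
#' the predicted TIC is then the same as thresholding the integrated MS1
#' signal directly, which needs no platform-specific training data. A
#' platform-specific model is obtained with [fit_tic_model()] from pairs
#' measured in a standard DDA run.
#'
#' @param slope TIC units per (intensity * second).
#' @param intercept TIC units.
#' @param delta RT padding in seconds (>= 0). Default 0.2 s.
#' @return An object of class `tic_model`.
#' @export
tic_model <- function(slope = 1, intercept = 0, delta = 0.2) {
  if (!is_number(slope) || !is_number(intercept))
    stop_input("slope and intercept must be finite numbers")
  if (!is_number(delta) || delta < 0) stop_input("delta must be >= 0")
  structure(list(slope = slope, intercept = intercept, delta = delta,
                 r_squared = NA_real_, se_slope = NA_real_,
                 se_intercept = NA_real_),
            class = "tic_model")
}

#' Integrate MS1 intensity over a padded RT window
#'
#' Trapezoidal integral of a cluster's raw-signal intensities over the scan
#' points whose RT falls in `[rt_start - delta, rt_end + delta]`. Scan
#' points outside the padded window are excluded entirely (no edge
#' interpolation). With fewer than two points inside the window the
#' integral is 0.
#'
#' @param cluster An `ms2_cluster` (or a data frame of members with
#'   columns `rt`, `intensity`, sorted or not).
#' @param rt_start,rt_end Window bounds in seconds, `rt_start < rt_end`.
#' @param delta Padding in seconds (>= 0).
#' @return The accumulated intensity in intensity-seconds (scalar >= 0).
#' @export
integrate_intensity <- function(cluster, rt_start, rt_end, delta = 0) {
  if (rt_start >= rt_end) stop_input("rt_start must be < rt_end")
  if (delta < 0) stop_input("delta must be >= 0")
  members <- if (inherits(cluster, "ms2_cluster")) cluster$members else cluster
  if (is.null(members) || nrow(members) < 2L) return(0)
  rt <- members$rt
  if (is.unsorted(rt)) {
    o <- order(rt)
    rt <- rt[o]
    members <- members[o, , drop = FALSE]
  }
  inside <- rt >= rt_start - delta & rt <= rt_end + delta
  if (sum(inside) < 2L) return(0)
  t <- rt[inside]
  y <- members$intensity[inside]
  sum(diff(t) * (y[-length(y)] + y[-1L]) / 2)
}

#' Fit the TIC model by ordinary least squares
#'
#' Regresses observed MS2 TIC on integrated MS1 intensity over training
#' pairs collected in a conventional DDA run on the same platform. The fit
#' includes an intercept; R-squared and coefficient standard errors are
#' kept on the returned object as diagnostics.
#'
#' @param pairs Data frame with numeric columns `integral` and
#'   `observed_tic`; at least two rows with at least two distinct integral
#'   values.
#' @param delta RT padding (seconds) to store on the fitted model.
#' @return A [tic_model()] with fitted `slope` and `intercept` and fields
#'   `r_squared`, `se_slope`, `se_intercept`.
#' @export
fit_tic_model <- function(pairs, delta = 0.2) {
  .require_columns(pairs, c("integral", "observed_tic"), "training pairs")
  if (nrow(pairs) < 2L || length(unique(pairs$integral)) < 2L) {
    stop_input("fit_tic_model: need >= 2 pairs with >= 2 distinct integrals")
  }
  fit <- stats::lm(observed_tic ~ integral, data = pairs)
  s <- summary(fit)
  m <- tic_model(slope = unname(stats::coef(fit)[["integral"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 delta = delta)
  m$r_squared <- s$r.squared
  m$se_intercept <- s$coefficients["(Intercept)", "Std. Error"]
  m$se_slope <- s$coefficients["integral", "Std. Error"]
  m
}

#' Predict MS2 TIC from an integrated MS1 intensity
#'
#' @param model A [tic_model()].
#' @param integral Accumulated intensity (intensity-seconds, >= 0);
#'   vectorized.
#' @return Predicted TIC, floored at 0 (a negative ion current is not
#'   physical).
#' @export
predict_tic <- function(model, integral) {
  stopifnot(inherits(model, "tic_model"))
  if (any(integral < 0)) stop_input("integral must be >= 0")
  pmax(0, model$slope * integral + model$intercept)
}

#' Persist / load a TIC model
#'
#' Three-line key-value text file holding slope, intercept and delta.
#'
#' @param model A [tic_model()].
#' @param path File path.
#' @return `write_tic_model`: invisibly, the path. `read_tic_model`: a
#'   [tic_model()].
#' @export
write_tic_model <- function(model, path) {
  stopifnot(inherits(model, "tic_model"))
  writeLines(c(paste0("slope\t", .fmt_num(model$slope)),
               paste0("intercept\t", .fmt_num(model$intercept)),
               paste0("delta\t", .fmt_num(model$delta))), path)
  invisible(path)
}

#' @rdname write_tic_model
#' @export
read_tic_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2L]), numeric(1)),
                          vapply(kv, `[[`, character(1), 1L))
  for (k in c("slope", "intercept", "delta")) {
    if (!k %in% names(vals) || is.na(vals[[k]]))
      stop_input("TIC model file: missing or invalid field '", k, "'")
  }
  tic_model(vals[["slope"]], vals[["intercept"]], vals[["delta"]])
}

#' @export
print.tic_model <- function(x, ...) {
  cat(sprintf("<tic_model> TIC = max(0, %.6g * integral + %.6g), delta = %g s\n",
              x$slope, x$intercept, x$delta))
  if (!is.na(x$r_squared)) cat(sprintf("  fit R^2 = %.4f\n", x$r_squared))
  invisible(x)
}
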