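## Synthetic LC-MS runs: Gaussian elution profiles on a regular MS1 scan
## grid, optional background-only features, multiplicative log-normal
## intensity noise. Plus a deliberately minimal top-N DDA simulator used
## to contrast planner redundancy with conventional data-dependent
## acquisition.

#' Specification of a synthetic MS1 run
#'
#' Each feature elutes as a Gaussian `I(t) = h * exp(-(t - rt0)^2 /
#' (2 sigma^2))` sampled on the regular scan grid and truncated at three
#' sigma; intensities receive multiplicative log-normal noise. Background
#' features (solvent/contaminant analogues) are generated identically but
#' carry `intensity_blank = intensity_sample` in the truth table, so they
#' are removed by [filter_background()].
#'
#' @param n_features Number of sample features (>= 0).
#' @param rt_range Run length in seconds (> 0).
#' @param scan_interval MS1 scan spacing in seconds (> 0).
#' @param peak_width_sigma Gaussian elution sigma in seconds (> 0).
#' @param height_range Length-2 range of apex intensities; heights are
#'   drawn log-uniformly.
#' @param mz_range Length-2 m/z range (Th).
#' @param n_background Number of background-only features (>= 0).
#' @param noise_sigma Standard deviation of the log-normal noise on the
#'   log scale (0 = noiseless).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(n_features = 50L, rt_range = 600,
                               scan_interval = 0.5, peak_width_sigma = 3,
                               height_range = c(1e4, 1e7),
                               mz_range = c(100, 1000), n_background = 0L,
                               noise_sigma = 0.05, seed = 1L) {
  if (n_features < 0L || n_background < 0L)
    stop_input("feature counts must be >= 0")
  if (!is_number(rt_range) || rt_range <= 0) stop_input("rt_range must be > 0")
  if (!is_number(scan_interval) || scan_interval <= 0)
    stop_input("scan_interval must be > 0")
  if (!is_number(peak_width_sigma) || peak_width_sigma <= 0)
    stop_input("peak_width_sigma must be > 0")
  if (noise_sigma < 0) stop_input("noise_sigma must be >= 0")
  structure(list(n_features = as.integer(n_features), rt_range = rt_range,
                 scan_interval = scan_interval,
                 peak_width_sigma = peak_width_sigma,
                 height_range = height_range, mz_range = mz_range,
                 n_background = as.integer(n_background),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synthetic_run_spec")
}

#' Generate a synthetic MS1 run with ground truth
#'
#' @param spec A [synthetic_run_spec()].
#' @return A list of class `synthetic_run` with elements `signals` (raw
#'   signal data frame: `mz`, `rt`, `intensity`, sorted by `(rt, mz)`),
#'   `truth` (apex table: `feature_id`, `mz`, `rt`, `intensity_sample`,
#'   `intensity_blank`, `charge`) and `spec`.
#' @export
generate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  n_total <- spec$n_features + spec$n_background
  empty_sig <- data.frame(mz = numeric(0), rt = numeric(0),
                          intensity = numeric(0))
  empty_truth <- data.frame(feature_id = character(0), mz = numeric(0),
                            rt = numeric(0), intensity_sample = numeric(0),
                            intensity_blank = numeric(0), charge = integer(0),
                            stringsAsFactors = FALSE)
  if (n_total == 0L) {
    return(structure(list(signals = empty_sig, truth = empty_truth,
                          spec = spec), class = "synthetic_run"))
  }
  run <- with_seed(spec$seed, {
    sigma <- spec$peak_width_sigma
    margin <- min(3 * sigma, spec$rt_range / 2)
    mz <- sort(stats::runif(n_total, spec$mz_range[1L], spec$mz_range[2L]))
    rt0 <- stats::runif(n_total, margin, spec$rt_range - margin)
    h <- 10 ^ stats::runif(n_total, log10(spec$height_range[1L]),
                           log10(spec$height_range[2L]))
    is_bg <- rep(c(FALSE, TRUE), c(spec$n_features, spec$n_background))
    is_bg <- sample(is_bg)
    grid <- seq(0, spec$rt_range, by = spec$scan_interval)
    parts <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      t <- grid[abs(grid - rt0[i]) <= 3 * sigma]
      if (length(t) == 0L) next
      intensity <- h[i] * exp(-(t - rt0[i])^2 / (2 * sigma^2))
      if (spec$noise_sigma > 0) {
        intensity <- intensity * exp(stats::rnorm(length(t), 0,
                                                  spec$noise_sigma))
      }
      parts[[i]] <- data.frame(mz = mz[i], rt = t, intensity = intensity)
    }
    signals <- rbind_rows(parts)
    if (is.null(signals)) signals <- empty_sig
    signals <- signals[order(signals$rt, signals$mz), , drop = FALSE]
    rownames(signals) <- NULL
    truth <- data.frame(
      feature_id = sprintf("F%04d", seq_len(n_total)),
      mz = mz, rt = rt0, intensity_sample = h,
      intensity_blank = ifelse(is_bg, h, 0),
      charge = 1L, stringsAsFactors = FALSE)
    list(signals = signals, truth = truth)
  })
  structure(c(run, list(spec = spec)), class = "synthetic_run")
}

#' Top-N DDA configuration
#'
#' @param top_n Precursors fragmented per MS1 scan (>= 1); conventional
#'   instruments commonly run top-5.
#' @param exclusion_window Dynamic-exclusion duration in seconds: once
#'   fragmented, a feature is not reselected until this much time has
#'   passed.
#' @param n_replicates Number of identical injections to simulate.
#' @return An object of class `dda_config`.
#' @export
dda_config <- function(top_n = 5L, exclusion_window = 10,
                       n_replicates = 1L) {
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) stop_input("top_n must be >= 1")
  if (exclusion_window < 0) stop_input("exclusion_window must be >= 0")
  structure(list(top_n = top_n, exclusion_window = exclusion_window,
                 n_replicates = as.integer(n_replicates)),
            class = "dda_config")
}

#' Simulate top-N data-dependent acquisition
#'
#' Scan-by-scan replay of a conventional DDA method on the synthetic run:
#' at each MS1 scan the `top_n` most intense non-excluded features with
#' signal in that scan are fragmented, and each selection goes on dynamic
#' exclusion for `exclusion_window` seconds. The simulator is minimal by
#' design (no injection-time or charge-state modeling): it exists to
#' measure relative redundancy and coverage, not to emulate a specific
#' instrument. Replicate injections replay the same signals, so dynamics
#' are deterministic; `seed` only randomizes the order of exact intensity
#' ties.
#'
#' @param signals Raw-signal data frame from [generate_run()] (feature
#'   identity is recovered by exact m/z match against `truth`).
#' @param truth Apex/truth table from [generate_run()].
#' @param dda A [dda_config()].
#' @param seed Integer seed for tie ordering.
#' @return Data frame `feature_id`, `n_acquisitions` (summed over
#'   replicates; zero rows are kept).
#' @export
simulate_dda <- function(signals, truth, dda = dda_config(), seed = 1L) {
  stopifnot(inherits(dda, "dda_config"))
  nf <- nrow(truth)
  counts <- integer(nf)
  if (nf > 0L && nrow(signals) > 0L) {
    feat <- match(signals$mz, truth$mz)
    ok <- !is.na(feat)
    sig_feat <- feat[ok]
    sig_rt <- signals$rt[ok]
    sig_int <- signals$intensity[ok]
    tie_jitter <- with_seed(seed, stats::runif(nf))
    scan_of <- match(sig_rt, sort(unique(sig_rt)))
    scans <- sort(unique(sig_rt))
    by_scan_feat <- split(sig_feat, scan_of)
    by_scan_int <- split(sig_int, scan_of)
    single <- integer(nf)
    excl_until <- rep(-Inf, nf)
    for (s in seq_along(scans)) {
      t <- scans[s]
      f <- by_scan_feat[[s]]
      it <- by_scan_int[[s]]
      open <- excl_until[f] <= t
      if (!any(open)) next
      f <- f[open]; it <- it[open]
      o <- order(-it, tie_jitter[f])
      pick <- f[o][seq_len(min(dda$top_n, length(f)))]
      single[pick] <- single[pick] + 1L
      excl_until[pick] <- t + dda$exclusion_window
    }
    counts <- single * dda$n_replicates
  }
  data.frame(feature_id = truth$feature_id, n_acquisitions = counts,
             stringsAsFactors = FALSE)
}
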