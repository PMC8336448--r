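## Tabular readers/writers for the three dialect tables the planner consumes
## and emits: raw MS1 signals, feature apexes, and acquisition-path tables.
## Parsing is column-name based (extra columns pass through harmlessly) and
## locale-independent (decimal point, scientific notation accepted).

.sep_for <- function(dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") "\t" else ","
}

.read_table <- function(source, dialect) {
  utils::read.table(source, header = TRUE, sep = .sep_for(dialect),
                    colClasses = "character", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"",
                    blank.lines.skip = TRUE)
}

.require_columns <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop_input(sprintf("%s: missing required column%s: %s", what,
                       if (length(missing) > 1L) "s" else "",
                       paste(missing, collapse = ", ")))
  }
}

.as_numeric_col <- function(x, col, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0L) {
    stop_input(sprintf("%s: non-numeric value '%s' in column '%s' at row %d",
                       what, x[bad[1L]], col, bad[1L]))
  }
  out
}

#' Read a raw MS1 signal table
#'
#' Reads scan points of a preliminary MS1 full-scan run: one row per
#' (m/z, retention time, intensity) triplet. Rows with non-positive
#' intensity carry no usable signal and are dropped (a message reports how
#' many); the result is sorted by retention time, then m/z.
#'
#' @param source Path or connection to a delimited text file with a header
#'   row naming at least the columns `mz`, `rt_sec` and `intensity`
#'   (any order; extra columns are ignored).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A data frame with columns `mz` (Th), `rt` (seconds) and
#'   `intensity`, sorted by `(rt, mz)`.
#' @seealso [read_apexes()], [generate_run()]
#' @export
read_raw_signals <- function(source, dialect = c("tsv", "csv")) {
  tab <- .read_table(source, dialect)
  .require_columns(tab, c("mz", "rt_sec", "intensity"), "raw signal table")
  out <- data.frame(
    mz = .as_numeric_col(tab$mz, "mz", "raw signal table"),
    rt = .as_numeric_col(tab$rt_sec, "rt_sec", "raw signal table"),
    intensity = .as_numeric_col(tab$intensity, "intensity",
                                "raw signal table")
  )
  if (nrow(out) > 0L) {
    if (any(out$mz <= 0)) stop_input("raw signal table: mz must be > 0")
    if (any(out$rt < 0)) stop_input("raw signal table: rt_sec must be >= 0")
    drop <- out$intensity <= 0
    if (any(drop)) {
      message(sprintf("read_raw_signals: dropped %d row(s) with intensity <= 0",
                      sum(drop)))
      out <- out[!drop, , drop = FALSE]
    }
    out <- out[order(out$rt, out$mz), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a feature-apex table
#'
#' Reads the tabular output of an upstream MS1 feature finder: one row per
#' detected feature apex, with its intensity in the biological sample and
#' (optionally) in the background/control sample. Missing optional columns
#' default to `intensity_blank = 0` (no background signal) and `charge = 0`
#' (unknown).
#'
#' @inheritParams read_raw_signals
#' @param source Delimited text file with header columns `feature_id`,
#'   `mz`, `rt_sec`, `intensity_sample` and optionally `intensity_blank`,
#'   `charge`.
#' @return A data frame with columns `feature_id` (character), `mz`, `rt`
#'   (seconds), `intensity_sample`, `intensity_blank`, `charge`.
#' @export
read_apexes <- function(source, dialect = c("tsv", "csv")) {
  tab <- .read_table(source, dialect)
  .require_columns(tab, c("feature_id", "mz", "rt_sec", "intensity_sample"),
                   "apex table")
  n <- nrow(tab)
  out <- data.frame(
    feature_id = as.character(tab$feature_id),
    mz = .as_numeric_col(tab$mz, "mz", "apex table"),
    rt = .as_numeric_col(tab$rt_sec, "rt_sec", "apex table"),
    intensity_sample = .as_numeric_col(tab$intensity_sample,
                                       "intensity_sample", "apex table"),
    intensity_blank = if ("intensity_blank" %in% names(tab)) {
      .as_numeric_col(tab$intensity_blank, "intensity_blank", "apex table")
    } else rep(0, n),
    charge = if ("charge" %in% names(tab)) {
      as.integer(.as_numeric_col(tab$charge, "charge", "apex table"))
    } else rep(0L, n),
    stringsAsFactors = FALSE
  )
  dup <- unique(out$feature_id[duplicated(out$feature_id)])
  if (length(dup) > 0L) {
    stop_validation("apex table: duplicate feature_id: ",
                    paste(dup, collapse = ", "))
  }
  if (n > 0L && any(out$intensity_sample <= 0)) {
    stop_validation("apex table: intensity_sample must be > 0")
  }
  out
}

## Full-precision numeric formatting so that write-then-read round-trips are
## exact for doubles.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1L))
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

.write_table <- function(df, sink, dialect = "tsv") {
  chr <- df
  for (j in seq_along(chr)) {
    if (is.double(chr[[j]])) chr[[j]] <- .fmt_num(chr[[j]])
  }
  utils::write.table(chr, sink, sep = .sep_for(dialect), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Write raw signals / apex tables
#'
#' Serialize the in-memory representations back to the tabular dialects read
#' by [read_raw_signals()] and [read_apexes()]. Numeric columns are written
#' at full double precision so round-trips are exact.
#'
#' @param signals,apexes Data frames as returned by the corresponding
#'   readers (or [generate_run()]).
#' @param sink Path or connection to write to.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return Invisibly, the sink.
#' @export
write_raw_signals <- function(signals, sink, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- data.frame(mz = signals$mz, rt_sec = signals$rt,
                   intensity = signals$intensity)
  .write_table(df, sink, dialect)
  invisible(sink)
}

#' @rdname write_raw_signals
#' @export
write_apexes <- function(apexes, sink, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  df <- data.frame(feature_id = apexes$feature_id, mz = apexes$mz,
                   rt_sec = apexes$rt,
                   intensity_sample = apexes$intensity_sample,
                   intensity_blank = apexes$intensity_blank,
                   charge = apexes$charge)
  .write_table(df, sink, dialect)
  invisible(sink)
}

.path_cols <- c("path_index", "feature_id", "iso_mz", "rt_start_sec",
                "rt_end_sec", "accumulated_intensity", "predicted_tic",
                "charge")

#' Write acquisition paths to a path table
#'
#' One row per acquisition window, ordered by `(path_index, rt_start)`.
#' Each path is validated before writing; a schedule with overlapping
#' windows inside one path is refused.
#'
#' @param paths A single path or a list of paths as returned by
#'   [plan_paths()] / [longest_path()].
#' @param sink Path or connection.
#' @return Invisibly, the sink.
#' @seealso [read_paths()] for the inverse operation.
#' @export
write_paths <- function(paths, sink) {
  paths <- as_path_list(paths)
  for (p in paths) validate_path(p)
  rows <- lapply(paths, function(p) {
    w <- p$windows
    if (nrow(w) == 0L) return(NULL)
    data.frame(path_index = p$index, feature_id = w$feature_id,
               iso_mz = w$iso_mz, rt_start_sec = w$rt_start,
               rt_end_sec = w$rt_end,
               accumulated_intensity = w$accumulated_intensity,
               predicted_tic = w$predicted_tic, charge = w$charge,
               stringsAsFactors = FALSE)
  })
  tab <- rbind_rows(rows)
  if (is.null(tab)) {
    tab <- as.data.frame(stats::setNames(
      replicate(length(.path_cols), numeric(0), simplify = FALSE),
      .path_cols))
    tab$feature_id <- character(0)
  }
  tab <- tab[order(tab$path_index, tab$rt_start_sec), , drop = FALSE]
  .write_table(tab, sink, "tsv")
  invisible(sink)
}

#' Read an acquisition-path table
#'
#' @param source Path or connection to a TSV written by [write_paths()].
#' @return A list of path objects (see [new_path()]), one per distinct
#'   `path_index`, ordered by index.
#' @export
read_paths <- function(source) {
  tab <- .read_table(source, "tsv")
  .require_columns(tab, .path_cols, "path table")
  if (nrow(tab) == 0L) return(list())
  num <- function(col) .as_numeric_col(tab[[col]], col, "path table")
  df <- data.frame(
    path_index = as.integer(num("path_index")),
    feature_id = as.character(tab$feature_id),
    iso_mz = num("iso_mz"), rt_start = num("rt_start_sec"),
    rt_end = num("rt_end_sec"),
    accumulated_intensity = num("accumulated_intensity"),
    predicted_tic = num("predicted_tic"),
    charge = as.integer(num("charge")),
    stringsAsFactors = FALSE
  )
  lapply(sort(unique(df$path_index)), function(k) {
    w <- df[df$path_index == k, setdiff(names(df), "path_index"),
            drop = FALSE]
    w <- w[order(w$rt_start), , drop = FALSE]
    rownames(w) <- NULL
    new_path(k, w)
  })
}

#' Format paths as a vendor inclusion list
#'
#' Thin formatter from the internal path representation to the CSV column
#' layout used by Q Exactive / Exploris style inclusion lists (retention
#' times in minutes). The mapping is fixed; no vendor round-trip is
#' attempted.
#'
#' @param paths Path or list of paths.
#' @param polarity `"Positive"` or `"Negative"`.
#' @param nce Normalized collision energy to stamp on every row.
#' @return A data frame with vendor-style column names; one row per window.
#' @export
format_inclusion_list <- function(paths, polarity = c("Positive", "Negative"),
                                  nce = 30) {
  polarity <- match.arg(polarity)
  paths <- as_path_list(paths)
  rows <- lapply(paths, function(p) {
    w <- p$windows
    if (nrow(w) == 0L) return(NULL)
    data.frame(
      `Mass [m/z]` = w$iso_mz,
      `Formula [M]` = "",
      Species = "",
      `CS [z]` = ifelse(w$charge > 0L, w$charge, NA_integer_),
      Polarity = polarity,
      `Start [min]` = w$rt_start / 60,
      `End [min]` = w$rt_end / 60,
      `NCE` = nce,
      Comment = paste0("path", p$index, ":", w$feature_id),
      check.names = FALSE, stringsAsFactors = FALSE
    )
  })
  out <- rbind_rows(rows)
  if (is.null(out)) out <- data.frame()
  out
}
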