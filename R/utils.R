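#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## random-number stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_input <- function(...) {
  stop(structure(class = c("ms2plan_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("ms2plan_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## rbind a list of data frames, ignoring NULL entries; NULL when empty
rbind_rows <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
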