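#' Read and write spike tables
#'
#' Spike tables are plain CSV with columns `cell_id`, `frequency_hz`,
#' `sweep`, `time_s`, `evoked`, `cd_on`, `interval_index`. Times are
#' written with 17 significant digits so a write-then-read round trip
#' reproduces the table exactly.
#'
#' @param table A labeled spike table.
#' @param path File path.
#' @return `read_spike_table()` returns a tibble; `write_spike_table()`
#'   returns `path` invisibly.
#' @export
write_spike_table <- function(table, path) {
  table <- as_tibble(table)
  .check_columns(table, .spike_cols, "spike table")
  out <- table[, .spike_cols]
  out$time_s <- sprintf("%.17g", out$time_s)
  readr::write_csv(out, path)
  invisible(path)
}

.spike_cols <- c(
  "cell_id", "frequency_hz", "sweep", "time_s", "evoked", "cd_on",
  "interval_index"
)

.epoch_cols <- c("cell_id", "kind", "start_s", "end_s")

.check_columns <- function(table, cols, what) {
  missing <- setdiff(cols, names(table))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s", what,
      paste(missing, collapse = ", ")
    ))
  }
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = readr::col_character(),
      frequency_hz = readr::col_double(),
      sweep = readr::col_integer(),
      time_s = readr::col_character(),
      evoked = readr::col_logical(),
      cd_on = readr::col_logical(),
      interval_index = readr::col_integer()
    ),
    progress = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "malformed spike table: first problem at line %d (%s)",
      probs$row[1], probs$expected[1]
    ))
  }
  .check_columns(tbl, .spike_cols, "spike table")
  tbl$time_s <- as.numeric(tbl$time_s) # base strtod: correctly rounded
  tbl
}

#' Read and write epoch tables
#'
#' Epoch tables are CSV with columns `cell_id`, `kind`
#' (`"stimulus"`/`"swim"`), `start_s`, `end_s`.
#'
#' @param table An epoch table.
#' @param path File path.
#' @return `read_epoch_table()` returns a tibble; `write_epoch_table()`
#'   returns `path` invisibly.
#' @export
write_epoch_table <- function(table, path) {
  table <- as_tibble(table)
  .check_columns(table, .epoch_cols, "epoch table")
  out <- table[, .epoch_cols]
  out$start_s <- sprintf("%.17g", out$start_s)
  out$end_s <- sprintf("%.17g", out$end_s)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_epoch_table
#' @export
read_epoch_table <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      cell_id = readr::col_character(),
      kind = readr::col_character(),
      start_s = readr::col_character(),
      end_s = readr::col_character()
    ),
    progress = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed epoch table: first problem at line %d", probs$row[1]))
  }
  .check_columns(tbl, .epoch_cols, "epoch table")
  tbl$start_s <- as.numeric(tbl$start_s)
  tbl$end_s <- as.numeric(tbl$end_s)
  tbl
}
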