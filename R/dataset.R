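#' Validate (and normalise the shape of) a time-course dataset
#'
#' A dataset is a plain data frame with one row per measured point:
#' columns `time` (seconds), `readout` (label), `mean` (replicate mean),
#' `sd` (per-point noise standard deviation, > 0), `n_rep` (replicate count,
#' >= 1) and optionally `condition` (experimental condition id, defaults to
#' `"base"`; datasets that merge measurements taken under different designs —
#' e.g. with and without an inhibitor — distinguish them by this column).
#'
#' @param data A data frame.
#' @param check_order Require strictly increasing times per
#'   (condition, readout). Order-insensitive consumers (e.g. the residual
#'   objective, which is a plain sum over records) relax this.
#' @return A validated tibble with the `condition` column materialised.
#' @export
as_pls_dataset <- function(data, check_order = TRUE) {
  required <- c("time", "readout", "mean", "sd", "n_rep")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")),
          class = "plsens_parse_error")
  }
  data <- as_tibble(data)
  if (!("condition" %in% names(data))) data$condition <- "base"
  if (!nrow(data)) abort("dataset is empty", class = "plsens_validation_error")
  if (any(!is.finite(data$sd)) || any(data$sd <= 0)) {
    abort("dataset sd must be finite and > 0 everywhere",
          class = "plsens_validation_error")
  }
  if (any(data$n_rep < 1)) {
    abort("dataset n_rep must be >= 1", class = "plsens_validation_error")
  }
  if (isTRUE(check_order)) {
    bad <- data |>
      dplyr::group_by(.data$condition, .data$readout) |>
      dplyr::summarise(ok = !is.unsorted(.data$time, strictly = TRUE),
                       .groups = "drop")
    if (any(!bad$ok)) {
      abort("times must be strictly increasing within each (condition, readout)",
            class = "plsens_validation_error")
    }
  }
  data
}

#' Read / write a dataset CSV
#'
#' Schema: `time,readout,mean,sd,n_rep` with an optional `condition` column;
#' header required, `.` decimal, UTF-8. A `provenance` attribute
#' (`"measured"` or `"synthetic:<seed>"`) survives a round trip through a
#' sidecar comment line.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a validated tibble; `write_dataset()`
#'   returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: ", path), class = "plsens_parse_error")
  }
  first <- readLines(path, n = 1)
  provenance <- NULL
  if (startsWith(first, "# provenance:")) {
    provenance <- trimws(sub("# provenance:", "", first, fixed = TRUE))
  }
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  data <- as_pls_dataset(data)
  attr(data, "provenance") <- provenance %||% "measured"
  data
}

#' @param data A dataset (see [as_pls_dataset()]).
#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  data <- as_pls_dataset(data)
  provenance <- attr(data, "provenance") %||% "measured"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", provenance), con)
  cols <- intersect(c("time", "readout", "mean", "sd", "n_rep", "condition"),
                    names(data))
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(data[cols], function(x)
    if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
    else as.character(x)), sep = ","))
  writeLines(body, con)
  invisible(path)
}

# sigma floor: coincident replicates would otherwise give infinite weights
floor_sigma <- function(sd, y, rel = 1e-3, abs_floor = 1e-12) {
  floor_val <- max(rel * max(abs(y)), abs_floor)
  n_floored <- sum(sd < floor_val)
  if (n_floored > 0) {
    inform(paste0("sigma floor (", format(floor_val), ") applied to ",
                  n_floored, " point(s)"))
  }
  pmax(sd, floor_val)
}

#' Normalise raw replicate fluorescence traces
#'
#' Each replicate trace is normalised by its own ground value F0 (the value
#' at t = 0) and its own maximum Fm: Fn = (F - F0) / (Fm - F0). The dataset
#' mean and sd are then the pointwise sample mean and standard deviation
#' across the normalised replicates. Standard deviations are floored at
#' `max(1e-3 * max|mean|, 1e-12)` so coincident replicates never produce
#' zero-sd (infinite-weight) records.
#'
#' @param raw Data frame with a `time` column (first value must be t = 0)
#'   and one column per replicate, all on a common time grid.
#' @param readout Readout label to attach (default `"F"`).
#' @return A validated dataset tibble (see [as_pls_dataset()]).
#' @export
normalize_replicates <- function(raw, readout = "F") {
  if (!("time" %in% names(raw))) {
    abort("replicate table must have a time column", class = "plsens_parse_error")
  }
  reps <- setdiff(names(raw), "time")
  if (length(reps) < 2) {
    abort("need at least 2 replicate columns", class = "plsens_validation_error")
  }
  t <- raw$time
  if (is.unsorted(t, strictly = TRUE)) {
    abort("replicate time grid must be strictly increasing",
          class = "plsens_alignment_error")
  }
  if (t[1] != 0) {
    abort("replicate traces must start at t = 0 (ground fluorescence F0)",
          class = "plsens_alignment_error")
  }
  norm <- vapply(reps, function(r) {
    f <- raw[[r]]
    if (anyNA(f)) abort("replicate traces must share a common grid (no NA)",
                        class = "plsens_alignment_error")
    f0 <- f[1]
    fm <- max(f)
    if (fm == f0) {
      abort(paste0("degenerate trace in replicate ", r, ": Fm equals F0"),
            class = "plsens_degenerate_trace_error")
    }
    (f - f0) / (fm - f0)
  }, numeric(length(t)))
  m <- rowMeans(norm)
  s <- apply(norm, 1, sd)
  s <- floor_sigma(s, m)
  as_pls_dataset(tibble(time = t, readout = readout, mean = m, sd = s,
                        n_rep = length(reps)))
}
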