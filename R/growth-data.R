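#' Growth dataset container
#'
#' A `growth_dataset` is a tibble of long-format optical-density observations
#' with one row per well reading. Required columns are `strain`, `condition`,
#' `batch`, `bio_rep`, `tech_rep`, `time` (hours) and `value` (OD600 on the
#' raw scale, or log2 OD after [normalize_growth()]). The shared time grid,
#' the normalization state, and the per-condition zeroing offsets are carried
#' as attributes so the fitting functions can rely on them.
#'
#' @param x A data frame with the required columns (extra columns are kept).
#' @param normalized Logical; `TRUE` when `value` is already on the model
#'   (log2, trimmed, zeroed) scale — used by the simulator, which generates
#'   directly on that scale.
#' @param interval Sampling interval in hours used to snap times onto a
#'   common grid (default 0.5 h, i.e. a reading every 30 minutes). A time
#'   farther than 25% of the interval from the nearest grid point is an
#'   error: the model assumes a shared grid, and silently interpolating
#'   would hide a plate-layout problem.
#'
#' @return A tibble with class `growth_dataset` and attributes `time_grid`,
#'   `normalized`, `offsets`, `trim_hours`.
#' @export
growth_dataset <- function(x, normalized = FALSE, interval = 0.5) {
  x <- tibble::as_tibble(x)
  required <- c("strain", "condition", "batch", "bio_rep", "tech_rep",
                "time", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("growth data is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phenogp_schema_error")
  }
  if (!is.numeric(x$time) || anyNA(x$time) || any(x$time < 0)) {
    abort("`time` must be numeric, non-missing and nonnegative",
          class = "phenogp_validation_error")
  }
  if (!is.numeric(x$value) || anyNA(x$value)) {
    abort("`value` must be numeric and non-missing",
          class = "phenogp_validation_error")
  }
  if (!normalized && any(x$value <= 0)) {
    bad <- which(x$value <= 0)
    abort(paste0("OD must be strictly positive before log transform; ",
                 "offending row(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) " ..." else ""),
          class = "phenogp_validation_error")
  }
  x$time <- snap_times(x$time, interval)
  for (col in c("strain", "condition", "batch", "bio_rep", "tech_rep")) {
    x[[col]] <- as.character(x[[col]])
  }
  # curve identity is every column except the measured value (extra factor
  # columns, e.g. plasmid presence, distinguish curves too)
  dup <- duplicated(x[, setdiff(names(x), "value")])
  if (any(dup)) {
    abort(paste0("duplicate (curve, time) rows at: ",
                 paste(head(which(dup), 10), collapse = ", ")),
          class = "phenogp_validation_error")
  }
  x <- dplyr::arrange(x, strain, condition, batch, bio_rep, tech_rep, time)
  new_growth_dataset(x,
                     time_grid = sort(unique(x$time)),
                     normalized = normalized,
                     offsets = NULL,
                     trim_hours = NULL)
}

new_growth_dataset <- function(x, time_grid, normalized, offsets, trim_hours) {
  structure(x,
            class = c("growth_dataset", class(tibble::tibble())),
            time_grid = time_grid,
            normalized = normalized,
            offsets = offsets,
            trim_hours = trim_hours)
}

snap_times <- function(time, interval) {
  origin <- min(time)
  snapped <- origin + round((time - origin) / interval) * interval
  off <- abs(time - snapped)
  if (any(off > 0.25 * interval + 1e-12)) {
    bad <- which(off > 0.25 * interval + 1e-12)
    abort(paste0("time(s) farther than 25% of the sampling interval (",
                 interval, " h) from the grid; rows: ",
                 paste(head(bad, 10), collapse = ", ")),
          class = "phenogp_validation_error")
  }
  snapped
}

#' @export
print.growth_dataset <- function(x, ...) {
  grid <- time_grid(x)
  cat(sprintf(
    "<growth_dataset> %d observations, %d strain(s) x %d condition(s), %s\n",
    nrow(x), dplyr::n_distinct(x$strain), dplyr::n_distinct(x$condition),
    if (is_normalized(x)) "normalized (log2)" else "raw OD"))
  cat(sprintf("  time grid: %g to %g h (%d points)\n",
              min(grid), max(grid), length(grid)))
  NextMethod()
}

#' @rdname growth_dataset
#' @export
time_grid <- function(x) attr(x, "time_grid")

#' @rdname growth_dataset
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' Read a long-format plate-reader growth table
#'
#' Ingests CSV/TSV/XLSX files shaped like typical plate-reader exports: one
#' row per (strain, condition, batch, replicate, time) reading. Column names
#' are configurable through `column_map`; defaults match
#' `strain, condition, batch, bio_rep, tech_rep, time_h, od600`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"xlsx"`. `"auto"` picks
#'   by file extension.
#' @param column_map Named character vector mapping internal names
#'   (`strain`, `condition`, `batch`, `bio_rep`, `tech_rep`, `time`, `value`)
#'   to the file's column names. Only overrides need to be supplied.
#' @param interval Sampling interval (h) used to snap times onto the grid.
#' @param quiet Suppress the load log message.
#'
#' @return An unnormalized [growth_dataset()].
#' @export
read_growth_table <- function(path,
                              format = c("auto", "csv", "tsv", "xlsx"),
                              column_map = NULL,
                              interval = 0.5,
                              quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "phenogp_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx", xls = "xlsx",
                     abort(paste0("cannot infer format from extension .", ext),
                           class = "phenogp_io_error"))
  }
  raw <- switch(format,
    csv  = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv  = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading xlsx requires the readxl package",
              class = "phenogp_io_error")
      }
      readxl::read_excel(path)
    })
  map <- c(strain = "strain", condition = "condition", batch = "batch",
           bio_rep = "bio_rep", tech_rep = "tech_rep",
           time = "time_h", value = "od600")
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(map))
    if (length(unknown) > 0) {
      abort(paste0("unknown column_map key(s): ",
                   paste(unknown, collapse = ", ")),
            class = "phenogp_schema_error")
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("file is missing mapped column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "phenogp_schema_error")
  }
  out <- tibble::tibble(
    strain = raw[[map[["strain"]]]],
    condition = raw[[map[["condition"]]]],
    batch = raw[[map[["batch"]]]],
    bio_rep = raw[[map[["bio_rep"]]]],
    tech_rep = raw[[map[["tech_rep"]]]],
    time = raw[[map[["time"]]]],
    value = raw[[map[["value"]]]]
  )
  ds <- growth_dataset(out, normalized = FALSE, interval = interval)
  if (!quiet) {
    message(sprintf("loaded %d observations (%d strains, %d conditions, %d grid points) from %s",
                    nrow(ds), dplyr::n_distinct(ds$strain),
                    dplyr::n_distinct(ds$condition),
                    length(time_grid(ds)), basename(path)))
  }
  ds
}

#' Normalize growth data onto the model scale
#'
#' Log2-transforms the OD values, drops the early readings where instrument
#' variability dominates (times strictly below `trim_hours`; the boundary
#' point is retained), and subtracts one scalar offset per condition so that
#' the condition's mean log2 OD at its earliest retained grid point is zero.
#' Each step mirrors how multi-strain growth cohorts are prepared before a
#' functional ANOVA fit: the log scale makes exponential growth linear, and
#' the per-condition zeroing absorbs inoculum-density differences between
#' experimental designs.
#'
#' @param ds An unnormalized [growth_dataset()].
#' @param trim_hours Readings with `time < trim_hours` are removed
#'   (default 4 h, less than one generation for a slow-growing archaeon).
#'
#' @return A normalized `growth_dataset`; the offsets applied per condition
#'   are stored in `attr(, "offsets")`.
#' @export
normalize_growth <- function(ds, trim_hours = 4.0) {
  stopifnot(inherits(ds, "growth_dataset"))
  if (is_normalized(ds)) {
    abort("dataset is already normalized; refusing to double-apply",
          class = "phenogp_validation_error")
  }
  if (trim_hours < 0) abort("trim_hours must be nonnegative")
  x <- tibble::as_tibble(ds)
  x$value <- log2(x$value)
  kept <- x$time >= trim_hours
  dropped_conditions <- setdiff(unique(x$condition), unique(x$condition[kept]))
  if (length(dropped_conditions) > 0) {
    abort(paste0("condition(s) with no observations after the ", trim_hours,
                 " h trim: ", paste(dropped_conditions, collapse = ", ")),
          class = "phenogp_validation_error")
  }
  x <- x[kept, , drop = FALSE]
  # one scalar per condition: mean at the condition's earliest retained grid
  # point becomes exactly zero
  offsets <- x |>
    dplyr::group_by(condition) |>
    dplyr::summarise(
      first_time = min(time),
      offset = mean(value[time == min(time)]),
      .groups = "drop")
  x <- x |>
    dplyr::left_join(offsets[, c("condition", "offset")], by = "condition") |>
    dplyr::mutate(value = value - .data$offset) |>
    dplyr::select(-"offset")
  new_growth_dataset(x,
                     time_grid = sort(unique(x$time)),
                     normalized = TRUE,
                     offsets = offsets,
                     trim_hours = trim_hours)
}

#' Restrict a dataset to the post-shock window
#'
#' For shock experiments (e.g. a temperature shift partway through the run)
#' the phenotype metrics are computed from the shock onset onward. This
#' returns the observations at `time >= shock_start`; the dropped pre-shock
#' portion is kept in `attr(, "pre_shock")` so baseline divergence between
#' strains before the shock can be inspected, and `attr(, "shock_start")`
#' tags the dataset for the baseline subtraction done by
#' [od_delta_heatshock()].
#'
#' @param ds A normalized [growth_dataset()].
#' @param shock_start Shock onset in hours (default 16 h).
#'
#' @return A `growth_dataset` restricted to the post-shock grid.
#' @export
heatshock_window <- function(ds, shock_start = 16.0) {
  stopifnot(inherits(ds, "growth_dataset"))
  grid <- time_grid(ds)
  if (shock_start > max(grid)) {
    abort(paste0("shock_start (", shock_start,
                 " h) is beyond the last time point (", max(grid), " h)"),
          class = "phenogp_validation_error")
  }
  x <- tibble::as_tibble(ds)
  post <- x[x$time >= shock_start, , drop = FALSE]
  pre <- x[x$time < shock_start, , drop = FALSE]
  out <- new_growth_dataset(post,
                            time_grid = grid[grid >= shock_start],
                            normalized = is_normalized(ds),
                            offsets = attr(ds, "offsets"),
                            trim_hours = attr(ds, "trim_hours"))
  attr(out, "shock_start") <- shock_start
  attr(out, "pre_shock") <- pre
  out
}

#' Write a normalized dataset as CSV plus a JSON sidecar
#'
#' The sidecar records the time grid, the per-condition zeroing offsets, the
#' trim threshold and the normalization state, so a written dataset can be
#' audited without re-deriving them.
#'
#' @param ds A [growth_dataset()].
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_growth_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "growth_dataset"))
  readr::write_csv(tibble::as_tibble(ds), path)
  sidecar <- list(
    time_grid = time_grid(ds),
    normalized = is_normalized(ds),
    trim_hours = attr(ds, "trim_hours"),
    offsets = attr(ds, "offsets"),
    n_observations = nrow(ds)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
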