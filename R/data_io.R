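# Workbook input: one spreadsheet (XLSX/XLS) or an equivalent CSV bundle
# holding per-condition replicate time series, experiment metadata and
# user identity.
#
# Layout (identical between the spreadsheet sheets and the CSV files):
#   Data_Live / Data_Dead / Data_Total (data_live.csv, ...):
#       condition | time | rep_1 | rep_2 | ...   (one block per condition)
#   Conditions (conditions.csv):  condition | variable | value
#   Metadata (metadata.csv):      key | value   (cell_line_name, media,
#                                                notes, time_unit)
#   User (user.csv):              key | value   (name, contact)
# At least one data sheet is required; Conditions/User are optional.
# Times are converted to hours on load (accepted units: h, min, day).

OBSERVABLES <- c("Live", "Dead", "Total")

new_replicate_series <- function(times, counts, replicate_id) {
  structure(list(times = as.numeric(times), counts = as.numeric(counts),
                 replicate_id = replicate_id),
            class = "replicate_series")
}

new_condition <- function(label, environment = list(), replicates = list()) {
  structure(list(label = label, environment = environment,
                 replicates = replicates), class = "condition")
}

new_experiment_dataset <- function(conditions, metadata = list(),
                                   user_info = list(), source_path = NA) {
  metadata$time_unit <- metadata$time_unit %||% "h"
  structure(list(conditions = conditions, metadata = metadata,
                 user_info = user_info, source_path = source_path),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf("<experiment_dataset: %d condition(s); cell line: %s>\n",
              length(x$conditions),
              x$metadata$cell_line_name %||% "(unnamed)"))
  for (cond in x$conditions) {
    obs <- names(cond$replicates)
    cat(sprintf("  %s: %s\n", cond$label,
                paste(vapply(obs, function(o)
                  sprintf("%s x%d", o, length(cond$replicates[[o]])), ""),
                  collapse = ", ")))
  }
  invisible(x)
}

time_unit_factor <- function(unit) {
  switch(tolower(unit),
         h = , hr = , hour = , hours = 1,
         min = , minute = , minutes = 1 / 60,
         d = , day = , days = 24,
         stop_cellpopfit("format_error",
                         sprintf("unrecognised time unit '%s'", unit)))
}

read_table_source <- function(path, sheet) {
  if (dir.exists(path)) {
    f <- file.path(path, paste0(tolower(sheet), ".csv"))
    if (!file.exists(f)) return(NULL)
    utils::read.csv(f, check.names = FALSE, colClasses = "character",
                    fileEncoding = "UTF-8")
  } else {
    sheet_name <- c(data_live = "Data_Live", data_dead = "Data_Dead",
                    data_total = "Data_Total", conditions = "Conditions",
                    metadata = "Metadata", user = "User")[[tolower(sheet)]]
    if (!(sheet_name %in% readxl::excel_sheets(path))) return(NULL)
    as.data.frame(readxl::read_excel(path, sheet = sheet_name,
                                     col_types = "text"),
                  check.names = FALSE)
  }
}

parse_kv_table <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0L) return(list())
  stats::setNames(as.list(as.character(tab[[2L]])), as.character(tab[[1L]]))
}

# Strict numeric coercion: every failure surfaces with coordinates.
coerce_numeric <- function(x, sheet, rows, col, issues) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(trimws(x)))
  blank <- which(is.na(x) | !nzchar(trimws(x)))
  for (i in c(bad, blank)) {
    issues$add("error", sprintf("%s row %d column '%s'", sheet, rows[i], col),
               sprintf("non-numeric cell value '%s'", x[i] %||% ""))
  }
  out
}

issue_collector <- function() {
  issues <- data.frame(severity = character(0), location = character(0),
                       message = character(0))
  list(
    add = function(severity, location, message) {
      issues <<- rbind(issues, data.frame(severity = severity,
                                          location = location,
                                          message = message))
    },
    get = function() issues
  )
}

#' Read an experiment workbook
#'
#' Parses a spreadsheet (`.xlsx`/`.xls`) or a CSV-bundle directory into an
#' `experiment_dataset`. Cell counts are never silently coerced: every
#' unparseable cell is reported with its sheet, row and column, and
#' parsing fails closed (no partial dataset).
#'
#' @param path Path to a workbook file or a CSV-bundle directory.
#' @return An `experiment_dataset`.
#' @export
read_workbook <- function(path) {
  if (!file.exists(path)) {
    stop_invalid_input(sprintf("input '%s' does not exist", path))
  }
  issues <- issue_collector()

  data_tabs <- list()
  for (obs in OBSERVABLES) {
    tab <- read_table_source(path, paste0("data_", tolower(obs)))
    if (!is.null(tab)) data_tabs[[obs]] <- tab
  }
  if (length(data_tabs) == 0L) {
    stop_cellpopfit("format_error", sprintf(
      "no data sheet found in '%s' (need Data_Live, Data_Dead or Data_Total)",
      path))
  }

  meta <- parse_kv_table(read_table_source(path, "metadata"))
  user <- parse_kv_table(read_table_source(path, "user"))
  unit <- meta$time_unit %||% "h"
  tfac <- time_unit_factor(unit)

  cond_tab <- read_table_source(path, "conditions")
  environments <- list()
  if (!is.null(cond_tab) && nrow(cond_tab) > 0L) {
    for (i in seq_len(nrow(cond_tab))) {
      lab <- as.character(cond_tab[i, 1L])
      environments[[lab]] <- c(environments[[lab]] %||% list(),
                               stats::setNames(list(as.character(cond_tab[i, 3L])),
                                               as.character(cond_tab[i, 2L])))
    }
  }

  replicates_by_cond <- list()
  for (obs in names(data_tabs)) {
    tab <- data_tabs[[obs]]
    sheet <- paste0("Data_", obs)
    if (nrow(tab) == 0L) {
      stop_cellpopfit("format_error",
                      sprintf("sheet %s is present but empty", sheet))
    }
    if (ncol(tab) < 3L) {
      stop_cellpopfit("format_error", sprintf(
        "sheet %s needs columns: condition, time, rep_1, ...", sheet))
    }
    cond_col <- as.character(tab[[1L]])
    rows <- seq_len(nrow(tab)) + 1L  # +1 for the header row
    times_all <- coerce_numeric(as.character(tab[[2L]]), sheet, rows,
                                names(tab)[2L], issues)
    rep_cols <- names(tab)[-(1:2)]
    for (lab in unique(cond_col)) {
      sel <- cond_col == lab
      times <- times_all[sel] * tfac
      if (anyDuplicated(stats::na.omit(times))) {
        issues$add("error", sprintf("%s condition '%s'", sheet, lab),
                   "duplicate time point within a replicate series")
      }
      ord <- order(times)
      for (rc in rep_cols) {
        counts <- coerce_numeric(as.character(tab[[rc]][sel]), sheet,
                                 rows[sel], rc, issues)
        replicates_by_cond[[lab]][[obs]] <-
          c(replicates_by_cond[[lab]][[obs]] %||% list(),
            list(new_replicate_series(times[ord], counts[ord], rc)))
      }
    }
  }

  found <- issues$get()
  if (nrow(found) > 0L) {
    stop_cellpopfit("format_error", paste0(
      "workbook has unparseable cells:\n",
      paste(sprintf("  [%s] %s: %s", found$severity, found$location,
                    found$message), collapse = "\n")))
  }

  conditions <- lapply(names(replicates_by_cond), function(lab) {
    new_condition(lab, environments[[lab]] %||% list(),
                  replicates_by_cond[[lab]])
  })
  meta$time_unit_original <- unit
  meta$time_unit <- "h"
  new_experiment_dataset(conditions, meta, user, source_path = path)
}

#' Write an experiment dataset as a CSV bundle
#'
#' Inverse of [read_workbook()] for the CSV-bundle dialect; parent
#' directories are created. Round-tripping preserves times, counts,
#' labels and metadata.
#'
#' @param dataset An `experiment_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  for (obs in OBSERVABLES) {
    rows <- list()
    for (cond in dataset$conditions) {
      reps <- cond$replicates[[obs]]
      if (is.null(reps)) next
      block <- data.frame(condition = cond$label,
                          time = fmt(reps[[1L]]$times),
                          check.names = FALSE)
      for (k in seq_along(reps)) {
        block[[paste0("rep_", k)]] <- fmt(reps[[k]]$counts)
      }
      rows[[length(rows) + 1L]] <- block
    }
    if (length(rows) > 0L) {
      utils::write.csv(do.call(rbind, rows),
                       file.path(dir, paste0("data_", tolower(obs), ".csv")),
                       row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    }
  }
  env_rows <- list()
  for (cond in dataset$conditions) {
    for (v in names(cond$environment)) {
      env_rows[[length(env_rows) + 1L]] <- data.frame(
        condition = cond$label, variable = v,
        value = as.character(cond$environment[[v]]))
    }
  }
  if (length(env_rows) > 0L) {
    utils::write.csv(do.call(rbind, env_rows),
                     file.path(dir, "conditions.csv"), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  meta <- dataset$metadata
  meta$time_unit <- "h"
  meta$time_unit_original <- NULL
  kv <- function(x) data.frame(key = names(x),
                               value = vapply(x, as.character, ""))
  utils::write.csv(kv(meta), file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (length(dataset$user_info) > 0L) {
    utils::write.csv(kv(dataset$user_info), file.path(dir, "user.csv"),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Validate a parsed dataset
#'
#' Returns validation issues as data, not exceptions: an empty result
#' means the dataset is ready for fitting.
#'
#' @param dataset An `experiment_dataset`.
#' @return Data frame with columns `severity` ("error"/"warning"),
#'   `location` and `message`.
#' @export
validate_dataset <- function(dataset) {
  issues <- issue_collector()
  if (length(dataset$conditions) == 0L) {
    issues$add("error", "dataset", "no conditions present")
  }
  for (cond in dataset$conditions) {
    for (obs in names(cond$replicates)) {
      reps <- cond$replicates[[obs]]
      grid <- reps[[1L]]$times
      for (k in seq_along(reps)) {
        loc <- sprintf("condition '%s', %s replicate %s", cond$label, obs,
                       reps[[k]]$replicate_id)
        if (length(reps[[k]]$times) < 2L) {
          issues$add("warning", loc,
                     "unfittable replicate: fewer than 2 time points")
        }
        if (any(reps[[k]]$counts < 0, na.rm = TRUE)) {
          bad <- which(reps[[k]]$counts < 0)
          issues$add("error", sprintf("%s, time %s h", loc,
                                      paste(reps[[k]]$times[bad],
                                            collapse = ", ")),
                     "negative cell count")
        }
        if (any(reps[[k]]$times < 0)) {
          issues$add("error", loc, "negative time value")
        }
        if (length(reps[[k]]$times) > 1L &&
            any(diff(reps[[k]]$times) <= 0)) {
          issues$add("error", loc, "times not strictly increasing")
        }
        if (length(reps[[k]]$times) != length(grid) ||
            any(abs(reps[[k]]$times - grid) > 1e-6)) {
          issues$add("error", loc,
                     "replicate not on the condition's common time grid")
        }
      }
    }
  }
  issues$get()
}

#' Subsample a replicate series at a coarser interval
#'
#' Emulates sparser sampling of a densely sampled culture: keeps the
#' native points nearest to `t0 + k * interval` for k = 0, 1, ... within
#' the series span. Deterministic and seedless; idempotent at a fixed
#' interval.
#'
#' @param series A `replicate_series` (or list with `times`/`counts`).
#' @param interval Target sampling interval in hours; must be at least the
#'   native spacing.
#' @return The subsampled `replicate_series`.
#' @export
subsample_series <- function(series, interval) {
  times <- check_times(series$times)
  if (length(times) < 2L) return(series)
  native <- min(diff(times))
  if (!is.numeric(interval) || length(interval) != 1L || is.na(interval) ||
      interval < native - 1e-9) {
    stop_invalid_input(sprintf(
      "interval (%.4g h) must be at least the native spacing (%.4g h)",
      interval, native))
  }
  targets <- seq(times[1L], times[length(times)], by = interval)
  keep <- sort(unique(vapply(targets, function(tt)
    which.min(abs(times - tt)), 1L)))
  new_replicate_series(times[keep], series$counts[keep],
                       series$replicate_id %||% "rep_1")
}

# Aggregate every observable of a condition; when both Live and Dead are
# present on one grid, derive Total replicate-wise as their sum.
aggregate_condition <- function(cond, derive_total = TRUE) {
  out <- list()
  for (obs in names(cond$replicates)) {
    out[[obs]] <- aggregate_replicates(cond$replicates[[obs]], obs)
  }
  if (derive_total && !("Total" %in% names(out)) &&
      all(c("Live", "Dead") %in% names(cond$replicates))) {
    live <- cond$replicates$Live
    dead <- cond$replicates$Dead
    if (length(live) == length(dead) &&
        length(live[[1L]]$times) == length(dead[[1L]]$times) &&
        all(abs(live[[1L]]$times - dead[[1L]]$times) < 1e-6)) {
      tot <- lapply(seq_along(live), function(k)
        new_replicate_series(live[[k]]$times,
                             live[[k]]$counts + dead[[k]]$counts,
                             live[[k]]$replicate_id))
      out$Total <- aggregate_replicates(tot, "Total")
    }
  }
  out
}
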