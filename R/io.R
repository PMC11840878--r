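#' Read and write scheduling instances
#'
#' An instance on disk is an \code{instance.yaml} naming the horizon, the
#' priority weight map, optionally the specialty-room map, and the paths
#' (relative to the YAML file) of two CSVs: \code{surgeries.csv} with
#' columns \code{id,specialty,duration_min,turnover_min,entry_day,
#' deadline_day,priority} and \code{slots.csv} with columns
#' \code{id,day,room,specialty,start_min,length_min,max_surgeries} (blank
#' max = unbounded). Files are UTF-8, comma-separated, with a mandatory
#' header row. Malformed rows are reported with their line numbers;
#' \code{read_instance(write_instance(x))} is the identity.
#'
#' @param path path to the \code{instance.yaml} file.
#' @return an [ssp_instance()].
#' @export
read_instance <- function(path) {
  if (!file.exists(path)) stopf("instance config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  need <- c("horizon_days", "surgeries_csv", "slots_csv")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("%s is missing field(s): %s", path,
                          paste(miss, collapse = ", "))
  surgeries <- read_checked_csv(
    file.path(base, cfg$surgeries_csv),
    cols = c("id", "specialty", "duration_min", "turnover_min",
             "entry_day", "deadline_day", "priority"))
  slots <- read_checked_csv(
    file.path(base, cfg$slots_csv),
    cols = c("id", "day", "room", "specialty", "start_min", "length_min",
             "max_surgeries"))
  for (tab in list(surgeries, slots)) {
    dup <- which(duplicated(tab$id))
    if (length(dup)) {
      stopf("%s: duplicated id '%s' at line %d",
            attr(tab, "source"), tab$id[dup[1]], dup[1] + 1L)
    }
  }
  attr(surgeries, "source") <- NULL
  attr(slots, "source") <- NULL
  weights <- unlist(cfg$priority_weights %||%
                      list("1" = 1, "2" = 2, "3" = 4, "4" = 8))
  ssp_instance(surgeries, slots, cfg$horizon_days,
               priority_weights = weights,
               specialty_rooms = cfg$specialty_rooms)
}

read_checked_csv <- function(path, cols) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  miss <- setdiff(cols, names(tab))
  if (length(miss)) stopf("%s is missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  num <- intersect(names(tab),
                   c("duration_min", "turnover_min", "entry_day",
                     "deadline_day", "priority", "day", "start_min",
                     "length_min", "max_surgeries"))
  for (cn in num) {
    v <- tab[[cn]]
    bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad)) {
      stopf("%s line %d: column %s value '%s' is not numeric",
            path, bad[1] + 1L, cn, v[bad[1]])
    }
    tab[[cn]] <- as.numeric(v)
  }
  attr(tab, "source") <- path
  tab
}

#' @rdname read_instance
#' @param instance an [ssp_instance()].
#' @param dir output directory (created if needed); writes
#'   \code{surgeries.csv}, \code{slots.csv} and \code{instance.yaml}.
#' @return \code{write_instance}: the path of the written
#'   \code{instance.yaml}, invisibly.
#' @export
write_instance <- function(instance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(instance$surgeries, file.path(dir, "surgeries.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(instance$slots, file.path(dir, "slots.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- list(horizon_days = instance$horizon_days,
              surgeries_csv = "surgeries.csv",
              slots_csv = "slots.csv",
              priority_weights = as.list(instance$priority_weights),
              specialty_rooms = instance$specialty_rooms)
  path <- file.path(dir, "instance.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read and write schedules
#'
#' A schedule CSV has columns \code{surgery_id,slot_id,position,
#' scheduled_day}; an empty \code{slot_id} means unscheduled
#' (\code{scheduled_day} is then empty too and \code{position} blank).
#' Reading validates every id against the instance and reports offending
#' line numbers.
#'
#' @param schedule an [ssp_schedule()].
#' @param path CSV file path.
#' @param instance the [ssp_instance()] the schedule belongs to.
#' @return \code{write_schedule}: \code{path} invisibly;
#'   \code{read_schedule}: an [ssp_schedule()].
#' @export
write_schedule <- function(schedule, path, instance) {
  out <- as.data.frame(schedule)
  out$scheduled_day <- unname(scheduled_days(schedule, instance)[out$surgery_id])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, instance) {
  if (!file.exists(path)) stopf("schedule file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(surgery_id = "character",
                                        slot_id = "character"))
  miss <- setdiff(c("surgery_id", "slot_id"), names(tab))
  if (length(miss)) stopf("%s is missing column(s): %s", path,
                          paste(miss, collapse = ", "))
  tab$slot_id[!is.na(tab$slot_id) & tab$slot_id == ""] <- NA_character_
  bad <- which(!tab$surgery_id %in% instance$surgeries$id)
  if (length(bad)) {
    stopf("%s line %d: unknown surgery id '%s'", path, bad[1] + 1L,
          tab$surgery_id[bad[1]])
  }
  bad <- which(!is.na(tab$slot_id) & !tab$slot_id %in% instance$slots$id)
  if (length(bad)) {
    stopf("%s line %d: unknown slot id '%s'", path, bad[1] + 1L,
          tab$slot_id[bad[1]])
  }
  ssp_schedule(tab[, intersect(c("surgery_id", "slot_id", "position"),
                               names(tab))])
}

#' Comparison report across schedules
#'
#' Builds the per-specialty comparison table used to judge an optimized
#' schedule against a baseline: one row per (specialty, schedule) with the
#' penalty score and the counts (and percentages, to one decimal place) of
#' surgeries without penalty, with penalty, and unscheduled, plus an
#' all-specialties summary row per schedule carrying the percentage of
#' surgeries it managed to schedule. Counts in every row sum to that
#' specialty's number of surgeries.
#'
#' @param baseline a feasible [ssp_schedule()] (e.g. from
#'   [generate_manual_baseline()]), or NULL to compare optimized schedules
#'   only.
#' @param optimized named list of feasible schedules, e.g.
#'   \code{list(hc = ..., sa = ...)}.
#' @param instance an [ssp_instance()].
#' @return data.frame of class \code{ssp_compare_report} with columns
#'   \code{specialty}, \code{schedule}, \code{n}, \code{penalty_score},
#'   \code{n_without_penalty}, \code{pct_without_penalty},
#'   \code{n_with_penalty}, \code{pct_with_penalty}, \code{n_unscheduled},
#'   \code{pct_unscheduled}, \code{pct_scheduled}.
#' @export
compare_report <- function(baseline, optimized, instance) {
  schedules <- c(if (!is.null(baseline)) list(baseline = baseline),
                 optimized)
  if (!length(schedules) || is.null(names(schedules)) ||
      any(names(schedules) == "")) {
    stopf("schedules must be a non-empty named list")
  }
  specs <- sort(unique(instance$surgeries$specialty))
  rows <- list()
  for (nm in names(schedules)) {
    rep <- total_penalty(schedules[[nm]], instance)
    if (rep$infeasible) stopf("schedule '%s' is infeasible", nm)
    day <- scheduled_days(schedules[[nm]], instance)
    p <- rep$per_surgery
    for (sp in c(specs, "all")) {
      ids <- if (sp == "all") instance$surgeries$id else
        instance$surgeries$id[instance$surgeries$specialty == sp]
      n <- length(ids)
      n_un <- sum(is.na(day[ids]))
      n_w <- sum(p[ids] > 0)
      n_wo <- n - n_un - n_w
      pct <- function(k) if (n > 0) round(100 * k / n, 1) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        specialty = sp, schedule = nm, n = n,
        penalty_score = sum(p[ids]),
        n_without_penalty = n_wo, pct_without_penalty = pct(n_wo),
        n_with_penalty = n_w, pct_with_penalty = pct(n_w),
        n_unscheduled = n_un, pct_unscheduled = pct(n_un),
        pct_scheduled = pct(n - n_un),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ssp_compare_report", "data.frame")
  out
}

#' @export
print.ssp_compare_report <- function(x, ...) {
  cell <- function(n, p) sprintf("%d (%.1f)", n, p)
  cat(sprintf("%-20s %-10s %12s %16s %16s %16s\n", "specialty", "schedule",
              "penalty", "without pen.", "with pen.", "unscheduled"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-20s %-10s %12g %16s %16s %16s\n",
                x$specialty[i], x$schedule[i], x$penalty_score[i],
                cell(x$n_without_penalty[i], x$pct_without_penalty[i]),
                cell(x$n_with_penalty[i], x$pct_with_penalty[i]),
                cell(x$n_unscheduled[i], x$pct_unscheduled[i])))
  }
  invisible(x)
}

#' Write a report table
#'
#' @param report an [compare_report()] result (or any data.frame).
#' @param path output file.
#' @param format \code{"csv"}, \code{"json"} or \code{"markdown"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               vapply(seq_len(nrow(df)), function(i) {
                 cells <- vapply(df[i, ], function(v) base::format(v), "")
                 paste0("| ", paste(cells, collapse = " | "), " |")
               }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Per-surgery penalty table in the report formats
#'
#' @param report an \code{ssp_penalty_report} from [total_penalty()].
#' @param path output file; format chosen by extension (.json for JSON,
#'   anything else CSV).
#' @return \code{path}, invisibly.
#' @export
write_penalty_report <- function(report, path) {
  df <- data.frame(surgery_id = names(report$per_surgery),
                   penalty = unname(report$per_surgery),
                   stringsAsFactors = FALSE)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(total = report$total, objective = report$objective,
           counts = as.list(report$counts), per_surgery = df),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
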