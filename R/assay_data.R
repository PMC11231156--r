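#' @importFrom rlang .data
NULL

assay_columns <- c("subject_id", "trial_id", "group_label", "x_A", "x_B",
                   "dose_A_ng_ml", "dose_B_ng_ml", "fate", "fate_day",
                   "fate_stage")

new_assay_tbl <- function(data, schedule) {
  data <- tibble::as_tibble(data)
  attr(data, "schedule") <- schedule
  class(data) <- unique(c("assay_tbl", class(data)))
  data
}

#' Stage schedule attached to an assay table
#'
#' @param data An assay tibble (as returned by [read_assay_csv()] or
#'   [simulate_assay()]). If no schedule is attached the default larval
#'   schedule is returned.
#' @return A [stage_schedule()].
#' @export
assay_schedule <- function(data) {
  sch <- attr(data, "schedule", exact = TRUE)
  if (is.null(sch)) default_stage_schedule() else sch
}

#' Validate an assay table
#'
#' Checks the per-subject invariants of the bioassay data model: required
#' columns, unique subject ids, agreement of exposure indicators with doses
#' (`x_A = 1` iff `dose_A_ng_ml > 0`, likewise for B), a consistent
#' exposure/dose combination within each group, legal fates, and day/stage
#' consistency for deaths and removals. Violations are reported together,
#' indexed by row.
#'
#' @param data A data frame with the assay columns.
#' @param schedule A [stage_schedule()].
#' @return The validated data, invisibly, as an assay tibble.
#' @export
validate_assay <- function(data, schedule = assay_schedule(data)) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(assay_columns, names(data))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  problems <- character(0)
  flag <- function(rows, msg) {
    if (length(rows) > 0)
      problems <<- c(problems,
                     sprintf("row %s: %s", paste(rows, collapse = ", "), msg))
  }

  dup <- which(duplicated(data$subject_id))
  flag(dup, "duplicate subject_id")

  flag(which(is.na(data$dose_A_ng_ml) | data$dose_A_ng_ml < 0 |
             is.na(data$dose_B_ng_ml) | data$dose_B_ng_ml < 0),
       "doses must be present and >= 0")
  flag(which(!(data$x_A %in% c(0, 1)) | !(data$x_B %in% c(0, 1))),
       "exposure indicators must be 0/1")
  ok_dose <- !is.na(data$dose_A_ng_ml) & !is.na(data$dose_B_ng_ml) &
    data$x_A %in% c(0, 1) & data$x_B %in% c(0, 1)
  flag(which(ok_dose & data$x_A != as.integer(data$dose_A_ng_ml > 0)),
       "x_A must be 1 iff dose_A_ng_ml > 0")
  flag(which(ok_dose & data$x_B != as.integer(data$dose_B_ng_ml > 0)),
       "x_B must be 1 iff dose_B_ng_ml > 0")

  fates <- c("died", schedule$terminal, "removed")
  flag(which(!(data$fate %in% fates)),
       paste0("fate must be one of: ", paste(fates, collapse = ", ")))

  died <- data$fate == "died"
  flag(which(died & is.na(data$fate_day)), "died records need a fate_day")
  flag(which(data$fate == "removed" & is.na(data$fate_day)),
       "removed records need a removal day")
  has_day <- !is.na(data$fate_day)
  flag(which(has_day &
             (data$fate_day < 1 | data$fate_day > schedule$last_day |
              data$fate_day != floor(data$fate_day))),
       sprintf("fate_day must be an integer in [1, %d]", schedule$last_day))
  bad_stage <- which(died & !is.na(data$fate_stage) &
                     !(data$fate_stage %in% schedule$stages))
  flag(bad_stage, "fate_stage is not a stage of the schedule")

  # group_label -> unique exposure/dose combination
  combos <- dplyr::distinct(data, .data$group_label, .data$x_A, .data$x_B,
                            .data$dose_A_ng_ml, .data$dose_B_ng_ml)
  multi <- combos$group_label[duplicated(combos$group_label)]
  if (length(multi) > 0)
    problems <- c(problems,
                  sprintf("group %s maps to more than one exposure/dose combination",
                          paste(unique(multi), collapse = ", ")))

  if (length(problems) > 0)
    stop("assay validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  # fill fate_stage from the day range when absent (recorded stage wins)
  need <- died & is.na(data$fate_stage)
  if (any(need))
    data$fate_stage[need] <- attribute_stage(data$fate_day[need], schedule)

  invisible(new_assay_tbl(data, schedule))
}

#' Read a two-agent bioassay CSV
#'
#' Reads the per-subject assay dialect (UTF-8, comma-separated, header row,
#' `NA` for missing) and validates it against the data-model invariants.
#' Lines starting with `#` are treated as provenance comments and skipped.
#'
#' @param path Path to the CSV file.
#' @param schedule A [stage_schedule()] used for validation and stage
#'   attribution.
#' @return A validated assay tibble with the schedule attached.
#' @seealso [write_assay_csv()], [validate_assay()]
#' @export
read_assay_csv <- function(path, schedule = default_stage_schedule()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_csv(
    path, comment = "#", na = "NA", show_col_types = FALSE,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      trial_id = readr::col_character(),
      group_label = readr::col_character(),
      x_A = readr::col_integer(),
      x_B = readr::col_integer(),
      dose_A_ng_ml = readr::col_double(),
      dose_B_ng_ml = readr::col_double(),
      fate = readr::col_character(),
      fate_day = readr::col_integer(),
      fate_stage = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  prob <- readr::problems(data)
  if (nrow(prob) > 0)
    stop("unparseable values at row(s) ",
         paste(unique(prob$row), collapse = ", "), call. = FALSE)
  out <- validate_assay(data, schedule)
  out
}

#' Write an assay table to CSV
#'
#' Writes the assay dialect read by [read_assay_csv()]. An optional provenance
#' header (seed, package version) is embedded as `#`-prefixed comment lines.
#'
#' @param data An assay tibble.
#' @param path Output path.
#' @param provenance Optional named character vector written as comments.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(data, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  writeLines(paste(assay_columns, collapse = ","), con)
  out <- dplyr::select(tibble::as_tibble(data),
                       dplyr::all_of(assay_columns))
  lines <- do.call(paste, c(lapply(out, function(col) {
    x <- as.character(col)
    x[is.na(x)] <- "NA"
    x
  }), sep = ","))
  if (length(lines) > 0) writeLines(lines, con)
  invisible(path)
}

#' Group design of an assay table
#'
#' One row per treatment group: exposure indicators, doses, and the number of
#' subjects (total and per trial).
#'
#' @param data An assay tibble.
#' @return A tibble with one row per group.
#' @export
assay_groups <- function(data) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(data), .data$group_label, .data$x_A,
                    .data$x_B, .data$dose_A_ng_ml, .data$dose_B_ng_ml),
    n = dplyr::n(), .groups = "drop"
  )
}
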