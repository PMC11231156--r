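#' Developmental stage schedule
#'
#' Defines the ordered developmental stages of an assay, the inclusive day
#' range each stage occupies, the name of the terminal event, and the last
#' observation day. Day ranges must start at day 1, be contiguous within a
#' stage, disjoint and ordered across stages.
#'
#' @param stages Character vector of stage names, in developmental order.
#' @param day_ranges List of length-2 integer vectors `c(first, last)` per
#'   stage, inclusive day ranges.
#' @param terminal Name of the terminal (successful) event.
#' @param last_day Last observation day; deaths observed after the final
#'   stage's range but on or before `last_day` are attributed to the final
#'   stage.
#'
#' @return An object of class `stage_schedule`.
#' @examples
#' default_stage_schedule()
#' @export
stage_schedule <- function(stages, day_ranges, terminal = "emerged",
                           last_day = NULL) {
  stopifnot(is.character(stages), length(stages) >= 1,
            is.list(day_ranges), length(day_ranges) == length(stages))
  ranges <- lapply(day_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || anyNA(r) || r[1] > r[2])
      stop("each day range must be c(first, last) with first <= last",
           call. = FALSE)
    r
  })
  starts <- vapply(ranges, `[`, integer(1), 1)
  ends <- vapply(ranges, `[`, integer(1), 2)
  if (starts[1] != 1L)
    stop("the first stage must start at day 1", call. = FALSE)
  if (length(stages) > 1 && any(starts[-1] != ends[-length(ends)] + 1L))
    stop("stage day ranges must be contiguous and ordered", call. = FALSE)
  last_day <- if (is.null(last_day)) ends[length(ends)] else as.integer(last_day)
  if (last_day < ends[length(ends)])
    stop("last observation day must be >= end of the final stage",
         call. = FALSE)
  structure(
    list(stages = stages, day_ranges = ranges, terminal = terminal,
         last_day = last_day),
    class = "stage_schedule"
  )
}

#' Default larval assay schedule
#'
#' The conventional honey bee in vitro rearing timeline: larva days 1-6,
#' prepupa days 7-9, pupa days 10-14, observation through day 22 with adult
#' emergence as the terminal event.
#'
#' @return A [stage_schedule()].
#' @export
default_stage_schedule <- function() {
  stage_schedule(
    stages = c("larva", "prepupa", "pupa"),
    day_ranges = list(c(1L, 6L), c(7L, 9L), c(10L, 14L)),
    terminal = "emerged",
    last_day = 22L
  )
}

#' @export
print.stage_schedule <- function(x, ...) {
  cat("<stage_schedule>\n")
  for (i in seq_along(x$stages)) {
    r <- x$day_ranges[[i]]
    cat(sprintf("  %-10s days %d-%d\n", x$stages[i], r[1], r[2]))
  }
  cat(sprintf("  terminal: %s; last observation day %d\n",
              x$terminal, x$last_day))
  invisible(x)
}

#' Attribute a day of death to a developmental stage
#'
#' Returns the stage whose day range contains `fate_day`. Days after the final
#' stage's range but within the observation window map to the final stage
#' (death before the terminal event is still a pre-terminal death).
#'
#' @param fate_day Integer day (or vector of days) of death.
#' @param schedule A [stage_schedule()].
#' @return Character vector of stage names.
#' @examples
#' attribute_stage(c(3, 8, 12, 20), default_stage_schedule())
#' @export
attribute_stage <- function(fate_day, schedule = default_stage_schedule()) {
  stopifnot(inherits(schedule, "stage_schedule"))
  fate_day <- as.integer(fate_day)
  if (anyNA(fate_day) || any(fate_day < 1L) || any(fate_day > schedule$last_day))
    stop("fate_day must lie in [1, ", schedule$last_day, "]", call. = FALSE)
  ends <- vapply(schedule$day_ranges, `[`, integer(1), 2)
  idx <- pmin(findInterval(fate_day, c(1L, ends[-length(ends)] + 1L)),
              length(schedule$stages))
  schedule$stages[idx]
}
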