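# Reading/writing the three tabular inputs: plate-reader time series, plate
# layout, and flow-cytometry gate counts. All files are plain UTF-8 CSV with
# "." decimal separator; times are hours as decimals.

#' Read a plate-reader OD600 time series
#'
#' Expects a long-format CSV with header columns `well`, `time_h`, `od600`.
#' Rows are sorted by time within each well. An optional constant background
#' offset can be subtracted (no blank correction is applied by default).
#'
#' @param path CSV file path.
#' @param blank_offset Constant OD subtracted from every reading (result
#'   floored at 0); default 0.
#' @return Tibble `well`, `time_h`, `od600`, sorted by well then time, with
#'   one growth curve per well.
#' @export
read_timeseries <- function(path, blank_offset = 0) {
  # parse problems surface as NA and are turned into format errors below
  d <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(),
    time_h = readr::col_double(),
    od600 = readr::col_double()
  )))
  if (!all(c("well", "time_h", "od600") %in% names(d))) {
    stop("timeseries CSV must have columns well, time_h, od600")
  }
  if (anyNA(d$time_h) || anyNA(d$od600)) {
    stop("non-numeric time_h or od600 value in timeseries CSV")
  }
  dup <- duplicated(d[, c("well", "time_h")])
  if (any(dup)) {
    stop("duplicate (well, time) rows for well(s): ",
         paste(unique(d$well[dup]), collapse = ", "))
  }
  if (any(d$od600 < 0)) {
    stop("negative OD600 reading in timeseries CSV")
  }
  d <- dplyr::arrange(d, .data$well, .data$time_h)
  if (blank_offset != 0) {
    d$od600 <- pmax(d$od600 - blank_offset, 0)
  }
  counts <- table(d$well)
  if (any(counts < 4)) {
    stop("well(s) with fewer than 4 readings: ",
         paste(names(counts)[counts < 4], collapse = ", "))
  }
  d
}

#' Read a plate layout
#'
#' Expects a CSV with columns `well`, `kind`, `strain_a`, `strain_b`,
#' `species_a`, `species_b`, `replicate`, `run`. `kind` must be
#' `"monoculture"` (the two members are the same strain: wild type plus its
#' fluorescently tagged clone) or `"coculture"` (two different strains).
#'
#' @param path CSV file path.
#' @return Validated tibble of culture descriptors, one row per well.
#' @export
read_layout <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), kind = readr::col_character(),
    strain_a = readr::col_character(), strain_b = readr::col_character(),
    species_a = readr::col_character(), species_b = readr::col_character(),
    replicate = readr::col_integer(), run = readr::col_character()
  ))
  need <- c("well", "kind", "strain_a", "strain_b", "species_a", "species_b",
            "replicate", "run")
  if (!all(need %in% names(d))) {
    stop("layout CSV must have columns ", paste(need, collapse = ", "))
  }
  validate_layout(d)
  d
}

validate_layout <- function(d) {
  if (anyDuplicated(d$well)) {
    stop("duplicate well ids in layout: ",
         paste(unique(d$well[duplicated(d$well)]), collapse = ", "))
  }
  bad_kind <- setdiff(unique(d$kind), c("monoculture", "coculture"))
  if (length(bad_kind)) {
    stop("unknown kind token(s): ", paste(bad_kind, collapse = ", "))
  }
  mono_bad <- d$kind == "monoculture" & d$strain_a != d$strain_b
  if (any(mono_bad)) {
    stop("monoculture with two different strains in well(s): ",
         paste(d$well[mono_bad], collapse = ", "))
  }
  co_bad <- d$kind == "coculture" & d$strain_a == d$strain_b
  if (any(co_bad)) {
    stop("coculture with identical strains in well(s): ",
         paste(d$well[co_bad], collapse = ", "))
  }
  if (any(d$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  invisible(d)
}

#' Read flow-cytometry gate counts
#'
#' Expects a CSV with columns `culture_id`, `timepoint` (`T0` or `T24`),
#' `gate`, `events`. Samples are grouped per (culture, timepoint) and total
#' events computed.
#'
#' @param path CSV file path.
#' @return Tibble `culture_id`, `timepoint`, `gate`, `events`,
#'   `total_events`.
#' @export
read_cytometry <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    culture_id = readr::col_character(),
    timepoint = readr::col_character(),
    gate = readr::col_character(),
    events = readr::col_integer()
  ))
  need <- c("culture_id", "timepoint", "gate", "events")
  if (!all(need %in% names(d))) {
    stop("cytometry CSV must have columns ", paste(need, collapse = ", "))
  }
  bad_tp <- setdiff(unique(d$timepoint), c("T0", "T24"))
  if (length(bad_tp)) {
    stop("timepoint outside {T0, T24}: ", paste(bad_tp, collapse = ", "))
  }
  if (anyNA(d$events) || any(d$events < 0)) {
    stop("negative or missing event count in cytometry CSV")
  }
  d <- dplyr::group_by(d, .data$culture_id, .data$timepoint)
  d <- dplyr::mutate(d, total_events = sum(.data$events))
  d <- dplyr::ungroup(d)
  if (any(d$total_events <= 0)) {
    stop("cytometry sample with zero total events")
  }
  d
}

#' Join growth curves to their culture descriptors
#'
#' 1:1 join of layout wells to curves. A layout well with no curve is an
#' error; curves absent from the layout are dropped with a message.
#'
#' @param curves Tibble from [read_timeseries()].
#' @param layout Tibble from [read_layout()].
#' @return Long tibble: layout columns joined to `time_h`, `od600`.
#' @export
join_layout_curves <- function(curves, layout) {
  missing_curve <- setdiff(layout$well, unique(curves$well))
  if (length(missing_curve)) {
    stop("layout well(s) without a growth curve: ",
         paste(missing_curve, collapse = ", "))
  }
  extra <- setdiff(unique(curves$well), layout$well)
  if (length(extra)) {
    message(length(extra), " curve(s) not in layout dropped: ",
            paste(head(extra, 10), collapse = ", "))
  }
  dplyr::inner_join(layout, curves, by = "well")
}

#' Write a synthetic or processed dataset back to the CSV dialects
#'
#' Convenience inverse of the readers, used by the simulator and the
#' round-trip tests.
#'
#' @param curves,layout,cytometry Tibbles in the shapes produced by the
#'   readers (cytometry may be `NULL`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(curves, layout, cytometry = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    timeseries = file.path(dir, "timeseries.csv"),
    layout = file.path(dir, "layout.csv")
  )
  readr::write_csv(curves, paths[["timeseries"]])
  readr::write_csv(layout, paths[["layout"]])
  if (!is.null(cytometry)) {
    paths <- c(paths, cytometry = file.path(dir, "cytometry.csv"))
    cyto <- cytometry[, c("culture_id", "timepoint", "gate", "events")]
    readr::write_csv(cyto, paths[["cytometry"]])
  }
  invisible(paths)
}
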