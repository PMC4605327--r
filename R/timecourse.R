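# The universal measurement container: replicate-resolved absolute-quantity
# time courses, and their CSV interchange format.

.tc_columns <- c("scenario", "cell_line", "species", "condition",
                 "time_min", "replicate", "value_fg")
.tc_species <- c("pre_mrna", "spliced_mrna")

#' Construct / validate a time course
#'
#' A time course is a tibble with columns `scenario`, `cell_line`, `species`
#' (`pre_mrna` or `spliced_mrna`), `condition`, `time_min` (>= 0),
#' `replicate` (integer) and `value_fg` (>= 0, finite): absolute RNA mass per
#' qRT/PCR reaction at each sampled time, per replicate. Rows are sorted by
#' replicate then time; each replicate needs at least two distinct times; the
#' key (scenario, species, condition, time_min, replicate) must be unique.
#'
#' @param df Data frame with the columns above.
#' @return A validated `timecourse` tibble.
#' @export
timecourse <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(.tc_columns, names(df))
  if (length(missing_cols)) {
    stop("missing time-course column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[.tc_columns]
  bad_sp <- which(!df$species %in% .tc_species)
  if (length(bad_sp)) {
    stop(sprintf("row %d: species '%s' not one of %s", bad_sp[1],
                 df$species[bad_sp[1]], paste(.tc_species, collapse = "/")),
         call. = FALSE)
  }
  if (any(!is.finite(df$time_min)) || any(df$time_min < 0)) {
    stop(sprintf("row %d: time_min must be finite and >= 0",
                 which(!is.finite(df$time_min) | df$time_min < 0)[1]),
         call. = FALSE)
  }
  if (any(!is.finite(df$value_fg)) || any(df$value_fg < 0)) {
    stop(sprintf("row %d: value_fg must be finite and >= 0",
                 which(!is.finite(df$value_fg) | df$value_fg < 0)[1]),
         call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  key <- interaction(df$scenario, df$species, df$condition, df$time_min,
                     df$replicate, drop = TRUE)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (scenario, species, condition, time, replicate) key at row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  df <- df[order(df$scenario, df$species, df$condition, df$replicate,
                 df$time_min), ]
  n_times <- tapply(df$time_min,
                    interaction(df$scenario, df$species, df$condition,
                                df$replicate, drop = TRUE),
                    function(t) length(unique(t)))
  if (any(n_times < 2)) {
    stop("each replicate trajectory needs >= 2 distinct time points",
         call. = FALSE)
  }
  class(df) <- c("timecourse", class(tibble::tibble()))
  df
}

#' Read a time-course CSV
#'
#' Reads the package's interchange format: a UTF-8 CSV with header
#' `scenario,cell_line,species,condition,time_min,replicate,value_fg`.
#' Lines beginning with `#` (metadata headers written by
#' [write_timecourse()]) are ignored. A header-only file yields an empty
#' dataset with a warning. Schema violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return A `timecourse` tibble (possibly zero rows).
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.tc_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$time_min <- as.numeric(df$time_min)
  df$value_fg <- as.numeric(df$value_fg)
  if (nrow(df) == 0L) {
    warning("empty time-course file (header only): ", path, call. = FALSE)
    df <- tibble::as_tibble(df[.tc_columns])
    class(df) <- c("timecourse", class(tibble::tibble()))
    return(df)
  }
  timecourse(df)
}

#' Write a time-course CSV
#'
#' Serialises a time course losslessly (15 significant digits) with a comment
#' header recording the package version and a content hash of the data, so
#' any numerical output file is traceable to the code that produced it.
#'
#' @param tc A `timecourse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse") || is.data.frame(tc))
  df <- as.data.frame(tc)[.tc_columns]
  df$time_min <- format(df$time_min, digits = 15, trim = TRUE, scientific = FALSE)
  df$value_fg <- format(df$value_fg, digits = 15, trim = TRUE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# asokinetics %s",
            as.character(utils::packageVersion("asokinetics"))),
    sprintf("# rows=%d hash=%s", nrow(df), .content_hash(df))
  ), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cheap deterministic content hash (no digest dependency): sum of a rolling
# polynomial over the serialized bytes, hex-coded.
.content_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::write.csv(x, row.names = FALSE)),
                                      collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Subset a time course
#'
#' Convenience filter on the metadata columns.
#'
#' @param tc A `timecourse`.
#' @param scenario,species,condition,cell_line Optional values to keep.
#' @return A `timecourse` with matching rows.
#' @export
filter_timecourse <- function(tc, scenario = NULL, species = NULL,
                              condition = NULL, cell_line = NULL) {
  keep <- rep(TRUE, nrow(tc))
  if (!is.null(scenario)) keep <- keep & tc$scenario %in% scenario
  if (!is.null(species)) keep <- keep & tc$species %in% species
  if (!is.null(condition)) keep <- keep & tc$condition %in% condition
  if (!is.null(cell_line)) keep <- keep & tc$cell_line %in% cell_line
  out <- tc[keep, ]
  class(out) <- c("timecourse", class(tibble::tibble()))
  out
}
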