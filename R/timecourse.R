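# Long-format container for replicated analyte measurements over time.
# One canonical CSV dialect: comma-separated, '.' decimal, exact header
# setup_id,strain,replicate,time_h,analyte,value,unit — no sniffing, so
# fixtures round-trip bit-exactly.

.tc_header <- c("setup_id", "strain", "replicate", "time_h",
                "analyte", "value", "unit")
.tc_analytes <- c("Fe2", "NO3", "NO2", "N2O")

#' Construct and validate a measured time course
#'
#' A long-format table of replicated analyte measurements for one setup.
#' Validation enforces the file contract: known analytes, non-negative
#' finite values in mM, no duplicate (setup, replicate, time, analyte)
#' keys, and a shared time grid across all (replicate, analyte) series.
#'
#' @param df A data.frame with columns
#'   `setup_id, strain, replicate, time_h, analyte, value, unit`.
#' @return The validated data.frame, classed `nrfo_timecourse`.
#' @examples
#' df <- data.frame(setup_id = "s", strain = "x", replicate = 1,
#'                  time_h = c(0, 240), analyte = "NO3",
#'                  value = c(10, 8.92), unit = "mM")
#' timecourse(df)
#' @export
timecourse <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(.tc_header, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- df[.tc_header]
  df$replicate <- as.integer(df$replicate)
  df$time_h <- as.numeric(df$time_h)
  df$value <- as.numeric(df$value)
  bad <- which(!(df$analyte %in% .tc_analytes))
  if (length(bad))
    stop("row ", bad[1], ": unknown analyte '", df$analyte[bad[1]],
         "' (allowed: ", paste(.tc_analytes, collapse = ", "), ")",
         call. = FALSE)
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad))
    stop("row ", bad[1], ": value must be a non-negative finite number",
         call. = FALSE)
  key <- paste(df$setup_id, df$replicate, df$time_h, df$analyte, sep = "\r")
  if (anyDuplicated(key))
    stop("row ", which(duplicated(key))[1],
         ": duplicate (setup_id, replicate, time_h, analyte) key",
         call. = FALSE)
  # every (replicate, analyte) series must share one strictly increasing grid
  grids <- tapply(df$time_h, list(df$replicate, df$analyte),
                  function(t) paste(sort(t), collapse = ","))
  grids <- grids[!is.na(grids)]
  if (length(unique(grids)) > 1L)
    stop("ragged time grids across replicates/analytes", call. = FALSE)
  ord <- order(df$replicate, df$analyte, df$time_h)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("nrfo_timecourse", "data.frame"))
}

#' Read a time-course CSV
#'
#' Expects the exact canonical header
#' `setup_id,strain,replicate,time_h,analyte,value,unit`, UTF-8, '.'
#' decimal separator; all validation errors name the offending data row.
#'
#' @param path Path to a CSV file.
#' @return An `nrfo_timecourse`.
#' @seealso [write_timecourse()]
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (!identical(header, .tc_header))
    stop("header must be exactly '", paste(.tc_header, collapse = ","),
         "', got '", paste(header, collapse = ","), "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(setup_id = "character",
                                       strain = "character",
                                       replicate = "integer",
                                       time_h = "numeric",
                                       analyte = "character",
                                       value = "numeric",
                                       unit = "character"))
  timecourse(df)
}

#' Write a time-course CSV in the canonical dialect
#'
#' @param tc An `nrfo_timecourse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "nrfo_timecourse"))
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.nrfo_timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> setup '%s', strain '%s': %d replicates, %d times, analytes %s\n",
              x$setup_id[1], x$strain[1], length(unique(x$replicate)),
              length(unique(x$time_h)),
              paste(sort(unique(x$analyte)), collapse = "/")))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("... (", nrow(x) - 8L, " more rows)\n", sep = "")
  invisible(x)
}
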