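#' Read a DAM2-style monitor file
#'
#' Parses the common DAMSystem3 text layout: 42 tab-separated columns per row
#' with column 1 a running index, column 2 the date (`"D Mon YY"`), column 3
#' the time (`"HH:MM:SS"`), column 4 a status code (1 = valid), columns 5-9
#' auxiliary fields (preserved, not interpreted), column 10 the light-sensor
#' flag and columns 11-42 the 32 channel counts. Rows with a bad status code
#' are flagged (`valid == FALSE`), never dropped.
#'
#' @param path path to the monitor file.
#' @param n_channels number of count channels (32 in the DAM2 dialect).
#' @return an object of class `dam_monitor`: a data.frame with columns
#'   `index`, `datetime`, `status`, `valid`, `aux1..aux5`, `light_sensor` and
#'   `ch01..ch32`.
#' @export
read_dam_monitor <- function(path, n_channels = 32) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- 10 + n_channels
  nf <- lengths(fields)
  if (any(nf != ncols))
    stop(sprintf("parse error at line %d: expected %d columns, found %d",
                 which(nf != ncols)[1], ncols, nf[which(nf != ncols)[1]]))
  m <- matrix(unlist(fields), ncol = ncols, byrow = TRUE)
  datetime <- as.POSIXct(paste(m[, 2], m[, 3]), format = "%d %b %y %H:%M:%S",
                         tz = "UTC")
  if (any(is.na(datetime)))
    stop(sprintf("parse error at line %d: bad date/time '%s %s'",
                 which(is.na(datetime))[1], m[which(is.na(datetime))[1], 2],
                 m[which(is.na(datetime))[1], 3]))
  if (is.unsorted(datetime, strictly = TRUE))
    stop("ordering error: timestamps are not strictly increasing")
  counts <- m[, 10 + seq_len(n_channels), drop = FALSE]
  suppressWarnings(storage_ok <- !any(is.na(as.numeric(counts))))
  if (!storage_ok) stop("parse error: non-numeric channel count")
  counts <- matrix(as.integer(counts), nrow = nrow(m))
  if (any(counts < 0)) stop("parse error: negative channel count")
  out <- data.frame(index = as.integer(m[, 1]), datetime = datetime,
                    status = as.integer(m[, 4]), stringsAsFactors = FALSE)
  out$valid <- out$status == 1L
  for (k in 1:5) out[[paste0("aux", k)]] <- m[, 4 + k]
  out$light_sensor <- as.integer(m[, 10])
  colnames(counts) <- sprintf("ch%02d", seq_len(n_channels))
  out <- cbind(out, as.data.frame(counts))
  class(out) <- c("dam_monitor", "data.frame")
  out
}

#' Write activity series as a DAM2-style monitor file
#'
#' Inverse of [read_dam_monitor()] composed with [bin_counts()]: each series
#' becomes one channel; rows are emitted at the series' common bin spacing.
#' `read_dam_monitor()` followed by `bin_counts()` at the same width is the
#' identity on counts.
#'
#' @param series_set list of [activity_series()] on an identical time base
#'   (at most 32).
#' @param path output path.
#' @param light_sensor optional 0/1 vector per row (defaults to 0).
#' @return `path`, invisibly.
#' @export
write_dam_monitor <- function(series_set, path, light_sensor = NULL) {
  if (inherits(series_set, "activity_series")) series_set <- list(series_set)
  n <- length(series_set)
  if (n > 32) stop("capacity error: a DAM2 file holds at most 32 channels")
  if (n == 0) stop("no series to write")
  len <- length(series_set[[1]]$counts)
  bw <- series_set[[1]]$bin_width
  t0 <- series_set[[1]]$t0
  for (s in series_set) {
    if (length(s$counts) != len || s$bin_width != bw ||
        abs(as.numeric(difftime(s$t0, t0, units = "mins"))) > 1e-9)
      stop("all series must share an identical time base")
  }
  tt <- t0 + (seq_len(len) - 1) * bw * 60
  counts <- matrix(0L, len, 32)
  for (j in seq_len(n)) counts[, j] <- as.integer(series_set[[j]]$counts)
  ls <- if (is.null(light_sensor)) rep(0L, len) else as.integer(light_sensor)
  lt <- as.POSIXlt(tt)
  rows <- paste(seq_len(len),
                format(tt, "%d %b %y"), format(tt, "%H:%M:%S"),
                1L, 0L, 0L, 0L, 0L, 0L, ls,
                apply(counts, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Aggregate raw monitor rows of one channel into analysis bins
#'
#' Sums the per-row counts of `channel` into contiguous bins of `bin_width`
#' minutes, conserving total counts. The row spacing is inferred from the
#' timestamps; a gap in the record is an error unless `fill_gaps = TRUE`
#' (gaps are then filled with zero counts before binning).
#'
#' @param monitor a `dam_monitor` from [read_dam_monitor()].
#' @param channel channel number (1-32).
#' @param bin_width output bin width in minutes; must divide 60 and be a
#'   multiple of the row spacing.
#' @param fill_gaps zero-fill missing rows instead of raising an error.
#' @param fly_id,genotype identifiers for the resulting series.
#' @return an [activity_series()].
#' @export
bin_counts <- function(monitor, channel, bin_width = 30, fill_gaps = FALSE,
                       fly_id = sprintf("ch%02d", channel),
                       genotype = "unknown") {
  stopifnot(inherits(monitor, "dam_monitor"))
  if (60 %% bin_width != 0 && bin_width %% 60 != 0)
    stop("bin_width must divide 60 or be a multiple of 60 minutes")
  col <- sprintf("ch%02d", channel)
  if (!col %in% names(monitor)) stop("no such channel: ", channel)
  tt <- monitor$datetime
  x <- monitor[[col]]
  if (length(tt) < 2) stop("recording too short to infer row spacing")
  steps <- as.numeric(diff(tt), units = "mins")
  step <- min(steps)
  if (any(abs(steps - step) > 1e-6)) {
    if (!fill_gaps)
      stop("gap error: missing rows in the record (use fill_gaps = TRUE to zero-fill)")
    full_t <- seq(tt[1], tt[length(tt)], by = step * 60)
    xf <- rep(0L, length(full_t))
    xf[match(round(as.numeric(tt)), round(as.numeric(full_t)))] <- x
    tt <- full_t; x <- xf
  }
  if (abs(bin_width / step - round(bin_width / step)) > 1e-9)
    stop("bin_width must be a multiple of the row spacing (", step, " min)")
  per <- as.integer(round(bin_width / step))
  nbin <- length(x) %/% per
  if (nbin < 1) stop("recording shorter than one bin")
  x <- x[seq_len(nbin * per)]
  binned <- as.integer(tapply(x, rep(seq_len(nbin), each = per), sum))
  activity_series(binned, bin_width, tt[1], fly_id = fly_id, genotype = genotype)
}

#' Export annotated series as a tidy per-bin table
#'
#' @param series_set list of annotated [activity_series()].
#' @param path optional CSV path; if given the table is also written there.
#' @return data.frame with columns fly_id, genotype, t, zt, segment, light,
#'   count.
#' @export
series_to_table <- function(series_set, path = NULL) {
  if (inherits(series_set, "activity_series")) series_set <- list(series_set)
  out <- do.call(rbind, lapply(series_set, as.data.frame))
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
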