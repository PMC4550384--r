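# Plain-text container formats.  Image stacks use a one-line JSON header
# followed by a CSV block of frame rows (frame-major, then channel), so
# stacks, masks and traces are all diffable text; integer-valued
# intensities round-trip exactly.

#' Write an image stack to a text container
#'
#' Line 1 is a JSON header (dimensions, channel roles, timestamps);
#' the remainder is one CSV row per image row, frames ordered
#' frame-major then channel.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  hdr <- jsonlite::toJSON(list(
    format = "rfivm-stack-v1", nrow = d[1], ncol = d[2],
    n_channels = d[3], n_frames = d[4],
    channel_roles = as.list(stack$channel_roles),
    timestamps_s = stack$timestamps_s), auto_unbox = TRUE, digits = NA)
  writeLines(as.character(hdr), path)
  # rows x (cols) blocks: frame-major, then channel, then image row
  flat <- aperm(stack$frames, c(1L, 3L, 4L, 2L))
  dim(flat) <- c(d[1] * d[3] * d[4], d[2])
  data.table::fwrite(data.table::as.data.table(flat), path, append = TRUE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path File path.
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  hdr_line <- readLines(path, n = 1L)
  hdr <- tryCatch(jsonlite::fromJSON(hdr_line), error = function(e) NULL)
  if (is.null(hdr) || !identical(hdr$format, "rfivm-stack-v1"))
    stop("unknown stack format in ", path, call. = FALSE)
  dat <- data.table::fread(path, skip = 1L, header = FALSE)
  flat <- as.matrix(dat)
  expected <- hdr$nrow * hdr$n_channels * hdr$n_frames
  if (nrow(flat) != expected || ncol(flat) != hdr$ncol)
    stop("corrupt stack: data block does not match header in ", path,
         call. = FALSE)
  storage.mode(flat) <- "double"
  dimnames(flat) <- NULL
  dim(flat) <- c(hdr$nrow, hdr$n_channels, hdr$n_frames, hdr$ncol)
  frames <- aperm(flat, c(1L, 4L, 2L, 3L))
  roles <- vapply(hdr$channel_roles, as.integer, integer(1))
  image_stack(frames, roles, hdr$timestamps_s)
}

#' Write / read a binary mask as CSV of 0/1
#'
#' @param mask A [binary_mask()].
#' @param path File path.
#' @return `path` invisibly; `read_mask` returns a [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  data.table::fwrite(data.table::as.data.table(mask$pixels * 1L), path,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  px <- as.matrix(data.table::fread(path, header = FALSE)) > 0
  dimnames(px) <- NULL
  binary_mask(px)
}

#' Write / read a temperature trace as CSV
#'
#' Columns: `time_s`, then one column per probe.
#'
#' @param trace A [temperature_trace()].
#' @param path File path.
#' @return `path` invisibly; `read_temperature_trace` returns a
#'   [temperature_trace()].
#' @export
write_temperature_trace <- function(trace, path) {
  stopifnot(inherits(trace, "temperature_trace"))
  df <- data.frame(time_s = trace$times, trace$temperature,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperature_trace
#' @export
read_temperature_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  temperature_trace(df$time_s, as.matrix(df[, -1, drop = FALSE]),
                    probe_labels = names(df)[-1])
}

#' Write / read a power schedule as CSV
#'
#' Columns `time_s, power_w`; a `# max_power_w=` comment line carries the
#' amplifier maximum.
#'
#' @param schedule A [power_schedule()].
#' @param path File path.
#' @return `path` invisibly; `read_power_schedule` returns a
#'   [power_schedule()].
#' @export
write_power_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "power_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# max_power_w=%.10g", schedule$max_power), con)
  utils::write.csv(data.frame(time_s = schedule$times,
                              power_w = schedule$power),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_power_schedule
#' @export
read_power_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  max_power <- 200
  skip <- 0L
  if (startsWith(first, "#")) {
    max_power <- as.numeric(sub(".*max_power_w=", "", first))
    skip <- 1L
  }
  df <- utils::read.csv(path, skip = skip)
  power_schedule(df$time_s, df$power_w, max_power = max_power)
}

#' Write / read a voltage grid as CSV
#'
#' A `# spacing_m=` comment line carries the node spacing in meters,
#' followed by the voltage matrix.
#'
#' @param grid A [voltage_grid()].
#' @param path File path.
#' @return `path` invisibly; `read_voltage_grid` returns a
#'   [voltage_grid()].
#' @export
write_voltage_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voltage_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_m=%.10g", grid$spacing), con)
  utils::write.table(grid$values, con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
  invisible(path)
}

#' @rdname write_voltage_grid
#' @export
read_voltage_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#") || !grepl("spacing_m=", first))
    stop("voltage-grid file lacks the spacing header: ", path,
         call. = FALSE)
  spacing <- as.numeric(sub(".*spacing_m=", "", first))
  m <- as.matrix(utils::read.table(path, skip = 1L, sep = ","))
  dimnames(m) <- NULL
  voltage_grid(m, spacing)
}
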