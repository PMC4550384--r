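#' Positive area fraction of an image
#'
#' Fraction of pixels in the image whose intensity exceeds the background
#' threshold.
#'
#' @param img Numeric matrix.
#' @param background_threshold Threshold intensity.
#' @param region Optional logical matrix or [binary_mask()] restricting
#'   the count to a region (the default, the whole image, follows the
#'   whole-frame definition).
#' @return Fraction in `[0, 1]`.
#' @export
paf <- function(img, background_threshold, region = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(region)) return(mean(img > background_threshold))
  px <- if (inherits(region, "binary_mask")) region$pixels else region
  stopifnot(identical(dim(px), dim(img)))
  if (sum(px) == 0L) stop("region is empty", call. = FALSE)
  mean(img[px] > background_threshold)
}

region_means <- function(stack, region, tracer_channel, saturation) {
  px <- if (inherits(region, "binary_mask")) region$pixels else region
  stopifnot(is.logical(px))
  if (sum(px) == 0L) stop("region is empty", call. = FALSE)
  ch <- get_channel(stack, tracer_channel)
  nf <- dim(ch)[3]
  vapply(seq_len(nf), function(i) {
    v <- ch[, , i][px]
    if (!is.null(saturation)) v <- v[v < saturation]
    mean(v)
  }, numeric(1))
}

#' Relative tumor dye intensity (RTDI) series
#'
#' Mean tracer intensity over a region, per frame, normalized by the mean
#' over a baseline window of frames, so the baseline value is 1.  This is
#' the time course of tracer dye that has migrated into the (typically
#' extravascular tumor) region.
#'
#' @param stack An [image_stack()].
#' @param region [binary_mask()] or logical matrix (nonempty).
#' @param tracer_channel Channel role (default `"albumin"`).
#' @param baseline_frames Indices of the baseline window (default frame 1).
#' @param saturation Optional intensity at which pixels are considered
#'   saturated and excluded from the means.
#' @return Numeric vector of per-frame RTDI values.
#' @export
rtdi_series <- function(stack, region, tracer_channel = "albumin",
                        baseline_frames = 1L, saturation = NULL) {
  stopifnot(inherits(stack, "image_stack"), length(baseline_frames) >= 1L)
  m <- region_means(stack, region, tracer_channel, saturation)
  base <- mean(m[baseline_frames])
  if (base == 0) stop("baseline mean intensity is zero", call. = FALSE)
  m / base
}

#' Relative increase in albumin fluorescence (RAIF)
#'
#' End-to-start ratio of the region-mean tracer intensity: the mean over
#' an end window of frames divided by the mean over a start window.
#'
#' @inheritParams rtdi_series
#' @param window_start,window_end Frame-index windows; defaults are the
#'   first and last 10 percent of frames.  Windows must not overlap and
#'   the end window must come after the start window.
#' @return A single ratio (dimensionless).
#' @export
raif <- function(stack, region, tracer_channel = "albumin",
                 window_start = NULL, window_end = NULL,
                 saturation = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  nf <- length(stack$timestamps_s)
  w <- max(1L, floor(nf / 10))
  if (is.null(window_start)) window_start <- seq_len(w)
  if (is.null(window_end)) window_end <- (nf - w + 1L):nf
  if (length(intersect(window_start, window_end)) > 0L ||
      max(window_start) >= min(window_end))
    stop("windows must be nonoverlapping with end after start",
         call. = FALSE)
  m <- region_means(stack, region, tracer_channel, saturation)
  mean(m[window_end]) / mean(m[window_start])
}

#' RAIF over replicate stacks
#'
#' @param stacks List of at least two [image_stack()] objects.
#' @param regions A single region applied to all stacks, or a list of
#'   regions, one per stack.
#' @param ... Passed to [raif()].
#' @return A list with `values` (per-stack RAIF), `mean` and `sd`.
#' @export
raif_replicates <- function(stacks, regions, ...) {
  stopifnot(is.list(stacks), length(stacks) >= 2L)
  if (!is.list(regions) || inherits(regions, "binary_mask"))
    regions <- rep(list(regions), length(stacks))
  vals <- mapply(function(s, r) raif(s, r, ...), stacks, regions)
  list(values = vals, mean = mean(vals), sd = stats::sd(vals))
}
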