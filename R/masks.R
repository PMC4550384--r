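#' Binary region mask with provenance
#'
#' @param pixels Logical matrix.
#' @param source_channel Channel role the mask was derived from (or NA).
#' @param threshold_value Threshold used (or NA).
#' @param morphology_trace Character vector of applied morphology steps,
#'   in order.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, source_channel = NA_character_,
                        threshold_value = NA_real_,
                        morphology_trace = character(0)) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, source_channel = source_channel,
                 threshold_value = threshold_value,
                 morphology_trace = morphology_trace),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask %d x %d: %d px (%.1f%%), channel %s, thr %.4g%s\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$source_channel, x$threshold_value,
              if (length(x$morphology_trace))
                paste0(" [", paste(x$morphology_trace, collapse = ", "), "]")
              else ""))
  invisible(x)
}

threshold_and_clean <- function(img, channel, dilate_r, erode_r, method,
                                fixed_value) {
  thr <- global_threshold(img, method = method, fixed_value = fixed_value)
  m <- img > thr
  trace <- character(0)
  if (dilate_r > 0) {
    m <- dilate_mask(m, dilate_r)
    trace <- c(trace, sprintf("dilate(r=%g)", dilate_r))
  }
  if (erode_r > 0) {
    m <- erode_mask(m, erode_r)
    trace <- c(trace, sprintf("erode(r=%g)", erode_r))
  }
  binary_mask(m, source_channel = channel, threshold_value = thr,
              morphology_trace = trace)
}

#' Tumor mask by global thresholding of the tumor channel
#'
#' Thresholds the constitutive tumor-fluorophore channel into a binary
#' image, then applies dilate followed by erode (a morphological closing
#' when the radii are equal) to remove holes and smooth the mask edges.
#'
#' @param stack An [image_stack()] with a `tumor` channel role.
#' @param frame_idx Frame used for thresholding (default 1, the baseline).
#' @param dilate_r,erode_r Disc radii in pixels (defaults 2 and
#'   `dilate_r`).
#' @param method,fixed_value Passed to [global_threshold()].
#' @return A [binary_mask()].
#' @export
tumor_mask <- function(stack, frame_idx = 1L, dilate_r = 2,
                       erode_r = dilate_r, method = "otsu",
                       fixed_value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!"tumor" %in% names(stack$channel_roles))
    stop("stack has no 'tumor' channel role", call. = FALSE)
  img <- stack$frames[, , stack$channel_roles[["tumor"]], frame_idx]
  threshold_and_clean(img, "tumor", dilate_r, erode_r, method, fixed_value)
}

#' Vasculature mask from the high-intensity tracer signal
#'
#' Thresholds a tracer channel at a high-intensity cutoff — by default
#' Otsu on the baseline frame, where the tracer is still purely
#' intravascular and the vessels dominate the histogram — followed by the
#' same dilate/erode cleanup as [tumor_mask()].
#'
#' @param stack An [image_stack()].
#' @param tracer_channel Channel role (default `"dextran"`).
#' @param frame_idx Baseline frame used for thresholding (default 1).
#' @inheritParams tumor_mask
#' @return A [binary_mask()] (empty, with a warning, for an all-dark
#'   channel).
#' @export
vessel_mask <- function(stack, tracer_channel = "dextran", frame_idx = 1L,
                        dilate_r = 2, erode_r = dilate_r, method = "otsu",
                        fixed_value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!tracer_channel %in% names(stack$channel_roles))
    stop(sprintf("stack has no '%s' channel role", tracer_channel),
         call. = FALSE)
  img <- stack$frames[, , stack$channel_roles[[tracer_channel]], frame_idx]
  if (length(unique(as.numeric(img))) == 1L) {
    warning("tracer channel is constant; returning an empty vessel mask")
    return(binary_mask(matrix(FALSE, nrow(img), ncol(img)),
                       source_channel = tracer_channel,
                       threshold_value = img[1]))
  }
  threshold_and_clean(img, tracer_channel, dilate_r, erode_r, method,
                      fixed_value)
}

#' Extravascular component of the tumor area
#'
#' Combines the tumor and vasculature masks: pixels inside the tumor but
#' outside the vessels.  The partition is exact set arithmetic:
#' `|extravascular| + |tumor AND vessels| = |tumor|`.
#'
#' @param tumor,vessels [binary_mask()] objects of the same shape.
#' @return A [binary_mask()].
#' @export
extravascular_mask <- function(tumor, vessels) {
  stopifnot(inherits(tumor, "binary_mask"), inherits(vessels, "binary_mask"))
  if (!identical(dim(tumor$pixels), dim(vessels$pixels)))
    stop("mask shapes differ", call. = FALSE)
  binary_mask(tumor$pixels & !vessels$pixels,
              source_channel = sprintf("%s - %s", tumor$source_channel,
                                       vessels$source_channel))
}

#' Jaccard overlap of two binary masks
#'
#' @param a,b Logical matrices or [binary_mask()] objects.
#' @return Intersection-over-union in `[0, 1]` (1 for two empty masks).
#' @export
mask_jaccard <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$pixels else a
  pb <- if (inherits(b, "binary_mask")) b$pixels else b
  stopifnot(identical(dim(pa), dim(pb)))
  un <- sum(pa | pb)
  if (un == 0L) return(1)
  sum(pa & pb) / un
}
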