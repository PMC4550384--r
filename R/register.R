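#' Estimate rigid frame shifts by cross-correlation
#'
#' Integer-pixel translation of each frame relative to a reference frame,
#' located at the peak of the FFT cross-correlation of a chosen channel
#' (by default the tumor channel, whose signal is constant in time).
#'
#' @param stack An [image_stack()] with at least 2 frames.
#' @param reference_frame Index of the reference frame (default 1).
#' @param channel Channel role used for registration (default `"tumor"`).
#' @return Integer matrix `n_frames x 2` of (dy, dx) shifts of each frame
#'   relative to the reference.
#' @export
estimate_shifts <- function(stack, reference_frame = 1L,
                            channel = "tumor") {
  stopifnot(inherits(stack, "image_stack"))
  nf <- length(stack$timestamps_s)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  ch <- get_channel(stack, channel)
  ref <- ch[, , reference_frame]
  if (stats::sd(ref) == 0) {
    warning("featureless reference frame: low confidence, identity shifts")
    return(matrix(0L, nf, 2))
  }
  nr <- nrow(ref); nc <- ncol(ref)
  fref <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, nf, 2)
  for (i in seq_len(nf)) {
    if (i == reference_frame) next
    frm <- ch[, , i]
    cc <- Re(stats::fft(stats::fft(frm - mean(frm)) * Conj(fref),
                        inverse = TRUE))
    pk <- which.max(cc)
    dy <- (pk - 1L) %% nr
    dx <- (pk - 1L) %/% nr
    if (dy > nr / 2) dy <- dy - nr
    if (dx > nc / 2) dx <- dx - nc
    shifts[i, ] <- c(dy, dx)
  }
  shifts
}

#' Remove respiration jitter by rigid registration
#'
#' Estimates each frame's translation against a reference frame with
#' [estimate_shifts()] and shifts every channel back, filling vacated
#' pixels with the frame's median intensity.
#'
#' @inheritParams estimate_shifts
#' @return A corrected [image_stack()] with attribute `"shifts"` (the
#'   estimated per-frame (dy, dx)).
#' @export
jitter_correct <- function(stack, reference_frame = 1L, channel = "tumor") {
  shifts <- estimate_shifts(stack, reference_frame, channel)
  frames <- stack$frames
  nchan <- dim(frames)[3]
  for (i in seq_len(nrow(shifts))) {
    if (all(shifts[i, ] == 0L)) next
    for (j in seq_len(nchan)) {
      f <- frames[, , j, i]
      frames[, , j, i] <- shift_matrix(f, -shifts[i, 1], -shifts[i, 2],
                                       fill = stats::median(f))
    }
  }
  out <- image_stack(frames, stack$channel_roles, stack$timestamps_s)
  attr(out, "shifts") <- shifts
  out
}
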