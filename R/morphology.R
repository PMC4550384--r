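# Binary morphology with a disc structuring element, implemented as
# shift-and-combine over the disc's integer offsets.

disc_offsets <- function(r) {
  rr <- ceiling(r)
  off <- expand.grid(dy = -rr:rr, dx = -rr:rr)
  off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
}

#' Dilate a binary mask with a disc structuring element
#'
#' @param m Logical matrix.
#' @param r Disc radius in pixels (`r = 0` is the identity).
#' @return Logical matrix.
#' @export
dilate_mask <- function(m, r) {
  stopifnot(is.matrix(m))
  if (r <= 0) return(m)
  off <- disc_offsets(r)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(off)))
    out <- out | shift_matrix(m, off$dy[k], off$dx[k], fill = FALSE)
  out
}

#' Erode a binary mask with a disc structuring element
#'
#' Defined by duality with [dilate_mask()]; pixels outside the frame are
#' treated as background.
#'
#' @inheritParams dilate_mask
#' @return Logical matrix.
#' @export
erode_mask <- function(m, r) {
  stopifnot(is.matrix(m))
  if (r <= 0) return(m)
  !dilate_mask(!m, r)
}
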