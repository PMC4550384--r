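#' Global threshold of a single-channel image
#'
#' `method = "otsu"` returns the threshold maximizing the between-class
#' variance of the split into background (`<= t`) and foreground (`> t`),
#' computed exactly over the image's empirical intensity distribution
#' (every distinct intensity is a candidate); ties take the lowest
#' candidate.  `method = "fixed"` echoes `fixed_value`.
#'
#' A constant image admits no split: the constant is returned with a
#' warning (documented degenerate-image fallback).
#'
#' @param img Numeric matrix (nonempty).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Threshold to echo when `method = "fixed"`.
#' @return A single threshold value, within the image's intensity range.
#' @examples
#' img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
#' global_threshold(img)
#' @export
global_threshold <- function(img, method = c("otsu", "fixed"),
                             fixed_value = NULL) {
  method <- match.arg(method)
  if (length(img) == 0L) stop("image is empty", call. = FALSE)
  if (method == "fixed") {
    if (is.null(fixed_value))
      stop("fixed_value required for method 'fixed'", call. = FALSE)
    return(fixed_value)
  }
  v <- sort(as.numeric(img))
  u <- unique(v)
  if (length(u) == 1L) {
    warning("degenerate image: constant intensity, returning the constant")
    return(u)
  }
  n <- length(v)
  cnt <- tabulate(match(v, u), nbins = length(u))
  n0 <- cumsum(cnt)
  s0 <- cumsum(cnt * u)
  total <- s0[length(u)]
  # candidate thresholds: all but the largest distinct value
  i <- seq_len(length(u) - 1L)
  w0 <- n0[i] / n
  mu0 <- s0[i] / n0[i]
  mu1 <- (total - s0[i]) / (n - n0[i])
  bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
  u[i][which.max(bcv)]
}
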