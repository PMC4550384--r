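# Shared low-level matrix helpers.

# Translate a matrix by (dy, dx); vacated cells take `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

# 5-point Laplacian with reflecting (zero-flux) boundaries; conserves the
# matrix sum exactly.
laplacian_reflect <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  up + down + left + right - 4 * m
}
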