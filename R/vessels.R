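#' Generate a synthetic tumor vessel network
#'
#' Draws vessel centerlines as random walks through the tumor region:
#' each vessel enters at a random point on the tumor boundary, heads
#' toward the interior, and meanders with per-step angular noise
#' controlled by `tortuosity` until it exits the tumor or reaches the
#' maximum length.  When `area_fraction` is given, vessels are added
#' until the rasterized vessel mask covers at least that fraction of the
#' tumor region.
#'
#' @param cfg A [scene_config()].
#' @param n_vessels Number of vessels (>= 1) when `area_fraction` is
#'   `NULL`; otherwise a scale for the cap on added vessels
#'   (`10 * n_vessels`).
#' @param tortuosity Standard deviation (radians) of the per-step heading
#'   change; 0 gives straight segments.
#' @param radius_px Vessel radius in pixels (> 0).
#' @param area_fraction Optional target fraction of the tumor region to
#'   be covered by the rasterized vessel mask (e.g. 0.10).
#' @param step_px Centerline step length in pixels.
#' @param seed Integer seed (default taken from `cfg`).
#' @return An object of class `vessel_network`: a list with `segments`
#'   (each a list with `path` n x 2 matrix of (row, col) pixel coords,
#'   `radius`, `perfused`) and the `frame_shape`.
#' @export
generate_vessel_network <- function(cfg, n_vessels = 8L, tortuosity = 0.25,
                                    radius_px = 2, area_fraction = NULL,
                                    step_px = 2, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scene_config"), n_vessels >= 1L, radius_px > 0)
  if (!is.null(seed)) set.seed(seed)
  tumor <- tumor_region_mask(cfg)
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  cy <- cfg$tumor_center_frac[1] * nr; cx <- cfg$tumor_center_frac[2] * nc
  ay <- cfg$tumor_axes_frac[1] * nr; ax <- cfg$tumor_axes_frac[2] * nc
  tumor_area <- sum(tumor)
  max_len <- ceiling(2 * sqrt(ay^2 + ax^2) / step_px)

  walk_one <- function(cap = max_len) {
    phi <- stats::runif(1, 0, 2 * pi)
    start <- c(cy + ay * sin(phi), cx + ax * cos(phi))
    # initial heading: inward toward a random interior point
    aim_phi <- stats::runif(1, 0, 2 * pi)
    aim_r <- sqrt(stats::runif(1)) * 0.6
    aim <- c(cy + aim_r * ay * sin(aim_phi), cx + aim_r * ax * cos(aim_phi))
    theta <- atan2(aim[1] - start[1], aim[2] - start[2])
    cap <- max(3L, min(cap, max_len))
    path <- matrix(NA_real_, cap, 2)
    pos <- start
    n <- 0L
    repeat {
      n <- n + 1L
      path[n, ] <- pos
      if (n >= cap) break
      theta <- theta + stats::rnorm(1, 0, tortuosity)
      pos <- pos + step_px * c(sin(theta), cos(theta))
      r <- round(pos[1]); c <- round(pos[2])
      inside <- r >= 1 && r <= nr && c >= 1 && c <= nc && tumor[r, c]
      if (n > 2L && !inside) break
    }
    list(path = path[seq_len(n), , drop = FALSE], radius = radius_px,
         perfused = TRUE)
  }

  if (is.null(area_fraction)) {
    segments <- lapply(seq_len(n_vessels), function(i) walk_one())
  } else {
    # grow the network one vessel at a time, capping each new vessel's
    # length by the remaining target area so the final coverage lands
    # close to the request
    px_per_step <- 2 * ceiling(radius_px) * step_px
    segments <- list()
    net <- structure(list(segments = segments,
                          frame_shape = cfg$frame_shape),
                     class = "vessel_network")
    frac <- 0
    while (frac < area_fraction - 0.005 &&
           length(segments) < 10L * n_vessels) {
      remaining_px <- (area_fraction - frac) * tumor_area
      cap <- ceiling(remaining_px / px_per_step) + 2L
      segments[[length(segments) + 1L]] <- walk_one(cap)
      net$segments <- segments
      frac <- sum(rasterize_vessels(net) & tumor) / tumor_area
    }
  }
  structure(list(segments = segments, frame_shape = cfg$frame_shape),
            class = "vessel_network")
}

#' Rasterize a vessel network into a binary mask
#'
#' Stamps a disc of the segment radius at every centerline point.
#'
#' @param net A `vessel_network`.
#' @param perfused_only Keep only segments flagged as perfused.
#' @return Logical matrix of the scene's frame shape.
#' @export
rasterize_vessels <- function(net, perfused_only = FALSE) {
  stopifnot(inherits(net, "vessel_network"))
  nr <- net$frame_shape[1]; nc <- net$frame_shape[2]
  mask <- matrix(FALSE, nr, nc)
  for (seg in net$segments) {
    if (perfused_only && !isTRUE(seg$perfused)) next
    r <- seg$radius
    off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
    off <- off[off$dy^2 + off$dx^2 <= r^2, , drop = FALSE]
    pts <- round(seg$path)
    rows <- outer(pts[, 1], off$dy, `+`)
    cols <- outer(pts[, 2], off$dx, `+`)
    ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
    mask[cbind(rows[ok], cols[ok])] <- TRUE
  }
  mask
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("Vessel network: %d segment(s) on a %d x %d frame\n",
              length(x$segments), x$frame_shape[1], x$frame_shape[2]))
  invisible(x)
}
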