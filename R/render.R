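#' Multichannel time-lapse image stack
#'
#' @param frames 4-D numeric array `rows x cols x channels x frames` of
#'   nonnegative intensities.
#' @param channel_roles Named integer vector mapping channel roles to
#'   channel indices.
#' @param timestamps_s Strictly increasing frame times in seconds.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, channel_roles, timestamps_s) {
  stopifnot(is.array(frames), length(dim(frames)) == 4L)
  if (any(frames < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (length(timestamps_s) != dim(frames)[4])
    stop("timestamps must match the number of frames", call. = FALSE)
  if (any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (max(channel_roles) > dim(frames)[3])
    stop("channel role index out of range", call. = FALSE)
  structure(list(frames = frames, channel_roles = channel_roles,
                 timestamps_s = as.numeric(timestamps_s)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Image stack: %d x %d px, %d channel(s) [%s], %d frames\n",
              d[1], d[2], d[3],
              paste(names(x$channel_roles), collapse = ", "), d[4]))
  invisible(x)
}

#' Extract one channel of a stack as a rows x cols x frames array
#'
#' @param stack An [image_stack()].
#' @param role Channel role name (e.g. `"albumin"`) or channel index.
#' @return 3-D numeric array.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "image_stack"))
  idx <- if (is.character(role)) {
    if (!role %in% names(stack$channel_roles))
      stop(sprintf("channel role '%s' not present in stack", role),
           call. = FALSE)
    stack$channel_roles[[role]]
  } else as.integer(role)
  stack$frames[, , idx, , drop = FALSE][, , 1L, ]
}

#' Render a simulated tracer scene into a noisy image stack
#'
#' Composes the three channels from the ground-truth scene: the tumor
#' channel carries a fixed textured signal on the tumor region, the
#' dextran channel the vessel network, and the albumin channel the
#' intravascular concentration on the vessel mask plus the extravascular
#' field.  Signal-dependent (variance `photon_scale * I`) and additive
#' read noise are then applied, with an optional rigid sinusoidal
#' respiration jitter (rounded to whole pixels).
#'
#' @param scene A `tracer_scene` from [simulate_tracer()].
#' @param noise An [acquisition_noise()]; with all parameters zero, pixel
#'   values equal the scene concentrations (plus the constant background
#'   and fixed texture) exactly.
#' @param background Constant background offset added to every channel
#'   (default 10 intensity units).
#' @param tumor_level Mean tumor-channel signal above background.
#' @param vessel_level Dextran-channel vessel signal above background.
#' @param seed Integer seed for the noise draws (default from the scene's
#'   config).
#' @return An [image_stack()] with attribute `"jitter"`: the injected
#'   per-frame (dy, dx) shifts.
#' @export
render_timelapse <- function(scene, noise = acquisition_noise(),
                             background = 10, tumor_level = 60,
                             vessel_level = 80, seed = scene$cfg$seed) {
  stopifnot(inherits(scene, "tracer_scene"),
            inherits(noise, "acquisition_noise"))
  if (!is.null(seed)) set.seed(seed + 1L)
  cfg <- scene$cfg
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  nf <- cfg$n_frames
  roles <- cfg$channel_roles
  times <- scene$times

  # fixed low-contrast texture gives the tumor channel registration features
  tex <- 1 + 0.25 * outer(sin(2 * pi * seq_len(nr) / 41),
                          sin(2 * pi * seq_len(nc) / 29))
  tumor_img <- background + tumor_level * tex * scene$tumor_mask
  dextran_img <- background + vessel_level * scene$vessel_mask

  jit <- matrix(0L, nf, 2)
  if (noise$jitter_amplitude_px > 0) {
    ph <- 2 * pi * times / noise$jitter_period_s
    jit[, 1] <- as.integer(round(noise$jitter_amplitude_px * sin(ph)))
    jit[, 2] <- as.integer(round(0.6 * noise$jitter_amplitude_px *
                                   sin(ph + pi / 3)))
  }

  frames <- array(0, dim = c(nr, nc, 3L, nf))
  for (i in seq_len(nf)) {
    alb <- background + scene$c_vasc[i] * scene$vessel_mask +
      scene$extravascular[, , i]
    ch <- array(0, dim = c(nr, nc, 3L))
    ch[, , roles[["tumor"]]] <- tumor_img
    ch[, , roles[["dextran"]]] <- dextran_img
    ch[, , roles[["albumin"]]] <- alb
    if (any(jit[i, ] != 0))
      for (j in 1:3)
        ch[, , j] <- shift_matrix(ch[, , j], jit[i, 1], jit[i, 2],
                                  fill = background)
    if (noise$photon_scale > 0 || noise$read_sigma > 0) {
      sd_px <- sqrt(noise$photon_scale * ch + noise$read_sigma^2)
      ch <- ch + stats::rnorm(length(ch)) * sd_px
      ch[ch < 0] <- 0
    }
    frames[, , , i] <- ch
  }
  out <- image_stack(frames, roles, times)
  attr(out, "jitter") <- jit
  out
}
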