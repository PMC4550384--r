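#' Simulate temperature-dependent tracer extravasation
#'
#' Two-compartment kinetics driven by the tumor temperature trace.  The
#' intravascular concentration obeys
#' `dC/dt = -(clearance + k(T)) * C`, with `k(T)` from
#' [permeability_at()].  Tracer crossing the vessel wall is deposited at
#' the perfused-vessel boundary pixels and then spreads through the
#' interstitium by isotropic diffusion (zero-flux frame boundaries).
#' Within each frame interval the permeability is held at its value at
#' the interval start and the compartment exchange is integrated exactly,
#' so total tracer (intravascular + extravascular + cleared) is conserved
#' to machine precision.
#'
#' @param net A `vessel_network` from [generate_vessel_network()].
#' @param kin A [tracer_kinetics()].
#' @param trace A [temperature_trace()] covering all frame times (first
#'   probe is used as the tumor temperature).
#' @param cfg A [scene_config()].
#' @return An object of class `tracer_scene`: ground-truth `tumor_mask`
#'   and `vessel_mask`, per-frame intravascular concentration `c_vasc`,
#'   cleared amount `cleared`, permeability series `k`, the extravascular
#'   concentration field stack `extravascular` (rows x cols x frames),
#'   per-frame extravascular totals `extravascular_total`, and `times`.
#' @export
simulate_tracer <- function(net, kin, trace, cfg) {
  stopifnot(inherits(net, "vessel_network"), inherits(kin, "tracer_kinetics"),
            inherits(trace, "temperature_trace"),
            inherits(cfg, "scene_config"))
  times <- scene_times(cfg)
  if (min(trace$times) > min(times) || max(trace$times) < max(times))
    stop("temperature trace does not cover all frame times", call. = FALSE)

  tumor <- tumor_region_mask(cfg)
  vessel <- rasterize_vessels(net, perfused_only = TRUE)
  n_vessel_px <- sum(vessel)
  if (n_vessel_px == 0L) stop("vessel mask is empty", call. = FALSE)
  # deposition sites: pixels adjacent to (but outside) perfused vessels
  boundary <- dilate_mask(vessel, 1) & !vessel
  bnd_idx <- which(boundary)

  nf <- cfg$n_frames
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  extv <- array(0, dim = c(nr, nc, nf))
  c_vasc <- numeric(nf); cleared <- numeric(nf)
  k_series <- permeability_at(kin, trace_temperature_at(trace, times))
  c_vasc[1] <- kin$c_vasc0
  fld <- matrix(0, nr, nc)

  for (i in seq_len(nf - 1L)) {
    dt <- times[i + 1L] - times[i]
    k <- k_series[i]
    cl <- kin$clearance_rate
    tot <- k + cl
    if (tot > 0) {
      f <- exp(-tot * dt)
      released <- c_vasc[i] * (1 - f)          # per vessel pixel
      amt_out <- released * n_vessel_px        # total leaving the vessels
      extrav_amt <- amt_out * k / tot
      cleared[i + 1L] <- cleared[i] + amt_out * cl / tot
      c_vasc[i + 1L] <- c_vasc[i] * f
    } else {
      extrav_amt <- 0
      cleared[i + 1L] <- cleared[i]
      c_vasc[i + 1L] <- c_vasc[i]
    }
    if (extrav_amt > 0)
      fld[bnd_idx] <- fld[bnd_idx] + extrav_amt / length(bnd_idx)
    if (kin$diffusion_coeff > 0) {
      m <- max(1L, ceiling(kin$diffusion_coeff * dt / 0.2))
      tau <- kin$diffusion_coeff * dt / m
      for (s in seq_len(m)) fld <- fld + tau * laplacian_reflect(fld)
    }
    extv[, , i + 1L] <- fld
  }

  structure(list(tumor_mask = tumor, vessel_mask = vessel,
                 c_vasc = c_vasc, cleared = cleared, k = k_series,
                 extravascular = extv,
                 extravascular_total = apply(extv, 3, sum),
                 n_vessel_px = n_vessel_px, times = times, cfg = cfg,
                 kinetics = kin),
            class = "tracer_scene")
}

#' @export
print.tracer_scene <- function(x, ...) {
  cat(sprintf(
    paste0("Tracer scene: %d frames (%.0f s), %d vessel px, ",
           "final extravascular total %.3g (%.1f%% of injected)\n"),
    length(x$times), max(x$times), x$n_vessel_px,
    x$extravascular_total[length(x$times)],
    100 * x$extravascular_total[length(x$times)] /
      (x$kinetics$c_vasc0 * x$n_vessel_px)))
  invisible(x)
}

#' Tracer mass balance of a simulated scene
#'
#' @param scene A `tracer_scene`.
#' @return Numeric vector, per frame: the relative deviation of
#'   intravascular + extravascular + cleared tracer from the injected
#'   total.
#' @export
mass_balance_error <- function(scene) {
  stopifnot(inherits(scene, "tracer_scene"))
  injected <- scene$kinetics$c_vasc0 * scene$n_vessel_px
  if (injected == 0) return(rep(0, length(scene$times)))
  total <- scene$c_vasc * scene$n_vessel_px + scene$extravascular_total +
    scene$cleared
  abs(total - injected) / injected
}
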