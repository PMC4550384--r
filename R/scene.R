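#' Configuration of a synthetic intravital-microscopy scene
#'
#' Describes the geometry and acquisition parameters of a generated
#' three-channel time-lapse: a tumor region constitutively expressing a
#' red fluorophore, a vessel network carried on the dextran channel, and a
#' circulating tracer (albumin channel) whose extravasation is simulated.
#'
#' @param frame_shape Integer vector `c(rows, cols)` in pixels
#'   (default `c(512, 512)`).
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Time between frames in seconds.
#' @param pixel_size_um Pixel size in micrometers (metadata only).
#' @param channel_roles Named integer vector mapping roles
#'   (`tumor`, `dextran`, `albumin`) to channel indices.
#' @param tumor_axes_frac Semi-axes of the elliptical tumor region as
#'   fractions of the frame (rows, cols).
#' @param tumor_center_frac Center of the tumor ellipse as fractions of
#'   the frame.
#' @param seed Integer seed; mandatory for reproducible generation.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(frame_shape = c(512L, 512L), n_frames = 60L,
                         frame_interval_s = 5, pixel_size_um = 1.24,
                         channel_roles = c(tumor = 1L, dextran = 2L,
                                           albumin = 3L),
                         tumor_axes_frac = c(0.36, 0.40),
                         tumor_center_frac = c(0.5, 0.5),
                         seed = 1L) {
  frame_shape <- as.integer(frame_shape)
  stopifnot(length(frame_shape) == 2L, all(frame_shape > 0L),
            n_frames >= 2L, frame_interval_s > 0,
            all(c("tumor", "dextran", "albumin") %in% names(channel_roles)))
  structure(list(frame_shape = frame_shape, n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 channel_roles = channel_roles,
                 tumor_axes_frac = tumor_axes_frac,
                 tumor_center_frac = tumor_center_frac,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Frame times of a scene
#' @param cfg A [scene_config()].
#' @return Numeric vector of frame timestamps in seconds, starting at 0.
#' @export
scene_times <- function(cfg) {
  (seq_len(cfg$n_frames) - 1) * cfg$frame_interval_s
}

#' Ground-truth tumor region of a scene
#'
#' @param cfg A [scene_config()].
#' @return Logical matrix marking the elliptical tumor region.
#' @export
tumor_region_mask <- function(cfg) {
  nr <- cfg$frame_shape[1]; nc <- cfg$frame_shape[2]
  cy <- cfg$tumor_center_frac[1] * nr; cx <- cfg$tumor_center_frac[2] * nc
  ay <- cfg$tumor_axes_frac[1] * nr; ax <- cfg$tumor_axes_frac[2] * nc
  row_d <- (seq_len(nr) - cy) / ay
  col_d <- (seq_len(nc) - cx) / ax
  outer(row_d^2, col_d^2, `+`) <= 1
}

#' Temperature-dependent tracer kinetics
#'
#' Parameters of the two-compartment (intravascular/extravascular)
#' extravasation model.  The permeability is modulated by temperature:
#' baseline `permeability_base` below 39 degC, multiplied by
#' `enhancement_factor` in the mild-hyperthermia band 39-41 degC, declining
#' linearly above 41 degC, and zero at or above `shutdown_temp_c` where
#' vessel coagulation and shutdown occur.
#'
#' @param c_vasc0 Initial intravascular tracer concentration (arbitrary
#'   intensity units per vessel pixel).
#' @param clearance_rate Systemic clearance rate (1/s).
#' @param permeability_base Baseline vessel-wall transfer rate k0 (1/s).
#' @param enhancement_factor Multiplier alpha (>= 1) applied within the
#'   39-41 degC band.
#' @param shutdown_temp_c Temperature (degC) of complete vessel shutdown
#'   (default 44).
#' @param diffusion_coeff Extravascular (interstitial) diffusion
#'   coefficient in px^2/s.
#' @return An object of class `tracer_kinetics`.
#' @export
tracer_kinetics <- function(c_vasc0 = 200, clearance_rate = 1e-4,
                            permeability_base = 2e-5,
                            enhancement_factor = 100,
                            shutdown_temp_c = 44, diffusion_coeff = 0.5) {
  stopifnot(c_vasc0 >= 0, clearance_rate >= 0, permeability_base >= 0,
            enhancement_factor >= 1, diffusion_coeff >= 0)
  structure(list(c_vasc0 = c_vasc0, clearance_rate = clearance_rate,
                 permeability_base = permeability_base,
                 enhancement_factor = enhancement_factor,
                 shutdown_temp_c = shutdown_temp_c,
                 diffusion_coeff = diffusion_coeff),
            class = "tracer_kinetics")
}

#' Vessel permeability as a function of temperature
#'
#' Piecewise temperature response: baseline `k0` below 39 degC, enhanced
#' `alpha * k0` across the mild-hyperthermia band 39-41 degC (a documented
#' jump at the 39 degC band edge), a linear decline from `alpha * k0` at
#' 41 degC to zero at `shutdown_temp_c`, and zero at or above shutdown
#' (vessel coagulation).
#'
#' @param kin A [tracer_kinetics()].
#' @param temp_c Temperature(s) in degC (finite); vectorized.
#' @return Permeability in 1/s.
#' @examples
#' kin <- tracer_kinetics(permeability_base = 1e-4, enhancement_factor = 10)
#' permeability_at(kin, c(37, 40, 44))
#' @export
permeability_at <- function(kin, temp_c) {
  stopifnot(inherits(kin, "tracer_kinetics"), all(is.finite(temp_c)))
  k0 <- kin$permeability_base
  ka <- kin$enhancement_factor * k0
  ts <- kin$shutdown_temp_c
  k <- rep(k0, length(temp_c))
  band <- temp_c >= 39 & temp_c <= 41
  k[band] <- ka
  decl <- temp_c > 41 & temp_c < ts
  k[decl] <- ka * (ts - temp_c[decl]) / (ts - 41)
  k[temp_c >= ts] <- 0
  k
}

#' Acquisition-noise and motion model
#'
#' @param photon_scale Scale of the signal-dependent (Poisson-like) noise:
#'   the photon variance contribution at intensity `I` is
#'   `photon_scale * I`.
#' @param read_sigma Standard deviation of additive Gaussian read noise.
#' @param jitter_amplitude_px Amplitude of the sinusoidal respiration
#'   jitter in pixels (0 disables).
#' @param jitter_period_s Jitter period in seconds.
#' @return An object of class `acquisition_noise`.
#' @export
acquisition_noise <- function(photon_scale = 0.5, read_sigma = 2,
                              jitter_amplitude_px = 0, jitter_period_s = 2) {
  stopifnot(photon_scale >= 0, read_sigma >= 0, jitter_amplitude_px >= 0,
            jitter_period_s > 0)
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 jitter_amplitude_px = jitter_amplitude_px,
                 jitter_period_s = jitter_period_s),
            class = "acquisition_noise")
}
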