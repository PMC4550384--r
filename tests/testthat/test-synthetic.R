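test_that("vessel network generation is reproducible and controllable", {
  cfg <- scene_config(frame_shape = c(128L, 128L), n_frames = 5L, seed = 1L)
  n1 <- generate_vessel_network(cfg, n_vessels = 4L)
  n2 <- generate_vessel_network(cfg, n_vessels = 4L)
  expect_identical(n1, n2)
  # a single vessel with zero tortuosity is a straight segment
  straight <- generate_vessel_network(cfg, n_vessels = 1L, tortuosity = 0)
  expect_length(straight$segments, 1L)
  p <- straight$segments[[1]]$path
  expect_gt(nrow(p), 2L)
  d <- diff(p)
  cross <- d[-1, 1] * d[1, 2] - d[-1, 2] * d[1, 1]
  expect_true(all(abs(cross) < 1e-9))
})

test_that("requested vessel area fraction is met within 0.03", {
  cfg <- scene_config(frame_shape = c(128L, 128L), n_frames = 5L, seed = 2L)
  for (seed in 1:5) {
    cfg$seed <- seed
    net <- generate_vessel_network(cfg, area_fraction = 0.10)
    frac <- sum(rasterize_vessels(net) & tumor_region_mask(cfg)) /
      sum(tumor_region_mask(cfg))
    expect_gt(frac, 0.07)
    expect_lt(frac, 0.13)
  }
})

test_that("permeability follows the piecewise temperature response", {
  kin <- tracer_kinetics(permeability_base = 1e-4, enhancement_factor = 10,
                         shutdown_temp_c = 44)
  k0 <- 1e-4
  expect_equal(permeability_at(kin, 37), k0)
  expect_equal(permeability_at(kin, 30), k0)
  expect_equal(permeability_at(kin, 40), 10 * k0)   # enhancement band
  expect_equal(permeability_at(kin, 39), 10 * k0)
  expect_equal(permeability_at(kin, 41), 10 * k0)
  expect_equal(permeability_at(kin, 44), 0)         # vessel shutdown
  expect_equal(permeability_at(kin, 48), 0)
  # linear decline between 41 and shutdown, continuous at both ends
  expect_equal(permeability_at(kin, 42.5), 5 * k0)
  expect_equal(permeability_at(kin, 41 + 1e-9), 10 * k0, tolerance = 1e-6)
  expect_lt(permeability_at(kin, 44 - 1e-6), 1e-9)
  # vectorization
  expect_equal(permeability_at(kin, c(37, 40, 44)), c(k0, 10 * k0, 0))
})

test_that("no extravasation without permeability", {
  scen <- tiny_scenario(seed = 4)
  scen$kinetics <- tracer_kinetics(permeability_base = 0,
                                   enhancement_factor = 50)
  scen$trace <- temperature_trace(c(0, 1000), c(37, 37))
  g <- generate_scene(scen)
  expect_true(all(g$scene$extravascular == 0))
  expect_true(all(g$scene$extravascular_total == 0))
})

test_that("one-compartment closed form is reproduced exactly", {
  scen <- tiny_scenario(seed = 5, n_frames = 20L)
  k <- 2e-3
  scen$kinetics <- tracer_kinetics(c_vasc0 = 100, clearance_rate = 0,
                                   permeability_base = k,
                                   enhancement_factor = 1,
                                   diffusion_coeff = 0)
  scen$trace <- temperature_trace(c(0, 1000), c(37, 37))
  g <- generate_scene(scen)
  tt <- g$scene$times
  expected <- 100 * g$scene$n_vessel_px * (1 - exp(-k * tt))
  expect_equal(g$scene$extravascular_total, expected, tolerance = 1e-10)
})

test_that("enhancement-factor scaling matches a fine-step ODE oracle", {
  run_total <- function(alpha) {
    scen <- tiny_scenario(seed = 6, n_frames = 15L)
    scen$kinetics <- tracer_kinetics(c_vasc0 = 100, clearance_rate = 5e-4,
                                     permeability_base = 1e-4,
                                     enhancement_factor = alpha,
                                     diffusion_coeff = 0.5)
    scen$trace <- temperature_trace(c(0, 1000), c(40, 40))
    g <- generate_scene(scen)
    tail(g$scene$extravascular_total, 1)
  }
  oracle_total <- function(alpha, t_end, nv) {
    k <- alpha * 1e-4; cl <- 5e-4
    dt <- 0.01
    C <- 100; E <- 0
    for (i in seq_len(t_end / dt)) {
      E <- E + k * C * dt
      C <- C - (k + cl) * C * dt
    }
    E * nv
  }
  scen <- tiny_scenario(seed = 6, n_frames = 15L)
  net <- generate_vessel_network(scen$scene, area_fraction = 0.10)
  nv <- sum(rasterize_vessels(net))
  t_end <- (15 - 1) * 5
  r_sim <- run_total(5) / run_total(1)
  r_ora <- oracle_total(5, t_end, nv) / oracle_total(1, t_end, nv)
  expect_equal(r_sim, r_ora, tolerance = 1e-3)
})

test_that("tracer mass is conserved and extravasation is monotone", {
  for (seed in 1:3) {
    scen <- tiny_scenario(seed = seed, n_frames = 20L)
    g <- generate_scene(scen)
    expect_lt(max(mass_balance_error(g$scene)), 1e-6)
    tot <- g$scene$extravascular_total
    expect_true(all(diff(tot) >= 0))
    # strictly increasing while k(T) * C_vasc > 0
    active <- (g$scene$k * g$scene$c_vasc)[-length(tot)] > 0
    expect_true(all(diff(tot)[active] > 0))
  }
})

test_that("noise-free render equals the scene concentrations exactly", {
  scen <- tiny_scenario(seed = 7, n_frames = 10L)
  g <- generate_scene(scen, background = 10)
  alb <- get_channel(g$stack, "albumin")
  for (i in c(1, 5, 10)) {
    expected <- 10 + g$scene$c_vasc[i] * g$scene$vessel_mask +
      g$scene$extravascular[, , i]
    expect_equal(alb[, , i], expected)
  }
})

test_that("photon noise variance scales with photon_scale", {
  scen1 <- tiny_scenario(seed = 8, n_frames = 4L,
                         noise = acquisition_noise(1, 0, 0))
  scen2 <- tiny_scenario(seed = 8, n_frames = 4L,
                         noise = acquisition_noise(2, 0, 0))
  g1 <- generate_scene(scen1)
  g2 <- generate_scene(scen2)
  # uniform background region: outside the tumor and clear of vessels
  outside <- !g1$scene$tumor_mask & !dilate_mask(g1$scene$vessel_mask, 4)
  v1 <- var(as.numeric(get_channel(g1$stack, "albumin")[, , 2][outside]))
  v2 <- var(as.numeric(get_channel(g2$stack, "albumin")[, , 2][outside]))
  expect_gt(sum(outside), 1e4 / 4)
  expect_equal(v2 / v1, 2, tolerance = 0.1)
})

test_that("rendered jitter is recovered by cross-correlation", {
  scen <- tiny_scenario(seed = 9, n_frames = 16L,
                        noise = acquisition_noise(0, 0, 3, 2.7),
                        frame_interval_s = 0.4)
  g <- generate_scene(scen)
  inj <- attr(g$stack, "jitter")
  inj <- sweep(inj, 2, inj[1, ])  # shifts relative to the reference frame
  est <- estimate_shifts(g$stack)
  expect_true(any(inj != 0))
  expect_lte(max(abs(est - inj)), 0.5)
})

test_that("default scenarios encode treated vs control contrast", {
  scen <- default_scenarios(frame_shape = c(96L, 96L), seed = 11)
  # treated enters the 39-41 enhancement band during exposure
  k_series <- permeability_at(scen$treated$kinetics,
                              trace_temperature_at(scen$treated$trace,
                                                   seq(0, 600, by = 5)))
  k0 <- scen$treated$kinetics$permeability_base
  alpha <- scen$treated$kinetics$enhancement_factor
  expect_true(any(k_series == alpha * k0))
  # control stays at baseline permeability
  kc <- permeability_at(scen$control$kinetics,
                        trace_temperature_at(scen$control$trace,
                                             seq(0, 1800, by = 15)))
  expect_true(all(kc == k0))
  # control extravascular accumulation is < 10% of treated
  gt <- generate_scene(scen$treated)
  gc <- generate_scene(scen$control)
  expect_lt(tail(gc$scene$extravascular_total, 1),
            0.1 * tail(gt$scene$extravascular_total, 1))
  # bit-for-bit reproducibility under a fixed seed
  gt2 <- generate_scene(scen$treated)
  expect_identical(gt$stack$frames, gt2$stack$frames)
})
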