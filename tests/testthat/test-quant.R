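# Brute-force oracles for the mask pipeline primitives.

otsu_oracle <- function(img) {
  v <- as.numeric(img)
  u <- sort(unique(v))
  best <- -Inf; best_t <- u[1]
  for (t in u[-length(u)]) {
    bg <- v[v <= t]; fg <- v[v > t]
    w0 <- length(bg) / length(v)
    bcv <- w0 * (1 - w0) * (mean(bg) - mean(fg))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

paf_oracle <- function(img, thr) {
  n <- 0L
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    if (img[i, j] > thr) n <- n + 1L
  n / length(img)
}

test_that("global threshold separates a two-level image and echoes fixed values", {
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  thr <- global_threshold(img)
  expect_gte(thr, 10); expect_lt(thr, 200)
  expect_identical(global_threshold(img, "fixed", fixed_value = 50), 50)
  expect_warning(t0 <- global_threshold(matrix(7, 4, 4)), "degenerate")
  expect_equal(t0, 7)
})

test_that("Otsu threshold equals the exhaustive between-class-variance search", {
  set.seed(101)
  for (rep in 1:40) {
    n_low <- sample(20:200, 1)
    img <- matrix(c(rnorm(n_low, 30, 6), rnorm(256 - n_low, 120, 15)), 16, 16)
    expect_identical(global_threshold(img), otsu_oracle(img))
  }
  # integer-valued images with ties
  for (rep in 1:10) {
    img <- matrix(sample(0:20, 64, replace = TRUE), 8, 8)
    expect_identical(global_threshold(img), otsu_oracle(img))
  }
})

test_that("tumor mask recovers a bright disc and fills small holes", {
  nr <- 64
  disc <- outer((1:nr - 32)^2, (1:nr - 32)^2, `+`) <= 20^2
  img <- 10 + 90 * disc
  frames <- array(img, dim = c(nr, nr, 1L, 2L))
  st <- image_stack(frames, c(tumor = 1L), c(0, 1))
  m <- tumor_mask(st)
  # exact within a 1-px boundary band
  band <- dilate_mask(disc, 1.5) & !erode_mask(disc, 1.5)
  expect_true(all(xor(m$pixels, disc) <= band))
  # a small interior hole (< structuring element) is removed by the closing
  holed <- img
  holed[32, 32:33] <- 10
  st2 <- image_stack(array(holed, dim = c(nr, nr, 1L, 2L)),
                     c(tumor = 1L), c(0, 1))
  m2 <- tumor_mask(st2)
  expect_true(all(m2$pixels[32, 32:33]))
  expect_equal(m2$morphology_trace, c("dilate(r=2)", "erode(r=2)"))
  expect_error(tumor_mask(stack_from_frames(img, img)), "tumor")
})

test_that("masks recover generator ground truth on noise-free scenes", {
  scen <- tiny_scenario(seed = 12, n_frames = 15L, shape = c(128L, 128L))
  g <- generate_scene(scen)
  tm <- tumor_mask(g$stack)
  expect_gte(mask_jaccard(tm, g$scene$tumor_mask), 0.9)
  vm <- vessel_mask(g$stack, "dextran")
  # vessels only carry signal at baseline: mask within a 1-px boundary band
  gt <- g$scene$vessel_mask
  band <- dilate_mask(gt, 1.5) & !erode_mask(gt, 1.5)
  expect_gte(mask_jaccard(vm, gt), 0.75)
  expect_lt(sum(xor(vm$pixels, gt) & !band) / sum(gt), 0.05)
  # noisy default: tumor mask still matches ground truth
  gn <- generate_scene(tiny_scenario(seed = 12, n_frames = 15L,
                                     shape = c(128L, 128L),
                                     noise = acquisition_noise()))
  expect_gte(mask_jaccard(tumor_mask(gn$stack), gn$scene$tumor_mask), 0.9)
})

test_that("all-dark tracer channel yields an empty vessel mask", {
  dark <- matrix(0, 8, 8)
  st <- stack_from_frames(dark, dark)
  expect_warning(vm <- vessel_mask(st, "albumin"), "constant")
  expect_equal(sum(vm$pixels), 0L)
})

test_that("vessel-mask area is stable across frames at the baseline threshold", {
  scen <- tiny_scenario(seed = 13, n_frames = 12L, shape = c(128L, 128L),
                        noise = acquisition_noise())
  g <- generate_scene(scen)
  base <- vessel_mask(g$stack, "dextran", frame_idx = 1L)
  areas <- vapply(seq_len(12), function(i)
    sum(vessel_mask(g$stack, "dextran", frame_idx = i, method = "fixed",
                    fixed_value = base$threshold_value)$pixels), numeric(1))
  expect_true(all(abs(areas / areas[1] - 1) <= 0.1))
})

test_that("extravascular mask is exact set arithmetic", {
  set.seed(77)
  for (rep in 1:30) {
    tp <- matrix(runif(25) < 0.5, 5, 5)
    vp <- matrix(runif(25) < 0.4, 5, 5)
    tm <- binary_mask(tp); vm <- binary_mask(vp)
    em <- extravascular_mask(tm, vm)
    # per-pixel brute-force oracle
    for (i in 1:5) for (j in 1:5)
      expect_identical(em$pixels[i, j], tp[i, j] && !vp[i, j])
    # disjoint partition of the tumor
    expect_identical(sum(em$pixels) + sum(tp & vp), sum(tp))
    expect_true(all((em$pixels | (tp & vp)) == tp))
  }
  none <- binary_mask(matrix(FALSE, 5, 5))
  all_m <- binary_mask(matrix(TRUE, 5, 5))
  tm <- binary_mask(matrix(runif(25) < 0.5, 5, 5))
  expect_identical(extravascular_mask(tm, none)$pixels, tm$pixels)
  expect_equal(sum(extravascular_mask(tm, all_m)$pixels), 0L)
  expect_error(extravascular_mask(tm, binary_mask(matrix(TRUE, 4, 5))),
               "shape")
})

test_that("positive area fraction matches an explicit loop count", {
  expect_equal(paf(matrix(5, 8, 8), 10), 0)
  half <- matrix(c(rep(0, 32), rep(20, 32)), 8, 8)
  expect_equal(paf(half, 10), 0.5)
  set.seed(55)
  for (rep in 1:30) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(paf(img, 100), paf_oracle(img, 100))
  }
  # region-restricted variant
  reg <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(paf(img, 100, region = reg),
               mean(img[reg] > 100))
})

test_that("RTDI is a baseline-normalized region mean", {
  base <- matrix(10, 6, 6)
  st <- stack_from_frames(base, base, base)
  reg <- binary_mask(matrix(TRUE, 6, 6))
  expect_equal(rtdi_series(st, reg), rep(1, 3))
  # linear doubling of region intensity: final RTDI = 2
  st2 <- stack_from_frames(base, 1.5 * base, 2 * base)
  expect_equal(rtdi_series(st2, reg), c(1, 1.5, 2))
  expect_error(rtdi_series(st, binary_mask(matrix(FALSE, 6, 6))), "empty")
})

test_that("RAIF is the end/start window intensity ratio", {
  base <- matrix(10, 6, 6)
  reg <- binary_mask(matrix(TRUE, 6, 6))
  st <- stack_from_frames(base, base, base, base)
  expect_equal(raif(st, reg, window_start = 1, window_end = 4), 1)
  st3 <- stack_from_frames(base, base, 2 * base, 3 * base)
  expect_equal(raif(st3, reg, window_start = 1, window_end = 4), 3)
  expect_error(raif(st3, reg, window_start = 1:3, window_end = 3:4),
               "window")
  # replicate aggregation
  reps <- raif_replicates(list(st3, st3, st, st), reg,
                          window_start = 1, window_end = 4)
  expect_equal(reps$mean, 2)
  expect_equal(reps$sd, sd(c(3, 3, 1, 1)))
})

test_that("saturated pixels are excluded from intensity means", {
  img1 <- matrix(10, 6, 6)
  img2 <- matrix(10, 6, 6); img2[1:2, 1:2] <- 4095
  st <- stack_from_frames(img1, img2)
  reg <- binary_mask(matrix(TRUE, 6, 6))
  r <- rtdi_series(st, reg, saturation = 4095)
  expect_equal(r[2], 1)  # saturated pixels dropped, mean unchanged
})

test_that("jitter correction is identity on still stacks and reduces variance", {
  scen <- tiny_scenario(seed = 14, n_frames = 10L)
  g <- generate_scene(scen)
  expect_true(all(estimate_shifts(g$stack) == 0L))
  # featureless stack: warning and identity
  flat <- matrix(3, 16, 16)
  st <- image_stack(array(3, dim = c(16, 16, 1, 3)), c(tumor = 1L), 1:3)
  expect_warning(s0 <- estimate_shifts(st), "featureless")
  expect_true(all(s0 == 0L))
  # known sinusoidal jitter, with noise: corrected series is steadier
  scen2 <- tiny_scenario(seed = 15, n_frames = 24L, shape = c(128L, 128L),
                         noise = acquisition_noise(0.5, 2, 3, 2.7),
                         frame_interval_s = 0.4)
  g2 <- generate_scene(scen2)
  corr <- jitter_correct(g2$stack)
  inj <- attr(g2$stack, "jitter"); inj <- sweep(inj, 2, inj[1, ])
  expect_lte(max(abs(attr(corr, "shifts") - inj)), 0.5)
  tm <- tumor_mask(corr); vm <- vessel_mask(corr, "dextran")
  em <- extravascular_mask(tm, vm)
  v_un <- var(diff(rtdi_series(g2$stack, em, "albumin")))
  v_co <- var(diff(rtdi_series(corr, em, "albumin")))
  expect_lt(v_co, v_un)
})
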