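test_that("accessibility generator encodes the segment plan and is deterministic", {
  spec <- accessibility_spec("deep_V", noise_sd_fraction = 0)
  acc <- gen_accessibility_profile(spec)
  truth <- attr(acc, "ground_truth")$true_accessibility

  emb <- truth$true_accessibility_pct[truth$residue_index >= 94 &
                                        truth$residue_index <= 122]
  exp_n <- truth$true_accessibility_pct[truth$residue_index >= 80 &
                                          truth$residue_index <= 89]
  expect_true(all(emb <= 10))
  expect_true(all(exp_n >= 90))
  expect_equal(nrow(truth), 49)
  expect_match(attr(acc, "ground_truth")$note, "49")

  # same seed, even with noise, gives identical tables
  spec_n <- accessibility_spec("deep_V", noise_sd_fraction = 0.1, seed = 42L)
  expect_identical(gen_accessibility_profile(spec_n),
                   gen_accessibility_profile(spec_n))
})

test_that("open-shallow embedded profile is periodic at the helical pitch", {
  spec <- accessibility_spec("open_shallow", noise_sd_fraction = 0)
  truth <- attr(gen_accessibility_profile(spec), "ground_truth")$true_accessibility
  sub <- truth$true_accessibility_pct[truth$residue_index >= 94 &
                                        truth$residue_index <= 122]
  # independent sinusoid-fit oracle agrees with the injected 3.6-residue pitch
  expect_equal(oracle_dominant_period(sub), 3.6, tolerance = 0.05)
  ps <- periodicity_score(sub)
  expect_gte(ps$dominant_period, 3)
  expect_lte(ps$dominant_period, 4)
})

test_that("accessibility spec validates segment plans and conformations", {
  expect_error(accessibility_spec("sideways"), "arg")
  expect_error(
    accessibility_spec(segments = list(exposed_a = c(80L, 100L),
                                       embedded = c(99L, 128L))),
    "disjoint"
  )
  expect_error(gen_accessibility_profile(list(conformation = "deep_V")),
               "accessibility_spec")
})

test_that("saturation curve generator reproduces the closed-form model", {
  # at P = P_1/2 the amplitude is exactly half the unsaturated value
  c1 <- gen_saturation_curve(1, 10, 1.5, powers = 10)
  expect_equal(c1$amplitude, sqrt(10) / 2, tolerance = 1e-12)
  # direct evaluation away from P_1/2
  c2 <- gen_saturation_curve(2, 5, 1.0, powers = 20)
  expect_equal(c2$amplitude, 2 * sqrt(20) / 5, tolerance = 1e-12)
  # unsaturated limit: A / (I sqrt(P)) -> 1
  c3 <- gen_saturation_curve(3, 10, 1.2, powers = 1e-8)
  expect_equal(c3$amplitude / (3 * sqrt(1e-8)), 1, tolerance = 1e-6)
  # default grid is the attenuation series of a 200 mW source
  c4 <- gen_saturation_curve(1, 10, 1.5)
  expect_equal(range(c4$power_mW), c(0.2, 126.19), tolerance = 1e-4)
  expect_equal(nrow(c4), 15)
  # rejected inputs
  expect_error(gen_saturation_curve(1, -1, 1.5), "P_half")
  expect_error(gen_saturation_curve(1, 10, 1.5, powers = c(1, -2)), "powers")
  # determinism under noise
  expect_identical(gen_saturation_curve(1, 10, 1.5, noise_sd = 0.05, seed = 9L),
                   gen_saturation_curve(1, 10, 1.5, noise_sd = 0.05, seed = 9L))
})

test_that("hairpin structure generator is calibrated against the geometry module", {
  deep <- gen_hairpin_structure(hairpin_geometry_spec("deep_V"))
  obs_d <- membrane_observables(deep)
  expect_equal(obs_d$kink_depth_nm, 2.0, tolerance = 0.02)
  expect_equal(obs_d$tilt_deg, 80, tolerance = 0.01)
  expect_equal(obs_d$tip_distance_A, 20, tolerance = 0.01)

  shallow <- gen_hairpin_structure(hairpin_geometry_spec("open_shallow"))
  obs_s <- membrane_observables(shallow)
  expect_equal(obs_s$tip_distance_A, 36, tolerance = 0.7)
  expect_lt(abs(obs_s$kink_depth_nm), 0.02)
  expect_equal(obs_s$tilt_deg, 30, tolerance = 0.01)

  # the closed V opens up between the two states
  expect_lt(obs_d$opening_angle_deg, obs_s$opening_angle_deg)

  # a 90-degree request puts the principal axis orthogonal to the plane
  vert <- gen_hairpin_structure(hairpin_geometry_spec("deep_V", tilt_deg = 90))
  expect_equal(tilt_angle(vert), 90, tolerance = 1)

  # infeasible tip distance names the violated constraint
  expect_error(
    gen_hairpin_structure(hairpin_geometry_spec("deep_V", arm_tip_distance = 200)),
    "arm_tip_distance"
  )
})

test_that("umbrella sampler draws from the exact biased density", {
  kT <- kT_from_temperature(310)
  flat <- analytic_pmf("tabulated", xi = c(-2, 2), G = c(0, 0), domain = c(-2, 2))
  um <- gen_umbrella_samples(flat, centers = c(-0.5, 0, 0.5), k = 1000,
                             n_per_window = 4000, kT = kT, seed = 3L)
  for (w in 1:3) {
    xi <- um$xi_nm[um$window_id == w]
    ctr <- c(-0.5, 0, 0.5)[w]
    expect_lt(abs(mean(xi) - ctr), 4 * sqrt(kT / 1000 / 4000) + 1e-3)
    expect_lt(abs(stats::var(xi) - kT / 1000), 0.15 * kT / 1000)
  }

  # harmonic landscape + harmonic bias: product-of-Gaussians variance
  kap <- 50
  harm <- analytic_pmf("harmonic", kappa = kap)
  um2 <- gen_umbrella_samples(harm, centers = 0, k = 1000,
                              n_per_window = 20000, kT = kT, seed = 5L)
  expect_lt(abs(stats::var(um2$xi_nm) - kT / (kap + 1000)),
            0.1 * kT / (kap + 1000))

  # determinism and domain guard
  expect_identical(um, gen_umbrella_samples(flat, centers = c(-0.5, 0, 0.5),
                                            k = 1000, n_per_window = 4000,
                                            kT = kT, seed = 3L))
  expect_error(gen_umbrella_samples(flat, centers = 3), "domain")
})

test_that("umbrella samples pass a KS test against the analytic biased density", {
  kT <- kT_from_temperature(310)
  harm <- analytic_pmf("harmonic", kappa = 50)
  centers <- c(-0.8, 0, 0.8)
  um <- gen_umbrella_samples(harm, centers, k = 1000, n_per_window = 5000,
                             kT = kT, seed = 11L)
  for (i in seq_along(centers)) {
    grid <- seq(-1.6, 1.6, by = 1e-4)
    E <- harm$fun(grid) + 0.5 * 1000 * (grid - centers[i])^2
    p <- exp(-(E - min(E)) / kT)
    cdf <- cumsum(p) / sum(p)
    keep <- c(TRUE, diff(cdf) > 0)
    Fn <- stats::approxfun(grid[keep], cdf[keep], rule = 2)
    xi <- um$xi_nm[um$window_id == i]
    ks <- suppressWarnings(stats::ks.test(xi, Fn))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("crosslink lane generator does species bookkeeping correctly", {
  # no crosslinking: BMH lane identical to the control
  l0 <- gen_crosslink_lanes(c(rm = 0), noise_sd_fraction = 0)
  expect_equal(l0$intensity[l0$lane == "BMH"], l0$intensity[l0$lane == "DMSO"])

  # complete crosslinking: everything in the 0-PEG band
  l1 <- gen_crosslink_lanes(c(rm = 1), noise_sd_fraction = 0)
  bmh <- l1[l1$lane == "BMH", ]
  expect_equal(bmh$intensity[bmh$band == "PEG0"], 100)
  expect_equal(sum(bmh$intensity[bmh$band != "PEG0"]), 0)

  # half crosslinking: 0-PEG gain equals half the PEGylatable pool
  p <- 0.8
  lh <- gen_crosslink_lanes(c(rm = 0.5), label_efficiency = p,
                            noise_sd_fraction = 0)
  peg0 <- function(lane) lh$intensity[lh$lane == lane & lh$band == "PEG0"]
  gain <- peg0("BMH") - peg0("DMSO")
  pegylatable_pool <- 100 * (1 - (1 - p)^2)
  expect_equal(gain, 0.5 * pegylatable_pool, tolerance = 1e-12)

  expect_error(gen_crosslink_lanes(c(a = 1.2)), "\\[0, 1\\]")
})
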