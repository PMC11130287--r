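test_that("pegylated_fraction normalises lane bands", {
  expect_equal(pegylated_fraction(100, 0), 0)
  expect_equal(pegylated_fraction(0, 50), 1)
  expect_equal(pegylated_fraction(60, 40), 0.4)
  expect_equal(pegylated_fraction(50, 30, 20), 0.5)
  expect_error(pegylated_fraction(0, 0, lane = "mPEG lane"), "mPEG lane")
  expect_error(pegylated_fraction(-1, 5), ">= 0")
})

test_that("relative_pegylation normalises to the detergent control with clipping", {
  expect_equal(relative_pegylation(0.6, 0.6)$relative_pegylation_pct, 100)
  expect_equal(relative_pegylation(0.3, 0.6)$relative_pegylation_pct, 50)
  expect_equal(relative_pegylation(0.7, 0.6)$relative_pegylation_pct, 100)
  low <- relative_pegylation(0.1, 0.15)
  expect_true(is.na(low$relative_pegylation_pct))
  expect_equal(low$reliability_flag, "low_positive_control")
})

test_that("aggregate_replicates gives mean, sample sd and count", {
  a <- aggregate_replicates(c(50, 60))
  expect_equal(a$mean, 55)
  expect_equal(a$sd, sqrt(50), tolerance = 1e-12)
  b <- aggregate_replicates(42)
  expect_equal(b$mean, 42)
  expect_true(is.na(b$sd))
  expect_equal(aggregate_replicates(c(7, 7, 7))$sd, 0)
})

test_that("relative pegylation is invariant to lane-wise intensity rescaling", {
  rec <- toy_access_records(100, f_native = 0.3, f_detergent = 0.75)
  scaled <- rec
  scaled$intensity <- scaled$intensity *
    ifelse(scaled$lane == "mPEG", 7.3, ifelse(scaled$lane == "detergent_mPEG", 0.2, 1.9))
  expect_equal(pegylation_profile(rec)$relative_pegylation_pct,
               pegylation_profile(scaled)$relative_pegylation_pct)
})

test_that("topology classification recovers the ground-truth embedded segment", {
  spec <- accessibility_spec("deep_V", noise_sd_fraction = 0)
  tm <- classify_topology(pegylation_profile(gen_accessibility_profile(spec)))
  expect_identical(attr(tm, "embedded_segment"), c(94L, 122L))
  expect_identical(attr(tm, "embedded_length"), 29L)
  # the low-positive-control residues were bridged into the embedded run
  bridged <- tm$label[tm$residue_index %in% c(102, 113, 114)]
  expect_true(all(bridged == "embedded"))
  expect_true(all(tm$reliability_flag[tm$residue_index %in% c(102, 113, 114)] ==
                    "low_positive_control"))
  # recovered boundaries match the generator's plan for every segment class
  expect_equal(sort(tm$residue_index[tm$label == "exposed"]),
               c(80:89, 124:128))
})

test_that("classification handles degenerate and synthetic step profiles", {
  flat <- tibble::tibble(residue_index = 1:6,
                         relative_pegylation_pct = rep(100, 6),
                         reliability_flag = "ok")
  tm <- classify_topology(flat)
  expect_true(all(tm$label == "exposed"))
  expect_null(attr(tm, "embedded_segment"))
  expect_identical(attr(tm, "embedded_length"), 0L)

  step <- tibble::tibble(residue_index = 1:6,
                         relative_pegylation_pct = c(100, 100, 0, 0, 0, 100),
                         reliability_flag = "ok")
  tm2 <- classify_topology(step)
  expect_identical(attr(tm2, "embedded_segment"), c(3L, 5L))
  expect_identical(attr(tm2, "embedded_length"), 3L)

  expect_error(classify_topology(flat[0, ]), "empty")
  expect_error(classify_topology(flat, exposed_min = 20, embedded_max = 30),
               "thresholds")
})

test_that("classification is monotone in the accessibility value", {
  rank_of <- c(embedded = 1, interface = 2, exposed = 3)
  base <- tibble::tibble(residue_index = 1:9,
                         relative_pegylation_pct = seq(5, 95, length.out = 9),
                         reliability_flag = "ok")
  for (i in 1:9) {
    for (bump in c(5, 20, 50)) {
      up <- base
      up$relative_pegylation_pct[i] <-
        min(100, up$relative_pegylation_pct[i] + bump)
      l0 <- classify_topology(base)$label[i]
      l1 <- classify_topology(up)$label[i]
      expect_gte(rank_of[[l1]], rank_of[[l0]])
    }
  }
})

test_that("bridging can be disabled, breaking the embedded run", {
  spec <- accessibility_spec("deep_V", noise_sd_fraction = 0)
  prof <- pegylation_profile(gen_accessibility_profile(spec))
  tm <- classify_topology(prof, bridge = FALSE)
  expect_true(all(tm$label[tm$residue_index %in% c(102, 113, 114)] == "interface"))
  expect_lt(attr(tm, "embedded_length"), 29L)
})

test_that("periodicity score finds the helical pitch and handles degeneracy", {
  x <- sin(2 * pi * (1:29) / 3.6)
  ps <- periodicity_score(x)
  expect_gte(ps$dominant_period, 3.2)
  expect_lte(ps$dominant_period, 4.0)
  expect_gt(ps$relative_power, 0.8)

  flat <- periodicity_score(rep(5, 29))
  expect_equal(flat$relative_power, 0)
  expect_true(is.na(flat$dominant_period))

  expect_error(periodicity_score(1:5), "short")
})

test_that("the open-shallow embedded profile is more periodic than the deep-V one", {
  get_sub <- function(conf) {
    spec <- accessibility_spec(conf, noise_sd_fraction = 0)
    tm <- classify_topology(pegylation_profile(gen_accessibility_profile(spec)))
    tm$relative_pegylation_pct[tm$residue_index >= 94 & tm$residue_index <= 122]
  }
  deep <- get_sub("deep_V"); deep[is.na(deep)] <- mean(deep, na.rm = TRUE)
  open <- get_sub("open_shallow"); open[is.na(open)] <- mean(open, na.rm = TRUE)
  expect_lt(periodicity_score(deep)$relative_power,
            periodicity_score(open)$relative_power)
})

test_that("crosslink efficiency quantification follows the 0-PEG band", {
  same <- tibble::tibble(
    context = "rm", lane = rep(c("DMSO", "BMH"), each = 3),
    band = rep(c("PEG0", "PEG1", "PEG2"), 2),
    intensity = rep(c(20, 30, 50), 2)
  )
  q0 <- crosslink_efficiency(same)
  expect_equal(q0$increase_pct, 0)
  expect_equal(q0$normalized_pct, 0)

  two <- tibble::tibble(
    context = rep(c("A", "B"), each = 4),
    lane = rep(c("DMSO", "DMSO", "BMH", "BMH"), 2),
    band = rep(c("PEG0", "PEG2"), 4),
    intensity = c(20, 80, 60, 40, 20, 80, 40, 60)
  )
  q <- crosslink_efficiency(two)
  expect_equal(q$normalized_pct[q$context == "A"], 100)
  expect_equal(q$normalized_pct[q$context == "B"], 50)

  zero <- same
  zero$intensity[zero$lane == "DMSO" & zero$band == "PEG0"] <- 0
  expect_error(crosslink_efficiency(zero), "zero")
})

test_that("end-to-end crosslink quantification matches the generator's fractions", {
  lanes <- gen_crosslink_lanes(c(bilayer = 0.9, monolayer = 0.45),
                               noise_sd_fraction = 0)
  q <- crosslink_efficiency(lanes)
  expect_equal(q$normalized_pct[q$context == "bilayer"], 100)
  expect_equal(q$normalized_pct[q$context == "monolayer"], 50, tolerance = 1e-10)
})
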