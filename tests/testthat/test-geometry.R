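test_that("phosphate plane is the mean cytoplasmic P level", {
  fr0 <- toy_frame(matrix(c(0, 0, -5), 1), plane_z = 0)
  expect_equal(phosphate_plane(fr0), 0)

  # P atoms at 1, 2, 3 nm -> plane at 2 nm
  atoms <- tibble::tibble(
    residue_index = c(1L, 501L, 502L, 503L),
    residue_name = c("ALA", "POP", "POP", "POP"),
    atom_name = c("CA", "P", "P", "P"),
    x = c(0, 1, 2, 3), y = 0, z = c(0, 10, 20, 30),
    leaflet = c(NA, "cytoplasmic", "cytoplasmic", "cytoplasmic")
  )
  expect_equal(phosphate_plane(membrane_frame(atoms)), 2.0)

  # xy-translation leaves the plane level unchanged
  shifted <- atoms
  shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 30
  expect_equal(phosphate_plane(membrane_frame(shifted)), 2.0)

  too_few <- atoms[1:3, ]
  expect_error(phosphate_plane(membrane_frame(too_few)), ">= 3")
})

test_that("residue depth is signed with insertion positive", {
  # three CAs below the plane (mean below): in-plane residue has depth 0,
  # solvent-side residue is negative
  fr <- toy_frame(matrix(c(0, 0, 0,
                           1, 0, -20,
                           2, 0, 5), 3, byrow = TRUE), residues = 1:3)
  d <- residue_depth(fr)
  expect_equal(d$depth_nm[1], 0)
  expect_equal(d$depth_nm[2], 2.0)
  expect_equal(d$depth_nm[3], -0.5)
  expect_error(residue_depth(fr, 99), "99")
})

test_that("depth sign flips automatically when the membrane is on +z", {
  # peptide mostly above the plane: insertion direction is +z
  fr <- toy_frame(matrix(c(0, 0, 20,
                           1, 0, 30,
                           2, 0, -5), 3, byrow = TRUE), residues = 1:3)
  d <- residue_depth(fr)
  expect_equal(d$depth_nm[1], 2.0)
  expect_equal(d$depth_nm[3], -0.5)
})

test_that("pair distance is Euclidean, symmetric, and triangle-consistent", {
  fr <- toy_frame(matrix(c(0, 0, 0,
                           3, 4, 0,
                           1, 2, 2), 3, byrow = TRUE), residues = 1:3)
  expect_equal(pair_distance(fr, 1, 1), 0)
  expect_equal(pair_distance(fr, 1, 2), 5)
  expect_equal(pair_distance(fr, 1, 2), pair_distance(fr, 2, 1))
  d12 <- pair_distance(fr, 1, 2); d13 <- pair_distance(fr, 1, 3)
  d23 <- pair_distance(fr, 2, 3)
  expect_lte(d12, d13 + d23 + 1e-12)
  expect_error(pair_distance(fr, 1, 9), "residue 9")
})

test_that("tilt angle measures the principal axis against the membrane plane", {
  along <- function(v) toy_frame(outer(0:4, v), residues = 1:5)
  expect_equal(tilt_angle(along(c(0, 0, 1))), 90)
  expect_equal(tilt_angle(along(c(1, 0, 0))), 0)
  expect_equal(tilt_angle(along(c(1, 0, 1))), 45)
  degenerate <- toy_frame(matrix(0, 3, 3), residues = 1:3)
  expect_error(tilt_angle(degenerate), "distinct")
})

test_that("opening angle is measured at the kink between oriented arms", {
  # arms along +x and -x from a central kink: straight, 180 degrees
  xyz <- rbind(
    outer(3:1, c(-1, 0, 0)),   # residues 1-3 on -x
    c(0, 0, 0),                # kink residue 4
    outer(1:3, c(1, 0, 0))     # residues 5-7 on +x
  )
  fr <- toy_frame(xyz, residues = 1:7)
  expect_equal(opening_angle(fr, c(1, 3), c(5, 7), 4), 180)

  xyz2 <- rbind(
    outer(3:1, c(1, 0, 1) / sqrt(2)),
    c(0, 0, 0),
    outer(1:3, c(-1, 0, 1) / sqrt(2))
  )
  fr2 <- toy_frame(xyz2, residues = 1:7)
  expect_equal(opening_angle(fr2, c(1, 3), c(5, 7), 4), 90, tolerance = 1e-6)
})

test_that("conformation classifier applies both thresholds", {
  expect_equal(classify_conformation(2.0, 80), "deep_V")
  expect_equal(classify_conformation(0.1, 30), "open_shallow")
  expect_equal(classify_conformation(0.7, 50), "ambiguous")
  expect_equal(classify_conformation(2.0, 30), "ambiguous")
  expect_error(classify_conformation(NA, 30), "finite")
})

test_that("observables are invariant under in-plane rigid motions", {
  fr <- gen_hairpin_structure(hairpin_geometry_spec("deep_V"))
  obs <- membrane_observables(fr)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  moved <- fr
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% t(rot)
  moved$x <- xyz[, 1] + 12.3; moved$y <- xyz[, 2] - 4.5; moved$z <- xyz[, 3]
  obs2 <- membrane_observables(moved)
  expect_equal(obs2$kink_depth_nm, obs$kink_depth_nm, tolerance = 1e-9)
  expect_equal(obs2$tilt_deg, obs$tilt_deg, tolerance = 1e-6)
  expect_equal(obs2$tip_distance_A, obs$tip_distance_A, tolerance = 1e-9)
  expect_equal(obs2$opening_angle_deg, obs$opening_angle_deg, tolerance = 1e-6)
})

test_that("frame averaging uses the trailing window with SEM across frames", {
  fr <- toy_frame(matrix(c(0, 0, -10), 1), plane_z = 0)
  depth_fun <- function(f) c(depth = residue_depth(f, 1)$depth_nm)

  same <- frame_average(list(fr, fr, fr), depth_fun, window = 1)
  expect_equal(same$mean, 1.0)
  expect_equal(same$sem, 0)

  fr2 <- fr; fr2$z[fr2$atom_name == "CA"] <- -20
  two <- frame_average(list(fr, fr2), depth_fun, window = 1)
  expect_equal(two$mean, 1.5)

  four <- frame_average(list(fr, fr, fr2, fr2), depth_fun, window = 0.5)
  expect_equal(four$n_frames, 2L)
  expect_equal(four$mean, 2.0)
  expect_error(frame_average(list(), depth_fun), "at least one")
})

test_that("coordinate files round-trip through PDB and GRO", {
  fr <- gen_hairpin_structure(hairpin_geometry_spec("open_shallow"))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_frame_pdb(fr, pdb)
  back <- read_membrane_frame(pdb)
  obs <- membrane_observables(back)
  expect_equal(obs$tilt_deg, 30, tolerance = 0.1)
  expect_equal(obs$tip_distance_A, 36, tolerance = 0.1)
  expect_equal(obs$conformation, "open_shallow")

  # minimal GRO fixture: coordinates in nm, fixed-width records
  gro <- withr::local_tempfile(fileext = ".gro")
  fmt <- function(resno, resnm, atom, id, x, y, z) {
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resno, resnm, atom, id, x, y, z)
  }
  writeLines(c(
    "toy hairpin", "5",
    fmt(1, "ALA", "CA", 1, 0, 0, 0),
    fmt(2, "ALA", "CA", 2, 0.3, 0.4, 0),
    fmt(501, "POP", "P", 3, -1, -1, 0.1),
    fmt(502, "POP", "P", 4, 0, 1, 0.1),
    fmt(503, "POP", "P", 5, 1, 0, 0.1),
    "  10.0  10.0  10.0"
  ), gro)
  g <- read_membrane_frame(gro)
  expect_equal(pair_distance(g, 1, 2), 5)  # 0.5 nm -> 5 A
  expect_equal(phosphate_plane(g), 0.1)
})
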