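test_that("reference width returns the medial-lateral extreme distance", {
  case <- generate_leg(leg_parameters(-3, "male", femoral_width_px = 80,
                                      tibial_width_px = 80,
                                      landmark_noise_sd_px = 0, rng_seed = 1))
  expect_equal(reference_width(case$knee, "femur"), 80, tolerance = 1e-6)
  expect_equal(reference_width(case$knee, "tibia"), 80, tolerance = 1e-6)

  # similarity invariance: scaling doubles the width
  scaled <- transform_knee(case$knee, scale = 2)
  expect_equal(reference_width(scaled, "femur"), 160, tolerance = 1e-6)

  # explicit plateau endpoints
  knee <- make_shaft_knee(plateau = rbind(c(-30, 18), c(-10, 22),
                                          c(10, 22), c(30, 18)))
  expect_equal(reference_width(knee, "tibia"), 60, tolerance = 1e-9)
})

test_that("shaft levels are fixed multiples of the reference width", {
  case <- generate_leg(leg_parameters(0, "male", femoral_width_px = 80,
                                      tibial_width_px = 80,
                                      landmark_noise_sd_px = 0, rng_seed = 1))
  expect_equal(shaft_level_distance(case$knee, "femur"), 121.6, tolerance = 1e-6)
  expect_equal(shaft_level_distance(case$knee, "tibia"), 113.6, tolerance = 1e-6)
})

test_that("mid-shaft circle sits on the midline of a straight shaft", {
  knee <- make_shaft_knee(width = 30, origin = c(500, 500))
  ms <- midshaft_point(knee, "femur", 100)
  expect_equal(ms$center, c(500, 400), tolerance = 1e-6)
  expect_equal(ms$radius, 15, tolerance = 1e-6)
  # tibial side: spine base midpoint is (500, 515); level measured distally
  mt <- midshaft_point(knee, "tibia", 100)
  expect_equal(mt$center, c(500, 615), tolerance = 1e-6)
  expect_equal(mt$radius, 15, tolerance = 1e-6)
})

test_that("mid-shaft circle is equivariant under rotation", {
  ms0 <- midshaft_point(make_shaft_knee(), "femur", 120)
  kneeR <- make_shaft_knee(rot = 10)
  msR <- midshaft_point(kneeR, "femur", 120)
  expected <- drop(rot_deg(matrix(ms0$center - c(500, 500), 1), 10)) + c(500, 500)
  expect_equal(msR$center, expected, tolerance = 1e-6)
  expect_equal(msR$radius, ms0$radius, tolerance = 1e-6)
})

test_that("tapered shafts: circle tangent to both cortices (distance oracle)", {
  knee <- make_shaft_knee(width = 40, taper_med_deg = 1.5, taper_lat_deg = 1.5)
  ms <- midshaft_point(knee, "femur", 150)
  dm <- oracle_polyline_dist(ms$center, region_points(knee, "fem_shaft_medial"))
  dl <- oracle_polyline_dist(ms$center, region_points(knee, "fem_shaft_lateral"))
  expect_lt(abs(dm - ms$radius), 1e-3 * ms$radius)
  expect_lt(abs(dl - ms$radius), 1e-3 * ms$radius)
  # radius equals half the local width at the measurement level
  expect_equal(ms$radius, 20 - tan(1.5 * pi / 180) * (150 - 20), tolerance = 1e-3)
})

test_that("mid-shaft levels outside the landmarked extent fail cleanly", {
  knee <- make_shaft_knee(extent = c(20, 200))
  expect_error(midshaft_point(knee, "femur", 500), "outside the landmarked")
  expect_error(midshaft_point(knee, "femur", 100, max_iter = 1L), "did not converge")
})

test_that("axis definitions resolve to their anatomical rules", {
  p <- leg_parameters(-6, "male", landmark_noise_sd_px = 0, rng_seed = 4)
  case <- generate_leg(p)
  knee <- case$knee
  w <- reference_width(knee, "femur")

  fem2 <- resolve_axis(knee, "Fem2")
  # distal point is the notch apex landmark
  expect_equal(fem2$p2, unname(drop(region_points(knee, "fem_notch_apex"))),
               tolerance = 1e-9)
  # proximal point lies 1.52 widths from the notch
  expect_equal(sqrt(sum((fem2$p1 - fem2$p2)^2)), 1.52 * w, tolerance = 1e-3)

  # symmetric neutral tibia aligned with the vertical -> vertical axis
  neutral <- generate_leg(leg_parameters(0, "male", bow_deg = 0,
                                         landmark_noise_sd_px = 0, rng_seed = 4))
  tib3 <- resolve_axis(neutral$knee, "Tib3")
  expect_equal(tib3$p1[1], tib3$p2[1], tolerance = 1e-6)

  expect_error(resolve_axis(knee, "Fem5"), "unknown axis definition")
})

test_that("Fem3 and Tib3 share the spine-base vertex (vertex-angle oracle)", {
  case <- generate_leg(leg_parameters(-7, "female", landmark_noise_sd_px = 0,
                                      rng_seed = 8))
  fem3 <- resolve_axis(case$knee, "Fem3")
  tib3 <- resolve_axis(case$knee, "Tib3")
  expect_equal(fem3$p2, tib3$p2, tolerance = 1e-9)
  got <- signed_angle(fem3, tib3)
  want <- oracle_signed_angle(fem3$p1, fem3$p2, tib3$p1, tib3$p2)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("signed angles follow the varus-negative convention", {
  fem <- bone_axis(c(0, 100), c(0, 0), "fem")
  expect_equal(signed_angle(fem, bone_axis(c(0, 200), c(0, 100), "tib")), 0)

  # varus: ankle end deviates medially (+x in canonical orientation)
  ankle <- c(100 * sin(5 * pi / 180), 100 + 100 * cos(5 * pi / 180))
  tib_var <- bone_axis(ankle, c(0, 100), "tib")
  expect_equal(signed_angle(fem, tib_var), -5, tolerance = 1e-9)
  expect_equal(signed_angle(fem, tib_var),
               oracle_signed_angle(fem$p1, fem$p2, tib_var$p1, tib_var$p2),
               tolerance = 1e-12)

  # rotating the femoral axis by the same amount instead flips the sign
  fem_rot <- bone_axis(rot_deg(matrix(c(0, 0), 1), -5, c(0, 100))[1, ],
                       c(0, 100), "fem")
  tib <- bone_axis(c(0, 200), c(0, 100), "tib")
  expect_equal(abs(signed_angle(fem_rot, tib)), 5, tolerance = 1e-9)
  expect_equal(sign(signed_angle(fem_rot, tib)), 1) # femur tilted into valgus

  expect_error(bone_axis(c(0, 0), c(0, 0)), "degenerate")
})

test_that("the battery returns the nine combinations in canonical order", {
  neutral <- generate_leg(leg_parameters(0, "male", bow_deg = 0,
                                         landmark_noise_sd_px = 0, rng_seed = 2))
  b <- fta_battery(neutral$knee)
  expect_equal(nrow(b), 9)
  expect_equal(b$definition, FTA_COMBINATIONS)
  expect_true(all(b$status == "ok"))
  expect_true(all(abs(b$value_deg) < 1e-6))

  varus <- generate_leg(leg_parameters(-8, "male", bow_deg = 0,
                                       landmark_noise_sd_px = 0, rng_seed = 2))
  bv <- fta_battery(varus$knee)
  expect_true(all(bv$value_deg < 0))
})

test_that("a failing definition is reported without aborting the battery", {
  # shaft landmarks start 50 px from the joint: the meta-/epiphysis points
  # of Fem1 and Tib1 (~48.6 px at width 80) become unreachable while every
  # other rule still resolves
  knee <- make_shaft_knee(extent = c(50, 200), condyle_halfw = 40)
  b <- fta_battery(knee)
  expect_equal(nrow(b), 9)
  fails <- grepl("Fem1|Tib1", b$definition)
  expect_true(all(b$status[fails] != "ok"))
  expect_true(all(is.na(b$value_deg[fails])))
  expect_true(all(b$status[!fails] == "ok"))
  expect_true(all(is.finite(b$value_deg[!fails])))
})

test_that("gold-standard HKAA matches the atan2 oracle incl. mirroring", {
  limb0 <- full_limb_set("s", c(0, 0), c(0, 400), c(0, 410), c(0, 800))
  expect_equal(hkaa(limb0), 0)

  # ankle displaced laterally (-x): 3 degrees valgus
  ankle <- c(-390 * tan(3 * pi / 180), 410 + 390)
  limb3 <- full_limb_set("s", c(0, 0), c(0, 400), c(0, 410), ankle)
  expect_equal(hkaa(limb3), 3, tolerance = 1e-9)

  # mirrored left-limb twin gives the same value
  m <- mirror_pts_about <- function(p) c(-p[1], p[2])
  limb3L <- full_limb_set("s", m(c(0, 0)), m(c(0, 400)), m(c(0, 410)), m(ankle))
  expect_equal(hkaa(limb3L, side = "left"), hkaa(limb3), tolerance = 1e-9)

  expect_error(full_limb_set("s", c(0, 0), c(0, 0), c(0, 10), c(0, 800)))
})

test_that("angles are invariant under similarity transforms of the landmarks", {
  case <- generate_leg(leg_parameters(-6.5, "female", landmark_noise_sd_px = 0.5,
                                      rng_seed = 21))
  base <- fta_battery(case$knee)$value_deg
  for (tr in list(list(deg = 17, shift = c(300, -40), scale = 1),
                  list(deg = 0, shift = c(-120, 55), scale = 2.5),
                  list(deg = -9, shift = c(10, 10), scale = 0.5))) {
    knee2 <- transform_knee(case$knee, deg = tr$deg, shift = tr$shift,
                            scale = tr$scale)
    got <- fta_battery(knee2)$value_deg
    expect_equal(got, base, tolerance = 1e-6)
  }
})

test_that("mirrored storage and reload leaves all angles unchanged", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(4, cohort_config(landmark_noise_sd_px = 1,
                                          left_fraction = 0.5), seed = 31)
  write_cohort(coh, dir)
  got <- read_cohort(dir, file.path(dir, "meta.csv"))
  for (id in names(coh$cases)) {
    expect_equal(fta_battery(got$cases[[id]]$knee)$value_deg,
                 fta_battery(coh$cases[[id]]$knee)$value_deg,
                 tolerance = 1e-6)
    expect_equal(hkaa(got$cases[[id]]$limb), hkaa(coh$cases[[id]]$limb),
                 tolerance = 1e-6)
  }
})
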