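test_that("screw operator matches the trigonometric oracle and the group law", {
  p <- rip2_params()
  expect_rt_equal(screw_operator(p, 0), rigid_transform())

  # k = 1 maps (10, 0, 0) to (10 cos(-101.4), 10 sin(-101.4), 4.936)
  got <- rt_apply(screw_operator(p, 1), c(10, 0, 0))
  th <- -101.4 * pi / 180
  expect_equal(as.numeric(got), c(10 * cos(th), 10 * sin(th), 4.936),
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    q <- random_params()
    a <- sample(-5:5, 1); b <- sample(-5:5, 1)
    expect_rt_equal(rt_compose(screw_operator(q, a), screw_operator(q, b)),
                    screw_operator(q, a + b))
  }
})

test_that("pitch, protrusion spacing and per-turn arithmetic reproduce the printed values", {
  # the published consistency formula: (720/101.36)*4.96 = 35.23
  expect_equal(round(protrusion_spacing(helical_params(4.96, -101.36)), 2), 35.23)
  expect_equal(protrusion_spacing(helical_params(4.936, -101.4)), 35.0485,
               tolerance = 1e-4)
  expect_equal(helical_pitch(helical_params(4.936, -101.4)), 17.5243,
               tolerance = 1e-4)
  expect_equal(helical_pitch(helical_params(10, 180)), 20)

  expect_equal(subunits_per_turn(helical_params(4.936, -101.4)), 3.5503,
               tolerance = 1e-4)
  expect_equal(subunits_per_turn(helical_params(5, 120)), 3)
  expect_equal(subunits_per_turn(helical_params(5, -101)), 3.5644,
               tolerance = 1e-4)

  set.seed(2)
  for (i in 1:50) {
    q <- random_params()
    expect_identical(protrusion_spacing(q), 2 * helical_pitch(q))
    # doubling the rise doubles the spacing
    q2 <- helical_params(2 * q$rise, q$twist)
    expect_equal(protrusion_spacing(q2), 2 * protrusion_spacing(q))
  }
})

test_that("subunit_count_in_span floors the span over the rise", {
  p <- rip2_params()
  expect_identical(subunit_count_in_span(60, p), 12L)     # the 60 A segment
  expect_identical(subunit_count_in_span(4.936, p), 1L)
  expect_identical(subunit_count_in_span(59.2, p), 11L)
  expect_error(subunit_count_in_span(-1, p), "positive")
})

test_that("helical_params validates its domain", {
  expect_error(helical_params(0, -101.4), "positive")
  expect_error(helical_params(4.936, 0), "nonzero")
  expect_error(helical_params(4.936, 181), "180")
  expect_error(helical_params(4.936, -180), "180")
  expect_error(helical_params(4.936, -101.4, point_group = "C2"), "C1")
})

test_that("build_filament places subunits on the screw lattice", {
  mono <- fx_monomer()
  p <- rip2_params()
  f1 <- build_filament(mono, p, 1)
  expect_identical(f1$subunits[[1L]]$atoms[, c("x", "y", "z")],
                   mono$atoms[, c("x", "y", "z")])

  f12 <- fx_filament(12)
  cen <- t(vapply(f12$subunits,
                  function(s) colMeans(as.matrix(s$atoms[, c("x", "y", "z")])),
                  numeric(3L)))
  expect_equal(diff(cen[, 3L]), rep(4.936, 11), tolerance = 1e-9)
  # axial extent of the 12 centroids: 11 x 4.936
  expect_equal(max(cen[, 3L]) - min(cen[, 3L]), 54.296, tolerance = 1e-9)

  expect_error(build_filament(mono, p, 0), ">= 1")
  centered <- mono
  xyz <- as.matrix(mono$atoms[, c("x", "y", "z")])
  centered$atoms[, c("x", "y", "z")] <- sweep(xyz, 2L, colMeans(xyz))
  expect_error(build_filament(centered, p, 3), "axis")
})

test_that("opposite-twist builds are mirror images distinguishable only by reflection", {
  mono <- fx_monomer()
  fl <- build_filament(mono, helical_params(4.936, -101.4), 8)
  fr <- build_filament(mono, helical_params(4.936, 101.4), 8)
  expect_identical(filament_handedness(fl), -1)
  expect_identical(filament_handedness(fr), 1)

  # mirroring the left-handed build through y -> -y gives exactly the
  # right-handed build of the mirrored monomer
  mmono <- mono
  mmono$atoms$y <- -mmono$atoms$y
  fr_m <- build_filament(mmono, helical_params(4.936, 101.4), 8)
  al <- do.call(rbind, lapply(fl$subunits, function(s) s$atoms))
  am <- do.call(rbind, lapply(fr_m$subunits, function(s) s$atoms))
  expect_equal(cbind(al$x, -al$y, al$z), cbind(am$x, am$y, am$z),
               tolerance = 1e-9, ignore_attr = TRUE)

  # superposing the build onto its mirror image requires a reflection
  P <- as.matrix(al[, c("x", "y", "z")])
  M <- cbind(al$x, -al$y, al$z)
  proper <- kabsch_fit(P, M)
  improper <- kabsch_fit(P, M, allow_reflection = TRUE)
  expect_gt(proper$rmsd, 1)
  expect_lt(improper$rmsd, 1e-9)
  expect_true(improper$reflected)
})

test_that("filament handedness sign tracks the sign of the twist", {
  mono <- fx_monomer()
  set.seed(5)
  for (i in 1:10) {
    q <- random_params()
    f <- build_filament(mono, q, 6)
    expect_identical(filament_handedness(f), sign(q$twist))
  }
})

test_that("filament_diameter is twice the 95th-percentile heavy-atom radius", {
  # all atoms on a 35 A cylinder -> 70 A
  th <- seq(0, 2 * pi, length.out = 50L)
  atoms <- atom_table(seq_along(th), "CA", "C", seq_along(th), "ALA", "A",
                      x = 35 * cos(th), y = 35 * sin(th), z = seq_along(th))
  cyl <- filament_model(list(list(index = 0L, transform = rigid_transform(),
                                  atoms = atoms)))
  expect_equal(filament_diameter(cyl), 70, tolerance = 1e-9)

  one <- fx_point_filament(y = 0, z = 0)
  one$subunits[[1L]]$atoms$x <- 0
  expect_equal(filament_diameter(one), 0)

  expect_gt(filament_diameter(fx_filament(12)), 50)
  expect_lt(filament_diameter(fx_filament(12)), 90)
})

test_that("helical parameters round-trip through a built filament", {
  p <- recover_params_from_filament(fx_filament(8))
  expect_equal(p$rise, 4.936, tolerance = 1e-6)
  expect_equal(p$twist, -101.4, tolerance = 1e-6)

  # right-handed build recovers a positive twist
  fr <- build_filament(fx_monomer(), helical_params(5.1, 101.0), 4)
  pr <- recover_params_from_filament(fr)
  expect_gt(pr$twist, 0)
  expect_equal(pr$rise, 5.1, tolerance = 1e-6)
  expect_equal(pr$twist, 101.0, tolerance = 1e-6)

  # 0.2 A coordinate jitter: recovery within 0.05 A / 0.5 deg
  set.seed(31)
  for (rep in 1:5) {
    fj <- fx_filament(8)
    for (k in seq_along(fj$subunits)) {
      a <- fj$subunits[[k]]$atoms
      a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
        matrix(rnorm(nrow(a) * 3, sd = 0.2), ncol = 3L)
      fj$subunits[[k]]$atoms <- a
    }
    pj <- recover_params_from_filament(fj)
    expect_lt(abs(pj$rise - 4.936), 0.05)
    expect_lt(abs(pj$twist + 101.4), 0.5)
  }

  # incongruent subunits are rejected
  fb <- fx_filament(4)
  fb$subunits[[2L]]$atoms$x <- fb$subunits[[2L]]$atoms$x +
    seq_len(nrow(fb$subunits[[2L]]$atoms))
  expect_error(recover_params_from_filament(fb), "not a filament")
  expect_error(recover_params_from_filament(fx_filament(1)), "two subunits")
})

test_that("twist sign is ambiguous from magnitude alone", {
  amb <- twist_sign_ambiguity(101)
  expect_setequal(amb$candidates, c(101, -101))
  expect_false(amb$resolved)

  amb180 <- twist_sign_ambiguity(180)
  expect_identical(amb180$candidates, 180)
  expect_error(twist_sign_ambiguity(0), "0, 180")
  expect_error(twist_sign_ambiguity(200), "0, 180")
})
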