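test_that("superposing a set onto itself gives identity and zero RMSD", {
  set.seed(7)
  ca <- as_calpha(matrix(rnorm(60, sd = 5), ncol = 3))
  sup <- kabsch_superpose(ca, ca)
  expect_equal(sup$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(sup$transform$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$n, 20)
})

test_that("a known rigid transform is recovered exactly", {
  set.seed(8)
  ref <- as_calpha(matrix(rnorm(45, sd = 6), ncol = 3))
  rot90 <- rotation_about_axis(c(0, 0, 1), 90)
  tf <- rigid_transform(rot90, c(1, 2, 3))
  mob <- ref
  mob[, c("x", "y", "z")] <- apply_transform(bundlemotion:::ca_xyz(ref), tf)
  sup <- kabsch_superpose(mob, ref)
  inv <- invert_transform(tf)
  expect_equal(sup$transform$rotation, inv$rotation, tolerance = 1e-8)
  expect_equal(sup$transform$translation, inv$translation, tolerance = 1e-8)
  expect_lt(sup$rmsd, 1e-8)
})

test_that("SVD superposition matches the quaternion oracle on noisy data", {
  set.seed(9)
  ref_xyz <- matrix(rnorm(300, sd = 8), ncol = 3)
  tf <- rigid_transform(random_rotation(), runif(3, -10, 10))
  mob_xyz <- apply_transform(ref_xyz, tf) + matrix(rnorm(300, sd = 0.1), ncol = 3)
  sup <- kabsch_superpose(as_calpha(mob_xyz), as_calpha(ref_xyz))
  oracle <- horn_superpose(mob_xyz, ref_xyz)
  expect_equal(sup$rmsd, oracle$rmsd, tolerance = 1e-8)
  expect_equal(sup$transform$rotation, oracle$rotation, tolerance = 1e-6)
  # and agrees with bio3d's fitting (which reports 3 decimals)
  rms_bio3d <- bio3d::rmsd(as.numeric(t(ref_xyz)), as.numeric(t(mob_xyz)),
                           fit = TRUE)
  expect_equal(round(sup$rmsd, 3), rms_bio3d)
})

test_that("superposition errors on degenerate input", {
  ca2 <- as_calpha(matrix(rnorm(6), ncol = 3))
  expect_error(kabsch_superpose(ca2, ca2), "at least 3")
  line <- as_calpha(cbind(1:10, 2 * (1:10), -1 * (1:10)))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD is invariant to rigid pre-transforms of the mobile set", {
  set.seed(10)
  ref <- as_calpha(matrix(rnorm(90, sd = 7), ncol = 3))
  mob <- as_calpha(bundlemotion:::ca_xyz(ref) +
                     matrix(rnorm(90, sd = 0.5), ncol = 3))
  base <- kabsch_superpose(mob, ref)$rmsd
  for (k in 1:5) {
    tf <- random_rigid()
    mob2 <- mob
    mob2[, c("x", "y", "z")] <- apply_transform(bundlemotion:::ca_xyz(mob), tf)
    expect_equal(kabsch_superpose(mob2, ref)$rmsd, base, tolerance = 1e-8)
  }
})

test_that("per-residue deviations are consistent with the overall RMSD", {
  set.seed(11)
  ref <- as_calpha(matrix(rnorm(120, sd = 6), ncol = 3))
  # identical structures: all deviations zero
  sup0 <- kabsch_superpose(ref, ref)
  dev0 <- per_residue_deviation(ref, ref, sup0$transform)
  expect_true(all(dev0$deviation < 1e-10))

  mob <- as_calpha(bundlemotion:::ca_xyz(ref) +
                     matrix(rnorm(120, sd = 0.3), ncol = 3))
  sup <- kabsch_superpose(mob, ref)
  dev <- per_residue_deviation(mob, ref, sup$transform)
  expect_true(all(dev$deviation >= 0))
  expect_equal(sqrt(mean(dev$deviation^2)), sup$rmsd, tolerance = 1e-10)
})

test_that("a residue displaced after alignment shows its displacement", {
  set.seed(12)
  ref_xyz <- matrix(rnorm(150, sd = 6), ncol = 3)
  mob_xyz <- ref_xyz
  mob_xyz[25, ] <- mob_xyz[25, ] + c(2, 0, 0)
  ref <- as_calpha(ref_xyz); mob <- as_calpha(mob_xyz)
  # align on all residues except the displaced one
  sup <- kabsch_superpose(mob[-25, ], ref[-25, ])
  dev <- per_residue_deviation(mob, ref, sup$transform)
  expect_equal(dev$deviation[dev$resno == 25], 2, tolerance = 1e-6)
  expect_lt(max(dev$deviation[dev$resno != 25]), 1e-6)
})

test_that("helix axis fitting recovers constructed directions", {
  h <- as_calpha(ideal_helix_points(20))
  fit <- fit_helix_axis(h)
  expect_equal(abs(sum(fit$direction * c(0, 0, 1))), 1, tolerance = 1e-3)
  expect_gte(fit$direction[3], 0)  # N->C along +z

  rot30 <- rotation_about_axis(c(1, 0, 0), 30)
  h2 <- as_calpha(ideal_helix_points(20) %*% t(rot30))
  a <- bundlemotion:::vec_angle(fit_helix_axis(h2)$direction, c(0, 0, 1))
  expect_equal(a, 30, tolerance = 0.5)

  # antiparallel helix: C->N along +z, so the axis must flip to -z
  anti <- ideal_helix_points(20)
  anti[, 3] <- -anti[, 3]
  expect_lt(fit_helix_axis(as_calpha(anti))$direction[3], 0)

  expect_error(fit_helix_axis(as_calpha(ideal_helix_points(4))), "at least 5")
})

test_that("membrane normal estimation agrees with explicit axis averaging", {
  b <- test_bundle()
  n1 <- estimate_membrane_normal(b$structure, b$segments)
  expect_equal(abs(n1[3]), 1, tolerance = 1e-3)

  # symmetric +-20 degree tilts cancel
  b2 <- test_bundle()
  s <- b2$structure
  seg <- bundlemotion:::assign_segments(s, b2$segments)
  for (k in 1:8) {
    rows <- seg == paste0("TM", k)
    ang <- if (k %% 2 == 0) 20 else -20
    rot <- rotation_about_axis(c(1, 0, 0), ang)
    xyz <- as.matrix(s[rows, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    s[rows, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, -ctr)
  }
  # an even-index helix is antiparallel, so +-20 about x is symmetric in pairs
  n2 <- estimate_membrane_normal(s, b2$segments)
  expect_equal(abs(n2[3]), 1, tolerance = 1e-3)

  # random small tilts: consensus stays near z and matches explicit averaging
  set.seed(13)
  s3 <- b2$structure
  for (k in 1:8) {
    rows <- seg == paste0("TM", k)
    axis <- c(rnorm(2), 0); axis <- axis / sqrt(sum(axis^2))
    rot <- rotation_about_axis(axis, 10)
    xyz <- as.matrix(s3[rows, c("x", "y", "z")])
    ctr <- colMeans(xyz)
    s3[rows, c("x", "y", "z")] <- sweep(sweep(xyz, 2, ctr) %*% t(rot), 2, -ctr)
  }
  n3 <- estimate_membrane_normal(s3, b2$segments)
  expect_lt(bundlemotion:::vec_angle(n3, c(0, 0, 1)), 3)
  ca3 <- select_calpha(s3, segments = b2$segments)
  axes <- t(sapply(paste0("TM", 1:8), function(nm)
    fit_helix_axis(ca3[ca3$segment == nm, ])$direction))
  axes[axes %*% axes[1, ] < 0, ] <- -axes[axes %*% axes[1, ] < 0, , drop = FALSE]
  oracle <- colMeans(axes); oracle <- oracle / sqrt(sum(oracle^2))
  expect_equal(abs(sum(n3 * oracle)), 1, tolerance = 1e-8)

  # orientation flag flips the sign deterministically
  expect_equal(estimate_membrane_normal(b$structure, b$segments,
                                        orient = c(0, 0, -1))[3] < 0, TRUE)
})

test_that("rotation angle from the trace matches the eigenvalue oracle", {
  set.seed(14)
  for (k in 1:100) {
    R <- random_rotation()
    expect_equal(rotation_angle(R), rotation_angle_eigen(R), tolerance = 1e-6)
  }
})

test_that("domain motion is zero for identical structures", {
  b <- test_bundle()
  rep0 <- domain_motion(b$structure, b$structure, b$segments, b$scaffold,
                        b$transport, normal = c(0, 0, 1))
  expect_equal(rep0$overall_rmsd, 0, tolerance = 1e-10)
  expect_equal(rep0$along_normal, 0, tolerance = 1e-10)
  expect_equal(rep0$in_plane, 0, tolerance = 1e-10)
  expect_equal(rep0$tilt, 0, tolerance = 1e-6)
})

test_that("domain motion recovers a planted 3 A / 11 degree elevator motion", {
  b <- test_bundle()
  mv <- apply_motion(b, motion_spec(translation = -3, rotation_deg = 11))
  rep <- domain_motion(b$structure, mv, b$segments, b$scaffold, b$transport,
                       normal = c(0, 0, 1))
  expect_equal(rep$along_normal, -3, tolerance = 1e-6)
  expect_equal(rep$tilt, 11, tolerance = 1e-4)
  expect_lt(rep$scaffold_rmsd, 1e-8)
  # moved helices change their axis angle, scaffold helices do not
  expect_true(all(rep$segment_angles[c("TM2", "TM3", "TM7", "TM8")] < 0.1))
  expect_true(all(rep$segment_angles[c("TM1", "TM4", "TM5", "TM6")] > 5))
})

test_that("swapping the two structures negates the translation, keeps the tilt", {
  b <- test_bundle()
  mv <- apply_motion(b, motion_spec(translation = -3, rotation_deg = 11))
  fwd <- domain_motion(b$structure, mv, b$segments, b$scaffold, b$transport,
                       normal = c(0, 0, 1))
  rev <- domain_motion(mv, b$structure, b$segments, b$scaffold, b$transport,
                       normal = c(0, 0, 1))
  expect_equal(rev$along_normal, -fwd$along_normal, tolerance = 1e-6)
  expect_equal(rev$tilt, fwd$tilt, tolerance = 1e-4)
})

test_that("site displacements and split-segment angles are reported", {
  b <- test_bundle()
  mv <- apply_motion(b, motion_spec(translation = -3, rotation_deg = 0))
  # a site on the moving domain (TM1 covers residues 1..25)
  site_mv <- site_definition("carried site", c("A", "A"), c(10, 12))
  # a site on the scaffold (TM2 covers residues 31..55)
  site_sc <- site_definition("static site", c("A", "A"), c(40, 42))
  rep <- domain_motion(b$structure, mv, b$segments, b$scaffold, b$transport,
                       normal = c(0, 0, 1), sites = list(site_mv, site_sc),
                       tm4_split = "TM4")
  expect_equal(unname(rep$site_displacements["carried site"]), 3,
               tolerance = 1e-6)
  expect_equal(unname(rep$site_displacements["static site"]), 0,
               tolerance = 1e-8)
  # pure translation leaves every axis direction unchanged
  expect_lt(rep$half_segment_angle, 0.1)
})

test_that("noise-corrupted pairs are recovered with error growing with noise", {
  errs <- sapply(c(0.05, 0.4), function(sd) {
    mean(sapply(1:8, function(r) {
      b <- make_bundle(bundle_spec(noise_sd = sd, seed = r))
      mv <- apply_motion(b, motion_spec(translation = -4, rotation_deg = 8,
                                        renoise = TRUE, seed = 1000 + r))
      rep <- domain_motion(b$structure, mv, b$segments, b$scaffold,
                           b$transport, normal = c(0, 0, 1))
      abs(rep$along_normal + 4)
    }))
  })
  expect_lt(errs[1], 0.1)   # ~ sigma/sqrt(N) scale, far below the motion
  expect_gt(errs[2], errs[1])  # error grows with the noise level
})
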