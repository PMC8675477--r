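# Split scanning, C2 axis extraction, helix tilts, connectivity counting.

test_that("split_trace partitions a trace cleanly and checks bounds", {
  d <- make_c2_dimer(seed = 1)
  tr <- d$trace
  h <- split_trace(tr, 74)
  expect_length(h$n, 74L)
  expect_length(h$c, length(tr) - 74L)
  expect_identical(c(h$n$sequence, h$c$sequence), tr$sequence)
  expect_identical(c(h$n$residue_ids, h$c$residue_ids), tr$residue_ids)
  expect_error(split_trace(tr, 0), "bounds")
  expect_error(split_trace(tr, length(tr)), "bounds")
  expect_error(split_trace(tr, 20), "bounds")  # < min_half_len
})

test_that("split scan pins the planted split on a noise-free dimer", {
  d <- make_c2_dimer(seed = 5)
  r <- scan_splits(d$trace, d$truth$split + c(-10, 10))
  expect_s3_class(r, "symreport")
  expect_lte(abs(r$split_index - d$truth$split), 2)
  expect_lt(r$core$core_rmsd, 1e-6)
  expect_identical(r$verdict, "symmetric")
  expect_equal(r$axis$angle_deg, 180, tolerance = 1e-6)
})

test_that("split scan recovers a noisy planted split", {
  d <- make_c2_dimer(noise_sd = 0.3, seed = 7)
  r <- scan_splits(d$trace, d$truth$split + c(-10, 10))
  expect_lte(abs(r$split_index - d$truth$split), 3)
  expect_identical(r$verdict, "symmetric")
})

test_that("a random-walk coil is judged asymmetric", {
  coil <- make_random_coil(150, seed = 5)
  r <- scan_splits(coil, c(60, 90))
  expect_identical(r$verdict, "asymmetric")
  expect_lt(r$core$tm_core, 0.30)
})

test_that("a trace fused to its own rotated copy is always symmetric", {
  for (cfg in list(c(2, 20, 6), c(4, 18, 12))) {
    d <- make_c2_dimer(n_helices = cfg[1], helix_length = cfg[2],
                       linker_length = cfg[3], seed = 17)
    r <- scan_splits(d$trace, d$truth$split + c(-5, 5))
    expect_identical(r$verdict, "symmetric")
  }
})

test_that("c2_axis extracts axis and angle and round-trips the rotation", {
  r180 <- pseudosym:::rotation_about_axis(c(0, 0, 1), pi)
  ax <- c2_axis(list(rotation = r180))
  expect_equal(ax$angle_deg, 180)
  expect_equal(ax$c2_deviation_deg, 0)
  expect_equal(abs(ax$axis), c(0, 0, 1), tolerance = 1e-9)
  expect_error(c2_axis(list(rotation = diag(3))), "undefined axis")
  set.seed(31)
  for (i in 1:50) {
    r <- random_rotation()
    a <- c2_axis(list(rotation = r))
    rebuilt <- pseudosym:::rotation_about_axis(a$axis, a$angle_deg * pi / 180)
    expect_lt(max(abs(rebuilt - r)), 1e-9)
  }
})

test_that("axis tilt against the membrane plane is reported", {
  frame <- membrane_frame(30)
  ax <- c2_axis(list(rotation = pseudosym:::rotation_about_axis(c(0, 1, 0), pi)),
                frame)
  expect_equal(ax$membrane_parallel_tilt_deg, 0, tolerance = 1e-9)
  tilted <- pseudosym:::rotation_about_axis(c(0, cos(pi / 9), sin(pi / 9)), pi)
  ax2 <- c2_axis(list(rotation = tilted), frame)
  expect_equal(ax2$membrane_parallel_tilt_deg, 20, tolerance = 1e-6)
})

test_that("noisy dimers yield near-180 rotations about the planted axis", {
  for (s in 1:5) {
    d <- make_c2_dimer(noise_sd = 0.3, seed = 100 + s)
    r <- scan_splits(d$trace, d$truth$split + c(-6, 6))
    expect_gte(r$axis$angle_deg, 178)
    expect_lte(r$axis$angle_deg, 182)
    expect_lte(axis_angle_deg(r$axis$axis, d$truth$axis), 3)
  }
})

test_that("helix axes report membrane tilts to within half a degree", {
  h <- pseudosym:::ideal_helix(20, direction = 1)
  frame <- membrane_frame(30)
  expect_lt(abs(0 - pseudosym:::angle_deg(helix_axis(h), frame$normal)), 0.5)
  r25 <- pseudosym:::rotation_about_axis(c(1, 0, 0), 25 * pi / 180)
  expect_lt(abs(25 - pseudosym:::angle_deg(helix_axis(h %*% t(r25)),
                                           frame$normal)), 0.5)
  expect_error(helix_axis(h[1:4, ]), "6 residues")
})

test_that("a planted symmetry-breaking tilt shows up in one helix only", {
  d <- make_c2_dimer(seed = 23)
  tr <- d$trace
  hl <- 23L; nh <- d$truth$half_length; lk <- length(tr) - 2 * nh
  # tilt the second helix of the C-half by 15 degrees about x, in place
  idx <- (nh + lk + hl + 1):(nh + lk + 2 * hl)
  seg <- tr$coords[idx, ]
  r15 <- pseudosym:::rotation_about_axis(c(1, 0, 0), 15 * pi / 180)
  tr$coords[idx, ] <- sweep(sweep(seg, 2, colMeans(seg)) %*% t(r15), 2,
                            colMeans(seg), "+")
  h <- split_trace(tr, d$truth$split)
  aln <- align_traces(h$n, h$c)
  segs <- rbind(
    data.frame(label = paste0("H", 1:3), half = "N",
               from = (0:2) * hl + 1, to = (1:3) * hl),
    data.frame(label = paste0("H", 1:3), half = "C",
               from = nh + lk + (0:2) * hl + 1, to = nh + lk + (1:3) * hl))
  tilts <- helix_tilts(aln, segs, membrane_frame(30))
  expect_equal(tilts$n_to_c_angle_deg[2], 15, tolerance = 3)
  expect_lt(max(tilts$n_to_c_angle_deg[c(1, 3)]), 5)
  bad <- segs; bad$to[1] <- bad$from[1] + 3
  expect_error(helix_tilts(aln, bad, membrane_frame(30)), "6 residues")
})

test_that("connectivity counts match the factorial formula and enumeration", {
  expect_equal(count_connectivities(3, 2, 3), 36)
  expect_equal(count_connectivities(1, 1, 1), 1)
  expect_equal(count_connectivities(0, 0, 1), 1)   # 0! = 1
  expect_equal(count_connectivities(2, 2, 0), 0)   # nothing to prepend to
  expect_equal(count_connectivities(4, 3, 4), 576)
  expect_equal(enumerate_connectivities(4, 3, 4), 576L)
  for (ni in 0:3) for (no in 0:3) for (np in 0:3)
    expect_equal(count_connectivities(ni, no, np),
                 enumerate_connectivities(ni, no, np))
  trip <- enumerate_connectivities(2, 1, 2, list_all = TRUE)
  expect_length(trip, 4L)
  expect_error(count_connectivities(-1, 2, 3), "non-negative")
  expect_error(count_connectivities(2.5, 2, 3), "non-negative")
})
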