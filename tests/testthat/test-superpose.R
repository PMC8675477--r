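# Kabsch superposition, TM-score, structural aligner, common core.

test_that("kabsch recovers exact rigid transforms", {
  a <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 1), 4, 3, byrow = TRUE)
  s <- kabsch(a, a)
  expect_equal(s$rotation, diag(3), tolerance = 1e-12)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  # 90 degrees about z plus a translation
  r90 <- pseudosym:::rotation_about_axis(c(0, 0, 1), pi / 2)
  b <- sweep(a %*% t(r90), 2, c(5, 0, 0), "+")
  s2 <- kabsch(a, b)
  expect_lt(s2$rmsd, 1e-9)
  expect_lt(max(abs(apply_superposition(s2, a) - b)), 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rejects reflections and degenerate input", {
  a <- matrix(rnorm(12), 4, 3)
  b <- a
  b[, 1] <- -b[, 1]    # mirrored set: best proper rotation still has det +1
  expect_equal(det(kabsch(a, b)$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(a[1:3, ], a), "equal length")
  expect_error(kabsch(a[1:2, ], a[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("kabsch agrees with the quaternion-eigenvalue oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    a <- matrix(rnorm(n * 3), ncol = 3) * 5
    b <- sweep(a %*% t(random_rotation()), 2, rnorm(3, 0, 10), "+") +
      matrix(rnorm(n * 3, 0, 0.2), ncol = 3)
    expect_lt(abs(kabsch(a, b)$rmsd - quaternion_rmsd(a, b)), 1e-6)
  }
})

test_that("d0 follows the standard TM normalisation with a 0.5 A floor", {
  expect_equal(tm_d0(21), 0.5)   # 1.24 * 6^(1/3) - 1.8 < 0.5, so floored
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8)
  expect_lt(tm_d0(50), tm_d0(200))
  expect_error(tm_params(0), "l_norm")
})

test_that("tm_score matches its formula on fixed deviations", {
  p <- tm_params(30)
  expect_equal(tm_score(rep(0, 30), p), 1)
  expect_equal(tm_score(rep(p$d0, 30), p), 0.5)
  expect_error(tm_score(numeric(0), p), "pair")
  expect_error(tm_score(c(1, -2), p), "non-negative")
})

test_that("self-alignment is exact and rigid copies align fully", {
  d <- make_c2_dimer(seed = 7)
  half <- split_trace(d$trace, d$truth$half_length)$n
  aln <- align_traces(half, half)
  expect_equal(nrow(aln$pairs), length(half))
  expect_identical(aln$pairs[, 1], aln$pairs[, 2])
  expect_equal(aln$tm_score, 1, tolerance = 1e-9)
  expect_lt(max(aln$deviations), 1e-6)
  # rigidly moved copy
  moved <- half
  moved$coords <- sweep(half$coords %*% t(random_rotation()), 2,
                        c(10, -4, 2), "+")
  aln2 <- align_traces(half, moved)
  expect_equal(nrow(aln2$pairs), length(half))
  expect_lt(aln2$superposition$rmsd, 1e-6)
  expect_error(align_traces(get_trace(half, residue_range = c(1, 10)), half),
               "15")
})

test_that("alignment of a noisy copy recovers the planted correspondence", {
  d <- make_c2_dimer(seed = 13)
  half <- split_trace(d$trace, d$truth$half_length)$n
  noisy <- half
  set.seed(99)
  # 0.5 A expected 3-D displacement per atom (sd 0.5/sqrt(3) per coordinate)
  noisy$coords <- half$coords +
    matrix(stats::rnorm(length(half$coords), 0, 0.5 / sqrt(3)), ncol = 3)
  aln <- align_traces(half, noisy)
  planted <- sum(aln$pairs[, 1] == aln$pairs[, 2])
  expect_gte(planted / length(half), 0.95)
  core <- common_core(aln, 4)
  expect_gte(core$core_rmsd, 0.3)
  expect_lte(core$core_rmsd, 0.8)
})

test_that("alignment TM-score is symmetric under trace exchange", {
  d <- make_c2_dimer(noise_sd = 0.4, seed = 21)
  h <- split_trace(d$trace, d$truth$split)
  p <- tm_params(min(length(h$n), length(h$c)))
  t_ab <- align_traces(h$n, h$c, params = p)$tm_score
  t_ba <- align_traces(h$c, h$n, params = p)$tm_score
  expect_equal(t_ab, t_ba, tolerance = 1e-3)
})

test_that("common core thresholds deviations and refits on survivors", {
  # five pairs with known deviations 1,2,3,5,6 A under the stored superposition
  base <- make_c2_dimer(seed = 3)$trace
  a <- get_trace(base, residue_range = c(1, 20))
  b <- a
  dev <- c(rep(0, 15), 1, 2, 3, 5, 6)
  b$coords <- a$coords + outer(dev, c(1, 0, 0))
  aln <- structure(list(a = a, b = b, pairs = cbind(1:20, 1:20),
                        deviations = dev,
                        superposition = structure(
                          list(rotation = diag(3), translation = c(0, 0, 0),
                               rmsd = sqrt(mean(dev^2))),
                          class = "superposition"),
                        tm_score = 0.9, params = tm_params(20)),
                   class = "structaln")
  core <- common_core(aln, cutoff = 4)
  expect_equal(core$core_size, 18L)   # the 5 A and 6 A pairs are dropped
  expect_false(core$empty)
  expect_true(all(core$deviations < 4))
  # nothing below the cutoff: empty core, flagged, not an error
  all_off <- aln
  all_off$deviations <- seq(1, 5.75, by = 0.25)   # every pair >= 1 A
  core0 <- common_core(all_off, cutoff = 0.5)
  expect_true(core0$empty)
  expect_identical(core0$core_size, 0L)
  expect_true(is.na(core0$core_rmsd))
})

test_that("common core size is monotone in the cutoff", {
  d <- make_c2_dimer(noise_sd = 1.5, seed = 31)
  h <- split_trace(d$trace, d$truth$split)
  aln <- align_traces(h$n, h$c)
  sizes <- vapply(c(0.5, 1, 2, 3, 4, 6, 10), function(cut)
    common_core(aln, cut)$core_size, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("alignment export writes consistent tables and models", {
  d <- make_c2_dimer(noise_sd = 0.3, seed = 8)
  h <- split_trace(d$trace, d$truth$split)
  aln <- align_traces(h$n, h$c)
  tab <- alignment_table(aln)
  expect_equal(nrow(tab), nrow(aln$pairs))
  expect_true(all(diff(tab$resid_a) > 0) && all(diff(tab$resid_b) > 0))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_superposed_pdb(aln, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(grepl("^MODEL", lines)), 2L)
  expect_equal(sum(grepl("^ATOM", lines)), length(h$n) + length(h$c))
})
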