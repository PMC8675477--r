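# Identity statistics, shuffled null, conservation, consensus, logos.

two_group_msa <- function(rows_a, rows_b) {
  msa(ids = c(paste0("a", seq_along(rows_a)), paste0("b", seq_along(rows_b))),
      rows = c(rows_a, rows_b),
      group = rep(c("A", "B"), c(length(rows_a), length(rows_b))))
}

test_that("percent identity follows the co-occupied-column definition", {
  m <- two_group_msa("ACDE", "ACDE")
  expect_equal(pairwise_identity(m, "A", "B")$mean_pct, 100)
  m2 <- two_group_msa("ACDE", "ACDF")
  expect_equal(pairwise_identity(m2, "A", "B")$mean_pct, 75)
  # gaps drop out of the denominator; X never matches even against X
  m3 <- two_group_msa("AC-EX", "ACDEX")
  expect_equal(pairwise_identity(m3, "A", "B")$mean_pct, 100 * 3 / 4)
  mx <- two_group_msa("XXXX", "XXXX")
  expect_equal(pairwise_identity(mx, "A", "B")$mean_pct, 0)
  # identity is direction-symmetric
  m4 <- two_group_msa(c("ACDEFG", "AKDEFG"), c("ACDEYG", "PCDEFG"))
  i_ab <- pairwise_identity(m4, "A", "B")$matrix
  i_ba <- pairwise_identity(m4, "B", "A")$matrix
  expect_equal(i_ab, t(i_ba))
  # a pair with no co-occupied columns is skipped with a warning
  m5 <- two_group_msa("AC--", "--DE")
  expect_error(suppressWarnings(pairwise_identity(m5, "A", "B")),
               "no comparable pairs")
})

test_that("re-alignment mode recovers identity across register shifts", {
  # the same non-repetitive motif at different offsets: columnwise identity
  # misses it entirely, re-alignment finds it
  m <- two_group_msa("ACDEFGHIKLMNPQRSTVWY-", "-ACDEFGHIKLMNPQRSTVWY")
  from_msa <- pairwise_identity(m, "A", "B", mode = "from_msa")$mean_pct
  realigned <- pairwise_identity(m, "A", "B", mode = "pairwise_realign")$mean_pct
  expect_equal(from_msa, 0)
  expect_equal(realigned, 100)
})

test_that("shuffling preserves composition exactly", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    s <- paste(sample(c(pseudosym:::AA20, "-"), n, replace = TRUE),
               collapse = "")
    sh <- with_seed(i, shuffle_residues(s))
    expect_identical(sort(strsplit(sh, "")[[1]]), sort(strsplit(s, "")[[1]]))
    # gap positions are fixed
    expect_identical(gregexpr("-", sh)[[1]], gregexpr("-", s)[[1]])
  }
})

test_that("the shuffled null matches the composition expectation", {
  set.seed(11)
  sa <- paste(sample(pseudosym:::AA20, 200, replace = TRUE), collapse = "")
  sb <- paste(sample(pseudosym:::AA20, 200, replace = TRUE), collapse = "")
  m <- two_group_msa(sa, sb)
  null <- shuffled_identity_null(m, "A", "B", n_reps = 100, seed = 3,
                                 mode = "from_msa")
  fa <- table(factor(strsplit(sa, "")[[1]], pseudosym:::AA20)) / 200
  fb <- table(factor(strsplit(sb, "")[[1]], pseudosym:::AA20)) / 200
  analytic <- 100 * sum(fa * fb)
  se <- null$sd_pct / sqrt(null$n_reps)
  expect_lt(abs(null$mean_pct - analytic), 3 * se)
  # deterministic under a fixed seed
  null2 <- shuffled_identity_null(m, "A", "B", n_reps = 100, seed = 3,
                                  mode = "from_msa")
  expect_identical(null$mean_pct, null2$mean_pct)
})

test_that("excess identity converts identity differences to residue counts", {
  expect_equal(as.integer(excess_identity(12.5, 9.3, 200)), 6L)
  expect_equal(as.integer(excess_identity(10, 10, 200)), 0L)
  expect_equal(as.integer(excess_identity(20, 10, 100)), 10L)
  neg <- excess_identity(8, 12, 200)
  expect_lt(neg, 0)
  expect_true(isTRUE(attr(neg, "negative")))
  expect_error(excess_identity(10, 9, 0), "per_length")
})

test_that("conservation is 1 for invariant and 0 for uniform columns", {
  m <- msa(paste0("s", 1:20),
           vapply(1:20, function(i)
             paste0("G", pseudosym:::AA20[i], "-"), character(1)))
  cc <- column_conservation(m)
  expect_equal(cc$conservation[1], 1)
  expect_equal(cc$conservation[2], 0)
  expect_true(is.na(cc$conservation[3]))
  expect_true(cc$low_confidence[3])
  cg <- column_conservation(m, grades = TRUE)
  expect_equal(cg$grade[1], 9L)
  expect_equal(cg$grade[2], 1L)
})

test_that("conservation tracks planted column diversity", {
  # column j uses k_j equiprobable residues; conservation must fall with k
  set.seed(5)
  ks <- sample(1:20, 30, replace = TRUE)
  rows <- vapply(1:60, function(i)
    paste(vapply(ks, function(k)
      pseudosym:::AA20[sample.int(k, 1)], character(1)), collapse = ""),
    character(1))
  cc <- column_conservation(msa(paste0("r", 1:60), rows))
  rho <- suppressWarnings(cor(ks, cc$conservation, method = "spearman"))
  expect_lt(rho, -0.95)
})

test_that("consensus picks modal residues, breaks ties lexicographically", {
  m <- msa(paste0("s", 1:4), c("AAC-", "AACC", "ACC-", "CA--"))
  cons <- consensus(m)
  expect_identical(as.character(cons), "AACC")   # col 1: {A:3, C:1} -> A
  tied <- consensus(msa(c("a", "b"), c("AA", "AC")))
  expect_identical(as.character(tied), "AA")     # tie {A,C} -> lexicographic
  expect_identical(attr(tied, "ties"), 2L)
  m2 <- msa(c("a", "b"), c("A-", "A-"))
  expect_identical(as.character(consensus(m2)), "A-")
  expect_identical(attr(consensus(m2), "all_gap"), 2L)
})

test_that("consensus identity over masked sites recovers a planted fraction", {
  cons_a <- paste(rep(c("A", "C", "D", "E"), 10), collapse = "")
  cons_b <- cons_a
  v <- strsplit(cons_b, "")[[1]]
  v[11:40] <- "W"          # 10 of 40 masked sites identical -> 25%
  cons_b <- paste(v, collapse = "")
  expect_equal(consensus_identity(cons_a, cons_b, 1:40), 25)
  expect_error(consensus_identity(cons_a, cons_b, integer(0)), "empty")
  expect_error(consensus_identity(cons_a, cons_b, 1:99), "range")
})

test_that("logo information content follows the entropy arithmetic", {
  m <- msa(paste0("s", 1:20),
           vapply(1:20, function(i)
             paste0("G", c("A", "C")[1 + (i %% 2)], pseudosym:::AA20[i]),
             character(1)))
  lg <- logo_information(m)
  expect_equal(lg$ic[1], log2(20))
  expect_equal(lg$ic[2], log2(20) - 1)     # 50/50 two-residue column
  expect_equal(lg$ic[3], 0)                # uniform over all 20
  expect_equal(sum(lg$heights[, 1] > 0), 1L)
  expect_equal(unname(lg$heights["G", 1]), log2(20))
})

test_that("conservation falls and IC falls as column entropy rises", {
  ks <- c(1, 2, 5, 10, 20)
  rows <- vapply(1:40, function(i)
    paste(vapply(ks, function(k)
      pseudosym:::AA20[1 + ((i - 1) %% k)], character(1)), collapse = ""),
    character(1))
  m <- msa(paste0("r", 1:40), rows)
  cc <- column_conservation(m)$conservation
  ic <- logo_information(m)$ic
  expect_true(all(diff(cc) < 0))
  expect_true(all(diff(ic) < 0))
})

test_that("aligned FASTA round-trips through read_msa with groups", {
  m <- make_msa_pair(n_rows_per_group = 3, length = 40, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_msa(m, tmp)
  back <- read_msa(tmp, group_pattern = c(A = "^A", B = "^B"))
  expect_identical(back$rows, m$rows)
  expect_identical(back$group, m$group)
  expect_error(read_msa(file.path(tempdir(), "absent.fasta")), "not found")
})
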