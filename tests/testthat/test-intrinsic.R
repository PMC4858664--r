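test_that("raw scores follow the z-scored combination formula", {
  s <- as_sequence(strrep("A", 8))
  r <- raw_residue_scores(s)
  expect_true(all(abs(r - r[1]) < 1e-12))          # constant input

  pv <- raw_residue_scores(as_sequence(strrep("V", 8)))
  ps <- raw_residue_scores(as_sequence(strrep("S", 8)))
  expect_gt(pv[1], ps[1])                          # hydrophobic beats polar

  # direct evaluation of the stated formula, independent of the package path
  sc <- default_scales()
  z <- function(v) (v[aggscape:::AA1] - mean(v[aggscape:::AA1])) /
    sd(v[aggscape:::AA1])
  manual <- 1.0 * z(sc$hydropathy)[["V"]] + 0.4 * z(sc$beta)[["V"]] -
    0.2 * z(sc$alpha)[["V"]] - 0.8 * z(abs(sc$charge))[["V"]]
  expect_equal(pv[1], manual, tolerance = 1e-12)

  # flipping the sign of the charge weight reverses the K-vs-V gap direction
  pk <- raw_residue_scores(as_sequence(strrep("K", 8)))
  p_noch <- profile_params(w_chg = -0.8)
  pk2 <- raw_residue_scores(as_sequence(strrep("K", 8)), params = p_noch)
  pv2 <- raw_residue_scores(as_sequence(strrep("V", 8)), params = p_noch)
  expect_lt(pk[1], pv[1])
  expect_gt(pk2[1] - pk[1], 0)                     # charged residue gains
  expect_lt(pv2[1] - pv[1], 0)                     # uncharged residue loses
})

test_that("smoothing is a truncated centred moving average", {
  x <- c(5, 1, 4, 1, 5)
  expect_equal(smooth_profile(x, 1), x)            # window 1 = identity
  expect_equal(smooth_profile(rep(2, 6), 5), rep(2, 6))
  expect_equal(smooth_profile(c(0, 0, 7, 0, 0), 3),
               c(0, 7 / 3, 7 / 3, 7 / 3, 0))
  expect_error(smooth_profile(x, 4), class = "aggscape_parameter_error")
  expect_error(smooth_profile(x, 7), class = "aggscape_parameter_error")
  # interior sum conservation: full-window positions preserve the mean
  set.seed(3)
  y <- rnorm(30)
  sm <- smooth_profile(y, 5)
  expect_equal(sm[10], mean(y[8:12]))
})

test_that("gatekeeper correction counts charged neighbours and never raises", {
  s <- as_sequence("SSEVKSS")
  v <- rep(1, 7)
  expect_equal(gatekeeper_correction(v, s, 0, 3), v)
  corr <- gatekeeper_correction(v, s, 0.15, 3)
  # residue 4 (V) has E at -1 and K at +1: lowered by 2 * 0.15
  expect_equal(corr[4], 1 - 0.30)
  expect_true(all(corr <= v + 1e-15))
  nochg <- as_sequence("SSTVTSS")
  expect_equal(gatekeeper_correction(v, nochg, 0.15, 3), v)
})

test_that("total score is the residue mean", {
  expect_equal(total_score(rep(0.7, 5)), 0.7)
  expect_equal(total_score(c(-1, 0, 1)), 0)
  set.seed(4)
  x <- rnorm(20)
  expect_equal(total_score(x), total_score(sample(x)))
  expect_error(total_score(numeric(0)), class = "aggscape_input_error")
})

test_that("aggregation-prone regions are maximal runs above threshold", {
  expect_identical(nrow(aggregation_prone_regions(c(0.2, 0.9, 1.0))), 0L)
  r <- aggregation_prone_regions(c(0.5, 1.2, 1.3, 0.9, 1.1))
  expect_equal(r$start, c(2, 5))
  expect_equal(r$end, c(3, 5))
  expect_equal(r$peak, c(1.3, 1.1))
  all_in <- aggregation_prone_regions(c(0.5, 1.2, 0.9), threshold = -Inf)
  expect_equal(c(all_in$start, all_in$end), c(1, 3))
})

test_that("the intrinsic profile is a pure function of sequence and params", {
  s <- make_sequence(synth_spec(seed = 21))
  p1 <- intrinsic_profile(s)
  p2 <- intrinsic_profile(s)
  expect_identical(p1, p2)
  expect_identical(p1$kind, "intrinsic")
  expect_equal(p1$total, mean(p1$values))
})

test_that("more hydrophobic, less charged substitutions never lower the total", {
  # exhaustive 20 x 20 check at the centre of a 15-mer: if the substituting
  # residue dominates the original on every term of the raw formula, the
  # total intrinsic score must not decrease
  sc <- default_scales()
  z <- function(v) (v[aggscape:::AA1] - mean(v[aggscape:::AA1])) /
    sd(v[aggscape:::AA1])
  zh <- z(sc$hydropathy); zb <- z(sc$beta)
  za <- z(sc$alpha); zc <- z(abs(sc$charge))
  base <- "STQNSGA"
  for (a in aggscape:::AA1) {
    seq_a <- as_sequence(paste0(base, a, base))
    tot_a <- intrinsic_profile(seq_a)$total
    for (b in aggscape:::AA1) {
      dominates <- zh[b] >= zh[a] && zb[b] >= zb[a] &&
        za[b] <= za[a] && zc[b] <= zc[a]
      if (!dominates) next
      seq_b <- as_sequence(paste0(base, b, base))
      expect_gte(intrinsic_profile(seq_b)$total, tot_a - 1e-12)
    }
  }
})
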