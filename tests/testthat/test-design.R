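test_that("candidate selection applies both thresholds exactly", {
  intr <- c(1.2, 1.2, 0.5, 1.5, 0.9)
  ca <- c(0.8, 0.8, 0.9, 0.1, 0.5)
  cb <- c(0.5, 0.7, 0.4, 0.4, 0.1)    # deltas: 0.3, 0.1, 0.5, -0.3, 0.4
  sel <- candidate_sites(intr, ca, cb)
  expect_equal(sel$site, c(1, 4))      # 2 fails |delta|, 3 & 5 fail intrinsic
  expect_equal(sel$delta_corrected, c(0.3, -0.3))
  # boundary values are strict inequalities
  none <- candidate_sites(c(1.0), c(0.2), c(0.0))
  expect_identical(nrow(none), 0L)
  expect_error(candidate_sites(intr, ca, cb[-1]),
               class = "aggscape_input_error")
})

test_that("saturation scans recompute the full pipeline per substitution", {
  s <- make_sequence(synth_spec(seed = 17))
  sc <- scan_site(s, 18)
  expect_identical(nrow(sc$table), 19L)
  expect_false(sc$wt %in% sc$table$residue)

  # mutate then revert reproduces the reference total exactly
  mut <- s; mut$residues[18] <- "E"
  back <- scan_site(mut, 18)
  expect_equal(back$table$delta[back$table$residue == sc$wt],
               -sc$table$delta[sc$table$residue == "E"], tolerance = 1e-12)

  # independent full-pipeline oracle for one substitution
  delta_E <- intrinsic_profile(mut)$total - intrinsic_profile(s)$total
  expect_equal(sc$table$delta[sc$table$residue == "E"], delta_E,
               tolerance = 1e-14)

  # hydrophobic -> charged at a hot spot protects; polar -> hydrophobic
  # at an exposed site promotes
  expect_lt(sc$table$delta[sc$table$residue == "E"], 0)
  sc_bg <- scan_site(s, 5)             # polar background site
  expect_gt(sc_bg$table$delta[sc_bg$table$residue == "V"], 0)
  expect_error(scan_site(s, 99), class = "aggscape_input_error")
})

test_that("rankings sort by delta with the deterministic tie-break", {
  mk <- function(site, wt, residues, deltas) {
    structure(list(site = site, wt = wt, reference_total = 0,
                   table = data.frame(residue = residues, delta = deltas)),
              class = "mutation_scan")
  }
  scans <- list(mk(2, "V", c("A", "E"), c(-0.3, 0.2)),
                mk(1, "L", c("D", "K"), c(-0.1, -0.3)))
  prot <- rank_designs(scans, "protect")
  expect_equal(prot$delta[1:2], c(-0.3, -0.3))
  expect_equal(prot$site[1:2], c(1, 2))          # tie -> lower site first
  expect_identical(prot$mutation[1], "L1K")
  prom <- rank_designs(scans, "promote")
  expect_identical(prom$mutation[1], "V2E")
  expect_error(rank_designs(list()), class = "aggscape_input_error")

  same <- list(mk(3, "V", c("C", "A"), c(0.5, 0.5)))
  r <- rank_designs(same, "promote")
  expect_equal(r$residue, c("A", "C"))           # alphabetical tie-break
})

test_that("box statistics use linear-interpolation quantiles", {
  b <- box_stats(1:5)
  expect_equal(b$median, 3)
  expect_equal(b$q1, 2)
  expect_equal(b$q3, 4)
  expect_equal(b$p5, unname(quantile(1:5, 0.05)))
  expect_equal(b$p95, unname(quantile(1:5, 0.95)))

  cst <- box_stats(rep(2.5, 7))
  expect_true(all(unlist(cst[c("p5", "q1", "median", "q3", "p95")]) == 2.5))
  expect_error(box_stats(numeric(0)), class = "aggscape_input_error")

  set.seed(51)
  for (k in 1:200) {
    b <- box_stats(rnorm(sample(3:50, 1)))
    expect_true(b$p5 <= b$q1 && b$q1 <= b$median &&
                b$median <= b$q3 && b$q3 <= b$p95)
  }
})

test_that("the design driver wires selection, scans and statistics together", {
  pair <- test_pair()
  intr <- intrinsic_profile(pair$sequence)
  a <- ensemble_average_profile(pair$A, intr)
  b <- ensemble_average_profile(pair$B, intr)
  # thresholds scaled to the synthetic fixture's corrected-score range
  rep <- design_mutations(intr, a$profile, b$profile,
                          intrinsic_threshold = 1.0,
                          delta_threshold = 0.1)
  expect_gt(nrow(rep$sites), 0)
  expect_true(all(rep$sites$site %in% 11:23))   # hot spot +/- window spill
  expect_identical(nrow(rep$protective),
                   nrow(rep$sites) * 19L)
  top <- rep$protective[1, ]
  expect_true(top$residue %in% c("D", "E", "K", "R"))
  expect_s3_class(rep$box_pooled, "box_stats")
  expect_length(rep$box_per_site, nrow(rep$sites))
})
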