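test_that("the structural correction reduces to the intrinsic profile when fully exposed", {
  pair <- test_pair()
  st <- pair$A$structures[[1]]
  intr <- intrinsic_profile(pair$sequence)
  n <- length(intr$values)
  ident <- corrected_profile(intr, st, kernel_params(sigma_d = 0),
                             exposure = rep(1, n))
  expect_equal(ident$values, intr$values, tolerance = 1e-12)
})

test_that("a buried residue is fully protected and burial acts monotonically", {
  pair <- test_pair()
  st <- pair$A$structures[[1]]
  intr <- intrinsic_profile(pair$sequence)
  n <- length(intr$values)
  hs <- 14:20
  peak_at <- function(e_hot) {
    e <- rep(1, n); e[hs] <- e_hot
    max(corrected_profile(intr, st, exposure = e)$values[hs])
  }
  expect_equal({
    e <- rep(1, n); e[17] <- 0
    corrected_profile(intr, st, exposure = e)$values[17]
  }, 0)
  p1 <- peak_at(1); p05 <- peak_at(0.5); p01 <- peak_at(0.1)
  expect_gt(p1, p05)
  expect_gt(p05, p01)
  # correction never amplifies beyond the largest intrinsic magnitude
  full <- corrected_profile(intr, st)
  expect_lte(max(abs(full$values)), max(abs(intr$values)) + 1e-12)
})

test_that("ensemble mean of totals equals total of the mean profile", {
  pair <- test_pair()
  intr <- intrinsic_profile(pair$sequence)
  es <- ensemble_average_profile(pair$A, intr)
  expect_equal(es$mean, total_score(es$profile$values), tolerance = 1e-12)
  expect_equal(es$mean, sum(es$weights * es$per_conformation),
               tolerance = 1e-12)
  expect_gte(es$se, 0)
  expect_true(es$mean >= min(es$per_conformation) - 1e-12 &&
              es$mean <= max(es$per_conformation) + 1e-12)
})

test_that("identical conformations give SE zero with a single-conformation warning path", {
  st <- build_chain("STVVLNQ")
  ens <- as_ensemble(list(st, st, st))
  intr <- intrinsic_profile(extract_sequence(st))
  es <- ensemble_average_profile(ens, intr)
  expect_equal(es$se, 0, tolerance = 1e-12)
  single <- as_ensemble(list(st))
  expect_warning(es1 <- ensemble_average_profile(single, intr),
                 "single conformation")
  expect_identical(es1$se, 0)
  expect_true(es1$single)
})

test_that("the protected variant scores lower on the shared fixture", {
  pair <- test_pair()
  intr <- intrinsic_profile(pair$sequence)
  a <- ensemble_average_profile(pair$A, intr)
  b <- ensemble_average_profile(pair$B, intr)
  expect_lt(b$mean, a$mean)
  # and the gap is concentrated on the hot spot
  hs <- 14:20
  expect_gt(mean(a$profile$values[hs] - b$profile$values[hs]),
            mean(a$profile$values[-hs] - b$profile$values[-hs]))
})

test_that("strand populations are the weighted beta fractions", {
  hp <- test_hairpin()
  ext <- build_chain(extract_sequence(hp))   # same composition, unfolded
  strands <- data.frame(label = c("S1", "S2"),
                        start = c(2, 8), end = c(5, 11))
  pop_h <- strand_beta_populations(as_ensemble(list(hp)), strands)
  expect_true(all(pop_h$population == 1))
  helix_ens <- as_ensemble(list(test_helix()))
  pop_x <- strand_beta_populations(helix_ens,
                                   data.frame(label = "S", start = 2,
                                              end = 11))
  expect_equal(pop_x$population, 0)
  # 50/50 mixture of folded and unfolded conformations
  mix <- as_ensemble(list(hp, ext))
  pop_m <- strand_beta_populations(mix, strands)
  expect_equal(pop_m$population, c(0.5, 0.5))

  expect_error(strand_beta_populations(mix, data.frame(
    label = c("a", "b"), start = c(2, 4), end = c(5, 7))),
    class = "aggscape_input_error")
})

test_that("RMSF is zero for rigid-body motion and localises planted wobble", {
  st <- build_chain(strrep("V", 15))
  rot <- aggscape:::axis_angle_matrix(c(0, 1, 1), 0.7)
  at <- st$atoms
  co <- aggscape:::apply_rigid(as.matrix(at[, c("x", "y", "z")]), rot,
                               c(3, 3, -2))
  at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  rotated <- aggscape:::new_structure(at)
  r <- rmsf_profile(as_ensemble(list(st, rotated)))
  expect_lt(max(r$rmsf), 1e-6)

  dup <- rmsf_profile(as_ensemble(list(st, st, st)))
  expect_lt(max(dup$rmsf), 1e-12)
  expect_error(rmsf_profile(as_ensemble(list(st))),
               class = "aggscape_input_error")

  # wobble of ~1 A planted on residues 7:9 only
  set.seed(31)
  wob <- lapply(1:8, function(k) {
    a <- st$atoms
    sel <- a$resno %in% 7:9
    a$z[sel] <- a$z[sel] + rnorm(1, sd = 1)
    aggscape:::new_structure(a)
  })
  rw <- rmsf_profile(as_ensemble(wob))
  expect_gt(min(rw$rmsf[7:9]), max(rw$rmsf[c(1:4, 12:15)]) * 3)
})
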