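# Synthetic-data generation with known ground truth: sequences with
# planted hydrophobic hot spots (optionally flanked by charged
# gatekeepers) and ensemble pairs in which the hot spot's mean solvent
# exposure is shifted between two variants by geometrically packing the
# chain's own flanking segments against it.

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

POLAR_BACKGROUND <- c("S", "T", "N", "Q", "G")
HOTSPOT_RESIDUES <- c("V", "I", "L", "F")

#' Specification of a synthetic benchmark instance
#'
#' Defines everything the generator needs: sequence layout, ensemble
#' size, per-variant solvent-exposure targets over the hot spot,
#' coordinate noise, and the seed fixing all randomness.
#'
#' @param length Sequence length (residues).
#' @param hotspot_start,hotspot_end Planted hydrophobic hot-spot window
#'   (1-based inclusive).
#' @param gatekeepers Place charged gatekeepers (D/E/K/R) at the window
#'   flanks.
#' @param n_conformations Conformations per ensemble (>= 10 for ensemble
#'   pairs).
#' @param burial Length-2 numeric: target mean relative exposure over the
#'   hot spot for variants A and B (A exposed, B protected; both in
#'   [0, 1]).
#' @param noise Gaussian coordinate noise amplitude (Angstrom, per
#'   coordinate).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(length = 40, hotspot_start = 16, hotspot_end = 22,
                       gatekeepers = FALSE, n_conformations = 12,
                       burial = c(A = 0.50, B = 0.30), noise = 0.3,
                       seed = 1) {
  if (hotspot_start < 2 || hotspot_end >= length ||
      hotspot_start > hotspot_end) {
    parameter_error("hot-spot window outside sequence")
  }
  if (any(burial < 0) || any(burial > 1)) {
    parameter_error("burial targets must be in [0, 1]")
  }
  structure(list(length = as.integer(length),
                 hotspot_start = as.integer(hotspot_start),
                 hotspot_end = as.integer(hotspot_end),
                 gatekeepers = isTRUE(gatekeepers),
                 n_conformations = as.integer(n_conformations),
                 burial = stats::setNames(as.numeric(burial), c("A", "B")),
                 noise = noise, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a sequence with a planted hot spot
#'
#' Background residues are drawn from the polar set (S, T, N, Q, G), the
#' hot-spot window is filled from the hydrophobic set (V, I, L, F), and,
#' if requested, charged gatekeepers are placed at the window flanks.
#' Deterministic under the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return An `agg_sequence`.
#' @export
make_sequence <- function(spec) {
  with_seed(spec$seed, {
    res <- sample(POLAR_BACKGROUND, spec$length, replace = TRUE)
    hs <- spec$hotspot_start:spec$hotspot_end
    res[hs] <- sample(HOTSPOT_RESIDUES, length(hs), replace = TRUE)
    if (spec$gatekeepers) {
      res[spec$hotspot_start - 1L] <- sample(CHARGED_RESIDUES, 1)
      if (spec$hotspot_end + 1L <= spec$length) {
        res[spec$hotspot_end + 1L] <- sample(CHARGED_RESIDUES, 1)
      }
    }
    as_sequence(res, id = sprintf("synth-seed%d", spec$seed))
  })
}

# Move the atoms of residues `segment` rigidly so the segment lies
# parallel to the hot spot, displaced by `h * direction` from its centre.
place_occluder <- function(atoms, segment, hotspot, h, direction) {
  seg_rows <- atoms$resno %in% segment
  hs_rows <- atoms$resno %in% hotspot
  seg_centroid <- colMeans(as.matrix(atoms[seg_rows, c("x", "y", "z")]))
  hs_centroid <- colMeans(as.matrix(atoms[hs_rows, c("x", "y", "z")]))
  shift <- hs_centroid + h * direction - seg_centroid
  atoms$x[seg_rows] <- atoms$x[seg_rows] + shift[1]
  atoms$y[seg_rows] <- atoms$y[seg_rows] + shift[2]
  atoms$z[seg_rows] <- atoms$z[seg_rows] + shift[3]
  atoms
}

hotspot_exposure <- function(structure, hotspot, n_points = 192) {
  s <- shrake_rupley_sasa(structure, n_points = n_points)
  rt <- residue_table(structure)
  hs <- rt$resno %in% hotspot
  mean(relative_exposure(s$residue$sasa[hs], rt$code[hs]))
}

# Occluder layout: the N- and C-terminal flanking segments, split in
# half, packed around the hot spot (above, below and on both sides).
occluder_layout <- function(spec) {
  n <- spec$length
  flank_n <- 1:max(3, spec$hotspot_start - 6L)
  flank_c <- min(n - 2L, spec$hotspot_end + 6L):n
  halves <- function(v) {
    k <- length(v) %/% 2
    list(v[seq_len(k)], v[(k + 1):length(v)])
  }
  fn <- halves(flank_n)
  fc <- halves(flank_c)
  list(segments = list(fn[[1]], fn[[2]], fc[[1]], fc[[2]]),
       directions = list(c(0, 0, 1), c(0, 1, 0), c(0, 0, -1),
                         c(0, -1, 0)))
}

# Apply the occluder layout to a (noisy) base atom table at distance h.
pack_occluders <- function(atoms, spec, h, id) {
  hs <- spec$hotspot_start:spec$hotspot_end
  lay <- occluder_layout(spec)
  for (k in seq_along(lay$segments)) {
    atoms <- place_occluder(atoms, lay$segments[[k]], hs, h,
                            lay$directions[[k]])
  }
  new_structure(atoms, id = id)
}

# Find the occluder distance h achieving the target mean hot-spot
# exposure by bisection on a fixed noisy base conformation; errors if the
# target is below what full packing reaches.
calibrate_height <- function(base_atoms, spec, target, id,
                             tol = 0.015, h_range = c(4, 40),
                             max_iter = 18) {
  hs <- spec$hotspot_start:spec$hotspot_end
  e_at <- function(h) {
    hotspot_exposure(pack_occluders(base_atoms, spec, h, id), hs)
  }
  e_lo <- e_at(h_range[1])   # most buried
  e_hi <- e_at(h_range[2])   # most exposed
  if (target > e_hi) return(list(h = h_range[2], e = e_hi))
  if (target < e_lo - tol) {
    input_error(sprintf(
      "burial target %.3f unreachable: most-packed exposure is %.3f",
      target, e_lo))
  }
  lo <- h_range[1]; hi <- h_range[2]
  e_mid <- e_lo; mid <- lo
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    e_mid <- e_at(mid)
    if (abs(e_mid - target) < tol) break
    if (e_mid > target) hi <- mid else lo <- mid
  }
  list(h = mid, e = e_mid)
}

#' Generate a pair of ensembles with a planted protection shift
#'
#' Both ensembles perturb the same idealized extended chain with Gaussian
#' coordinate noise; in each conformation the chain's own N- and
#' C-terminal flanking segments are rigidly packed above and below the
#' hot spot, with the packing distance calibrated per conformation so the
#' mean relative solvent exposure over the hot-spot residues matches the
#' variant's burial target (variant A exposed, variant B protected).
#' Burial is achieved geometrically, so the full SASA -> correction ->
#' averaging path is exercised.  Fully deterministic under the spec seed.
#'
#' @param spec A [synth_spec()]; benchmark ensembles use
#'   `n_conformations >= 10` (smaller sizes are accepted for quick
#'   exploratory runs).
#' @return A list: `sequence`, `A` and `B` (`agg_ensemble`s), and
#'   `ground_truth` (targets, per-conformation achieved exposures, their
#'   means, and the achieved exposure difference).
#' @export
make_ensemble_pair <- function(spec) {
  sequence <- make_sequence(spec)
  base <- build_chain(sequence, BETA_PHI, BETA_PSI, id = "base")
  n_atoms <- nrow(base$atoms)
  with_seed(spec$seed + 1L, {
    out <- list(sequence = sequence)
    achieved <- list()
    for (v in c("A", "B")) {
      structures <- vector("list", spec$n_conformations)
      e_vec <- numeric(spec$n_conformations)
      for (m in seq_len(spec$n_conformations)) {
        at <- base$atoms
        noise_mat <- matrix(stats::rnorm(n_atoms * 3, sd = spec$noise),
                            ncol = 3)
        at$x <- at$x + noise_mat[, 1]
        at$y <- at$y + noise_mat[, 2]
        at$z <- at$z + noise_mat[, 3]
        id <- sprintf("%s#%d", v, m)
        cal <- calibrate_height(at, spec, spec$burial[[v]], id)
        structures[[m]] <- pack_occluders(at, spec, cal$h, id)
        e_vec[m] <- cal$e
      }
      out[[v]] <- as_ensemble(structures, id = sprintf("synth-%s", v))
      achieved[[v]] <- e_vec
    }
    out$ground_truth <- list(
      hotspot = c(spec$hotspot_start, spec$hotspot_end),
      target_exposure = spec$burial,
      achieved_exposure = achieved,
      mean_exposure = vapply(achieved, mean, 0),
      delta_e_target = spec$burial[["A"]] - spec$burial[["B"]],
      delta_e_achieved = mean(achieved$A) - mean(achieved$B))
    out
  })
}
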