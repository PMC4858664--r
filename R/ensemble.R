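# Structurally corrected profiles and ensemble analytics.
#
# The structural correction gates the intrinsic profile by relative
# solvent exposure and smooths it spatially with an exposure-weighted
# Gaussian kernel over CA-CA distances, so buried aggregation-prone
# residues are treated as protected:
#   corrected_i = e_i * sum_j K(d_ij) I_j e_j / sum_j K(d_ij) e_j,
# K Gaussian with width sigma_d, support limited to a distance cutoff,
# j running over residues within the cutoff including i itself.

#' Spatial-correction kernel parameters
#'
#' @param sigma_d Gaussian width over CA-CA distances (Angstrom).
#' @param cutoff Kernel support cutoff (Angstrom).
#' @param probe_radius,n_points Solvent-accessibility settings passed to
#'   [shrake_rupley_sasa()].
#' @return A list of class `kernel_params`.
#' @export
kernel_params <- function(sigma_d = 5.0, cutoff = 8.0, probe_radius = 1.4,
                          n_points = 192) {
  if (sigma_d < 0 || cutoff <= 0) {
    parameter_error("sigma_d must be >= 0 and cutoff > 0")
  }
  structure(list(sigma_d = sigma_d, cutoff = cutoff,
                 probe_radius = probe_radius, n_points = n_points),
            class = "kernel_params")
}

#' Structurally corrected profile of one conformation
#'
#' Modulates an intrinsic profile by the conformation's relative solvent
#' exposure: exposure gating times exposure-weighted Gaussian spatial
#' smoothing over CA-CA distances.  A fully buried residue (e_i = 0)
#' scores 0 (fully protected); with all e_i = 1 and `sigma_d -> 0` the
#' corrected profile equals the intrinsic one.
#'
#' @param intrinsic An intrinsic `agg_profile` matching the structure's
#'   sequence.
#' @param structure An `agg_structure`.
#' @param params A [kernel_params()] list.
#' @param exposure Optional precomputed per-residue relative exposure
#'   (skips the SASA calculation; used by tests and generators).
#' @return An `agg_profile` with `kind = "corrected"` and the source
#'   conformation id as provenance.
#' @export
corrected_profile <- function(intrinsic, structure, params = kernel_params(),
                              exposure = NULL) {
  seq_s <- extract_sequence(structure)
  if (!identical(seq_s$residues, intrinsic$sequence$residues)) {
    input_error("structure sequence does not match profile sequence")
  }
  n <- length(intrinsic$values)
  if (is.null(exposure)) {
    ep <- exposure_profile(structure, params$probe_radius, params$n_points)
    exposure <- ep$exposure
  }
  if (length(exposure) != n) input_error("exposure/profile length mismatch")
  ca <- t(vapply(seq_len(n), function(i) {
    p <- atom_coord(structure, i, "CA")
    if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else p
  }, numeric(3)))
  missing_ca <- which(!stats::complete.cases(ca))
  if (length(missing_ca) > 0) {
    warning(sprintf("residues without CA excluded from correction: %s",
                    paste(missing_ca, collapse = ",")))
  }
  d <- as.matrix(stats::dist(ca))
  K <- if (params$sigma_d <= 1e-9) {
    diag(n)
  } else {
    exp(-d^2 / (2 * params$sigma_d^2)) * (d <= params$cutoff)
  }
  K[is.na(K)] <- 0
  vals <- numeric(n)
  I <- intrinsic$values
  e <- exposure
  for (i in seq_len(n)) {
    if (i %in% missing_ca || e[i] <= 0) {
      vals[i] <- 0
      next
    }
    w <- K[i, ] * e
    w[missing_ca] <- 0
    denom <- sum(w)
    vals[i] <- if (denom > 0) e[i] * sum(w * I) / denom else 0
  }
  new_profile(intrinsic$sequence, vals, "corrected", params = params,
              provenance = structure$id)
}

#' Ensemble-averaged corrected profile and total scores
#'
#' Computes the structurally corrected profile of every conformation,
#' averages per-residue with the ensemble weights, and summarizes the
#' per-conformation total scores as a weighted mean with a standard
#' error (weighted sd / sqrt(N); 0 with a warning flag for a single
#' conformation).
#'
#' @param ensemble An `agg_ensemble`.
#' @param intrinsic The intrinsic `agg_profile` of the shared sequence.
#' @param params A [kernel_params()] list.
#' @return A list of class `ensemble_scores`: `profile` (the
#'   ensemble-average corrected `agg_profile`, provenance
#'   `"ensemble-average"`), `per_conformation` (numeric totals), `mean`,
#'   `se`, `weights`, and `single` (logical flag).
#' @export
ensemble_average_profile <- function(ensemble, intrinsic,
                                     params = kernel_params()) {
  w <- normalize_weights(ensemble$weights)
  profs <- lapply(ensemble$structures, function(s) {
    corrected_profile(intrinsic, s, params)
  })
  mat <- vapply(profs, function(p) p$values,
                numeric(length(intrinsic$values)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(intrinsic$values))
  avg_vals <- as.vector(mat %*% w)
  totals <- vapply(profs, function(p) p$total, 0)
  m <- sum(w * totals)
  nconf <- length(totals)
  single <- nconf < 2
  se <- if (single) {
    warning("single conformation: standard error reported as 0")
    0
  } else {
    sqrt(sum(w * (totals - m)^2) * nconf / (nconf - 1)) / sqrt(nconf)
  }
  prof <- new_profile(intrinsic$sequence, avg_vals, "corrected",
                      params = params, provenance = "ensemble-average")
  structure(list(profile = prof, per_conformation = totals,
                 mean = m, se = se, weights = w, single = single),
            class = "ensemble_scores")
}

#' @export
print.ensemble_scores <- function(x, ...) {
  cat(sprintf(
    "<ensemble_scores> %d conformations: total corrected score %.4f +/- %.4f\n",
    length(x$per_conformation), x$mean, x$se))
  invisible(x)
}

#' Per-strand beta-structure populations of an ensemble
#'
#' For each strand (label, start, end) the weighted fraction, over
#' conformations and strand residues, of the Kabsch-Sander per-residue
#' beta indicator.
#'
#' @param ensemble An `agg_ensemble`.
#' @param strand_defs Data frame with columns `label`, `start`, `end`
#'   (1-based inclusive, non-overlapping).
#' @return Data frame `label`, `start`, `end`, `population` (in [0, 1]).
#' @export
strand_beta_populations <- function(ensemble, strand_defs) {
  need <- c("label", "start", "end")
  if (!all(need %in% names(strand_defs))) {
    input_error("strand_defs needs label/start/end columns")
  }
  nres <- length(unique(ensemble$structures[[1]]$atoms$resno))
  if (any(strand_defs$start < 1) || any(strand_defs$end > nres) ||
      any(strand_defs$start > strand_defs$end)) {
    input_error("strand ranges outside sequence")
  }
  covered <- unlist(mapply(seq, strand_defs$start, strand_defs$end,
                           SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) input_error("overlapping strand definitions")
  w <- normalize_weights(ensemble$weights)
  beta <- vapply(ensemble$structures, function(s) {
    kabsch_sander_bridges(s)$beta
  }, logical(nres))
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = nres)
  mean_beta <- as.vector(beta %*% w)   # per-residue weighted population
  pop <- mapply(function(s, e) mean(mean_beta[s:e]),
                strand_defs$start, strand_defs$end)
  data.frame(label = strand_defs$label, start = strand_defs$start,
             end = strand_defs$end, population = pop)
}

#' Per-residue RMSF of an ensemble
#'
#' Iteratively superposes every conformation (Kabsch, CA atoms, ensemble
#' weights) onto the weighted mean structure until the mean converges,
#' then reports the weighted root-mean-square fluctuation of each CA.
#'
#' @param ensemble An `agg_ensemble` with >= 2 conformations.
#' @param tol Convergence tolerance on the mean coordinates (Angstrom).
#' @param max_iter Maximum mean-refinement iterations.
#' @return Data frame `resno`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(ensemble, tol = 1e-6, max_iter = 50) {
  if (length(ensemble$structures) < 2) {
    input_error("RMSF needs at least 2 conformations")
  }
  w <- normalize_weights(ensemble$weights)
  ca <- lapply(ensemble$structures, function(s) {
    co <- coords_of(s, elety = "CA")
    if (nrow(co) == 0) input_error("conformation without CA atoms")
    co
  })
  nres <- nrow(ca[[1]])
  if (any(vapply(ca, nrow, 0L) != nres)) {
    input_error("conformations differ in CA count")
  }
  mean_co <- Reduce(`+`, mapply(function(x, wi) x * wi, ca, w,
                                SIMPLIFY = FALSE))
  for (it in seq_len(max_iter)) {
    fitted <- lapply(ca, function(x) superpose_onto(x, mean_co)$coords)
    new_mean <- Reduce(`+`, mapply(function(x, wi) x * wi, fitted, w,
                                   SIMPLIFY = FALSE))
    shift <- max(abs(new_mean - mean_co))
    mean_co <- new_mean
    ca <- fitted
    if (shift < tol) break
  }
  dev2 <- Reduce(`+`, mapply(function(x, wi) {
    wi * rowSums((x - mean_co)^2)
  }, ca, w, SIMPLIFY = FALSE))
  resno <- sort(unique(ensemble$structures[[1]]$atoms$resno))
  data.frame(resno = resno[seq_len(nres)], rmsf = sqrt(dev2))
}
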