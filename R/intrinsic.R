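# Intrinsic (sequence-only) aggregation propensity profiles.
#
# The score is built as a linear combination of z-normalised
# physico-chemical scales (hydropathy, beta propensity, alpha propensity,
# absolute net charge), smoothed with a centred window, reduced by a
# charge-gatekeeper term, and aggregated to a scalar total as the
# residue mean.  Higher values mean higher aggregation propensity; values
# above 1 mark aggregation-prone regions.

#' Default intrinsic-profile parameters
#'
#' @param w_hyd,w_beta,w_alpha,w_chg Combination weights of the
#'   z-normalised hydropathy, beta-sheet, alpha-helix and |charge| scales.
#' @param window Odd smoothing-window width (residues).
#' @param gatekeeper Gatekeeper strength `g` (score units per flanking
#'   charged residue).
#' @param gatekeeper_reach Reach `r_g` of the gatekeeper count (residues
#'   either side).
#' @param aggregation_threshold Profile value above which a residue is
#'   called aggregation-prone.
#' @return A list of class `profile_params`.
#' @export
profile_params <- function(w_hyd = 1.0, w_beta = 0.4, w_alpha = 0.2,
                           w_chg = 0.8, window = 7, gatekeeper = 0.15,
                           gatekeeper_reach = 3,
                           aggregation_threshold = 1.0) {
  if (window < 1 || window %% 2 == 0) {
    parameter_error("smoothing window must be a positive odd integer")
  }
  if (gatekeeper < 0 || gatekeeper_reach < 0) {
    parameter_error("gatekeeper strength and reach must be >= 0")
  }
  if (!is.finite(aggregation_threshold)) {
    parameter_error("aggregation threshold must be finite")
  }
  structure(list(w_hyd = w_hyd, w_beta = w_beta, w_alpha = w_alpha,
                 w_chg = w_chg, window = as.integer(window),
                 gatekeeper = gatekeeper,
                 gatekeeper_reach = as.integer(gatekeeper_reach),
                 aggregation_threshold = aggregation_threshold),
            class = "profile_params")
}

zscore_scale <- function(s) {
  if (!all(AA1 %in% names(s))) config_error("scale missing canonical residues")
  s <- s[AA1]
  (s - mean(s)) / stats::sd(s)
}

#' Raw per-residue aggregation scores
#'
#' Combines the four z-normalised scales as
#' `w_hyd*hyd + w_beta*beta - w_alpha*alpha - w_chg*|charge|`, where each
#' scale (including the absolute charge) is z-scored over the 20-residue
#' alphabet before combination.
#'
#' @param sequence An `agg_sequence`.
#' @param scales A `propensity_scales` list ([default_scales()]).
#' @param params A `profile_params` list (only the weights are used).
#' @return Numeric vector, one raw score per residue.
#' @export
raw_residue_scores <- function(sequence, scales = default_scales(),
                               params = profile_params()) {
  for (comp in c("hydropathy", "beta", "alpha", "charge")) {
    if (is.null(scales[[comp]]) || !all(AA1 %in% names(scales[[comp]]))) {
      config_error(sprintf("scale '%s' incomplete", comp))
    }
  }
  zh <- zscore_scale(scales$hydropathy)
  zb <- zscore_scale(scales$beta)
  za <- zscore_scale(scales$alpha)
  zc <- zscore_scale(abs(scales$charge))
  aa <- sequence$residues
  unname(params$w_hyd * zh[aa] + params$w_beta * zb[aa] -
         params$w_alpha * za[aa] - params$w_chg * zc[aa])
}

#' Centred moving-average smoothing
#'
#' At the termini the window is truncated to the available residues and
#' renormalised (a plain mean of what the window covers).
#'
#' @param raw Numeric vector of per-residue values.
#' @param window Odd window width, at most `length(raw)`.
#' @return Smoothed vector of the same length.
#' @export
smooth_profile <- function(raw, window) {
  n <- length(raw)
  if (window %% 2 == 0 || window < 1) {
    parameter_error("window must be a positive odd integer")
  }
  if (window > n) parameter_error("window larger than sequence")
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, raw))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Charge-gatekeeper correction
#'
#' Lowers each profile value by `g` times the number of charged residues
#' (D, E, K, R) within `r_g` positions of it; the correction never
#' increases a value.
#'
#' @param values Numeric profile aligned to `sequence`.
#' @param sequence An `agg_sequence`.
#' @param g Gatekeeper strength (>= 0).
#' @param r_g Reach in residues.
#' @return Corrected numeric vector.
#' @export
gatekeeper_correction <- function(values, sequence, g, r_g) {
  n <- length(sequence$residues)
  if (length(values) != n) input_error("profile/sequence length mismatch")
  if (g == 0 || r_g == 0) return(values)
  charged <- as.numeric(sequence$residues %in% CHARGED_RESIDUES)
  cs <- cumsum(c(0, charged))
  i <- seq_len(n)
  lo <- pmax(1L, i - r_g)
  hi <- pmin(n, i + r_g)
  count <- (cs[hi + 1L] - cs[lo]) - charged   # neighbours only, not self
  values - g * count
}

#' Total score of a profile
#'
#' The scalar aggregation score of a profile: the arithmetic mean of the
#' per-residue values (length-normalised so variants of different lengths
#' remain comparable).
#'
#' @param values Non-empty numeric vector or an `agg_profile`.
#' @return Scalar mean.
#' @export
total_score <- function(values) {
  if (inherits(values, "agg_profile")) values <- values$values
  if (length(values) == 0) input_error("empty profile")
  mean(values)
}

new_profile <- function(sequence, values, kind, params = NULL,
                        provenance = NULL) {
  structure(list(sequence = sequence, values = unname(values), kind = kind,
                 total = mean(values), params = params,
                 provenance = provenance),
            class = "agg_profile")
}

#' @export
print.agg_profile <- function(x, ...) {
  cat(sprintf("<agg_profile> %s (%s): %d residues, total %.4f\n",
              x$sequence$id, x$kind, length(x$values), x$total))
  invisible(x)
}

#' Intrinsic aggregation profile of a sequence
#'
#' Full sequence-only pipeline: raw combined scores, centred smoothing,
#' gatekeeper correction, and the mean total.  A pure function of the
#' sequence and parameters (no randomness).
#'
#' @param sequence An `agg_sequence` (or a plain string).
#' @param params A `profile_params` list.
#' @param scales A `propensity_scales` list.
#' @return An `agg_profile` with `kind = "intrinsic"`.
#' @export
intrinsic_profile <- function(sequence, params = profile_params(),
                              scales = default_scales()) {
  if (!inherits(sequence, "agg_sequence")) sequence <- as_sequence(sequence)
  raw <- raw_residue_scores(sequence, scales, params)
  sm <- smooth_profile(raw, params$window)
  gk <- gatekeeper_correction(sm, sequence, params$gatekeeper,
                              params$gatekeeper_reach)
  new_profile(sequence, gk, "intrinsic", params = params)
}

#' Aggregation-prone regions of a profile
#'
#' Maximal runs of consecutive residues whose profile value exceeds the
#' threshold.
#'
#' @param profile An `agg_profile` or numeric vector.
#' @param threshold Finite score threshold (default 1).
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `peak`; zero rows when nothing exceeds the threshold.
#' @export
aggregation_prone_regions <- function(profile, threshold = 1.0) {
  if (!is.finite(threshold) && threshold != -Inf) {
    parameter_error("threshold must be finite (or -Inf)")
  }
  v <- if (inherits(profile, "agg_profile")) profile$values else profile
  above <- v > threshold
  if (!any(above)) {
    return(data.frame(start = integer(0), end = integer(0),
                      peak = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             peak = mapply(function(s, e) max(v[s:e]),
                           starts[keep], ends[keep]))
}
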