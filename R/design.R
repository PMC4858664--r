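# Rational mutation design: candidate-site selection by the intrinsic and
# ensemble-difference thresholds, saturation mutagenesis scans on the
# intrinsic score, protective/promoting rankings, and box statistics.

#' Select candidate design sites
#'
#' A residue is a candidate when its intrinsic profile value exceeds
#' `intrinsic_threshold` AND the absolute difference of the two
#' ensemble-averaged structurally corrected profiles at that residue
#' exceeds `delta_threshold` (defaults 1.0 and 0.2).
#'
#' @param intrinsic Intrinsic `agg_profile` (or numeric vector).
#' @param corrected_a,corrected_b Ensemble-average corrected profiles of
#'   the two variants (`agg_profile` or numeric), same length.
#' @param intrinsic_threshold,delta_threshold Selection thresholds.
#' @return Data frame `site`, `intrinsic`, `delta_corrected` for the
#'   selected residues.
#' @export
candidate_sites <- function(intrinsic, corrected_a, corrected_b,
                            intrinsic_threshold = 1.0,
                            delta_threshold = 0.2) {
  vals <- function(x) if (inherits(x, "agg_profile")) x$values else x
  iv <- vals(intrinsic)
  ca <- vals(corrected_a)
  cb <- vals(corrected_b)
  if (length(iv) != length(ca) || length(iv) != length(cb)) {
    input_error("profiles differ in length")
  }
  delta <- ca - cb
  sel <- which(iv > intrinsic_threshold & abs(delta) > delta_threshold)
  data.frame(site = sel, intrinsic = iv[sel], delta_corrected = delta[sel])
}

#' Saturation mutagenesis scan at one site
#'
#' For each of the 19 non-identity amino acids, substitutes the site,
#' recomputes the full intrinsic pipeline on the mutated sequence, and
#' reports the change in total intrinsic score (mutant - reference).
#' Negative deltas are protective, positive promoting.
#'
#' @param sequence An `agg_sequence` (or string).
#' @param site 1-based residue index to scan.
#' @param params [profile_params()] used for every profile evaluation.
#' @param scales [default_scales()] or a custom scale set.
#' @return A list of class `mutation_scan`: `site`, `wt` (reference
#'   residue), `reference_total`, and `table` (data frame `residue`,
#'   `delta`, 19 rows in alphabetical residue order).
#' @export
scan_site <- function(sequence, site, params = profile_params(),
                      scales = default_scales()) {
  if (!inherits(sequence, "agg_sequence")) sequence <- as_sequence(sequence)
  n <- length(sequence$residues)
  if (site < 1 || site > n) input_error(sprintf("site %d outside 1..%d",
                                                site, n))
  ref_total <- intrinsic_profile(sequence, params, scales)$total
  wt <- sequence$residues[site]
  subs <- sort(setdiff(AA1, wt))
  delta <- vapply(subs, function(aa) {
    mut <- sequence
    mut$residues[site] <- aa
    intrinsic_profile(mut, params, scales)$total - ref_total
  }, 0)
  structure(list(site = site, wt = wt, reference_total = ref_total,
                 table = data.frame(residue = subs, delta = unname(delta),
                                    row.names = NULL)),
            class = "mutation_scan")
}

#' @export
print.mutation_scan <- function(x, ...) {
  best <- x$table[order(x$table$delta), ]
  cat(sprintf("<mutation_scan> site %d (%s): delta range [%.4f, %.4f]\n",
              x$site, x$wt, best$delta[1], best$delta[nrow(best)]))
  invisible(x)
}

#' Rank designed mutations across scanned sites
#'
#' Pools all substitutions of the supplied scans and ranks them by the
#' predicted change in intrinsic score: `direction = "protect"` ascending
#' (most negative delta first), `"promote"` descending.  Ties are broken
#' deterministically by site index, then residue letter.
#'
#' @param scans List of `mutation_scan` objects.
#' @param direction `"protect"` or `"promote"`.
#' @return A data frame of class `design_report`: `site`, `wt`,
#'   `residue`, `delta`, `mutation` (e.g. `"V85E"`), ranked.
#' @export
rank_designs <- function(scans, direction = c("protect", "promote")) {
  direction <- match.arg(direction)
  if (inherits(scans, "mutation_scan")) scans <- list(scans)
  if (length(scans) == 0) input_error("no scans supplied")
  rows <- do.call(rbind, lapply(scans, function(s) {
    data.frame(site = s$site, wt = s$wt, residue = s$table$residue,
               delta = s$table$delta, stringsAsFactors = FALSE)
  }))
  key <- if (direction == "protect") rows$delta else -rows$delta
  ord <- order(key, rows$site, rows$residue)
  out <- rows[ord, ]
  out$mutation <- sprintf("%s%d%s", out$wt, out$site, out$residue)
  rownames(out) <- NULL
  class(out) <- c("design_report", "data.frame")
  attr(out, "direction") <- direction
  out
}

#' Box statistics of a score distribution
#'
#' Median, lower/upper quartiles and 5th/95th percentiles (linear
#' interpolation between order statistics, quantile type 7), the summary
#' drawn as a box with whiskers from the 5th to the 95th percentile.
#'
#' @param scores Non-empty numeric vector.
#' @return Named list of class `box_stats`: `p5`, `q1`, `median`, `q3`,
#'   `p95`, `n`.
#' @export
box_stats <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) input_error("empty score set")
  q <- stats::quantile(scores, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = FALSE)
  structure(list(p5 = q[1], q1 = q[2], median = q[3], q3 = q[4],
                 p95 = q[5], n = length(scores)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "<box_stats> n=%d: p5 %.4f | Q1 %.4f | median %.4f | Q3 %.4f | p95 %.4f\n",
    x$n, x$p5, x$q1, x$median, x$q3, x$p95))
  invisible(x)
}

#' Full design stage
#'
#' Convenience driver: selects candidate sites from an intrinsic profile
#' and two ensemble-average corrected profiles, scans every candidate
#' site, and returns rankings in both directions plus box statistics of
#' the mutant total scores (pooled across sites and per site).
#'
#' @inheritParams candidate_sites
#' @param sequence The sequence scanned (defaults to the intrinsic
#'   profile's sequence).
#' @param params,scales Passed to [scan_site()].
#' @return List: `sites`, `scans`, `protective`, `promoting`,
#'   `box_pooled`, `box_per_site`.
#' @export
design_mutations <- function(intrinsic, corrected_a, corrected_b,
                             intrinsic_threshold = 1.0,
                             delta_threshold = 0.2,
                             sequence = NULL,
                             params = profile_params(),
                             scales = default_scales()) {
  if (is.null(sequence)) {
    if (!inherits(intrinsic, "agg_profile")) {
      input_error("supply `sequence` when `intrinsic` is not an agg_profile")
    }
    sequence <- intrinsic$sequence
  }
  sites <- candidate_sites(intrinsic, corrected_a, corrected_b,
                           intrinsic_threshold, delta_threshold)
  scans <- lapply(sites$site, function(s) scan_site(sequence, s, params,
                                                    scales))
  if (length(scans) == 0) {
    return(list(sites = sites, scans = list(), protective = NULL,
                promoting = NULL, box_pooled = NULL, box_per_site = list()))
  }
  ref_total <- scans[[1]]$reference_total
  mutant_totals <- unlist(lapply(scans, function(s) {
    ref_total + s$table$delta
  }))
  list(sites = sites,
       scans = scans,
       protective = rank_designs(scans, "protect"),
       promoting = rank_designs(scans, "promote"),
       box_pooled = box_stats(mutant_totals),
       box_per_site = lapply(scans, function(s) {
         box_stats(ref_total + s$table$delta)
       }))
}
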