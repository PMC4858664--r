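# Secondary-structure-content collective variables: the antiparallel and
# parallel beta CVs (switching function of segment-pair RMSD to an ideal
# two-strand template) and convenience wrappers around the AlphaBeta CV.

# Backbone atoms entering the segment RMSD, per residue, in order.
CV_BB_ATOMS <- c("N", "CA", "C", "O")

#' Switching function
#'
#' `S(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)`, the rational switching
#' function used to map a segment-pair RMSD onto [0, 1]; the removable
#' singularity at `r = r0` evaluates to `n/m`.
#'
#' @param r Non-negative distance/RMSD values.
#' @param r0 Switching radius (same units as `r`).
#' @param n,m Exponents, `m > n`.
#' @return Values in (0, 1].
#' @export
switching_function <- function(r, r0 = 1.0, n = 8, m = 12) {
  x <- r / r0
  out <- numeric(length(x))
  near <- abs(x - 1) < 1e-7
  out[near] <- n / m
  xn <- x[!near]
  out[!near] <- (1 - xn^n) / (1 - xn^m)
  out
}

# 12-atom coordinate block (N, CA, C, O for 3 consecutive residues) or
# NULL if any atom is missing.
segment_coords <- function(structure, start) {
  out <- matrix(NA_real_, 12, 3)
  k <- 0
  for (i in start:(start + 2)) {
    for (a in CV_BB_ATOMS) {
      k <- k + 1
      p <- atom_coord(structure, i, a)
      if (is.null(p)) return(NULL)
      out[k, ] <- p
    }
  }
  # degenerate (coincident atoms) segments are excluded
  if (min(stats::dist(out)) < 1e-3) return(NULL)
  out
}

beta_content_cv <- function(structure, parallel, r0, n, m, min_sep) {
  rt <- residue_table(structure)
  nres <- nrow(rt)
  if (nres < 6) parameter_error("beta-content CVs need >= 6 residues")
  template <- beta_pair_template(parallel)
  ta <- segment_coords(template, 1)
  tb <- segment_coords(template, 4)
  tmpl <- rbind(ta, tb)
  segs <- lapply(seq_len(nres - 2), function(i) segment_coords(structure, i))
  total <- 0
  for (i in seq_len(nres - 2)) {
    if (is.null(segs[[i]])) next
    jmax <- nres - 2
    j0 <- i + min_sep
    if (j0 > jmax) next
    for (j in j0:jmax) {
      if (is.null(segs[[j]])) next
      r <- superposed_rmsd(rbind(segs[[i]], segs[[j]]), tmpl)
      total <- total + switching_function(r, r0, n, m)
    }
  }
  total
}

#' Antiparallel beta-content collective variable
#'
#' Sum over pairs of non-adjacent 3-residue segments of a switching
#' function of the backbone RMSD (after optimal superposition) to the
#' ideal antiparallel two-strand template of [beta_pair_template()].  A
#' pair in perfect template geometry contributes 1; unpaired geometry
#' contributes ~0.
#'
#' @param structure An `agg_structure` with >= 6 residues.
#' @param r0,n,m Switching-function parameters ([switching_function()]);
#'   defaults r0 = 1 A, n = 8, m = 12.
#' @param min_sep Minimum segment-start separation (default 3: segments
#'   share no residues and are not adjacent in sequence).
#' @return Scalar CV value (>= 0).
#' @export
antibeta_cv <- function(structure, r0 = 1.0, n = 8, m = 12, min_sep = 3) {
  beta_content_cv(structure, parallel = FALSE, r0, n, m, min_sep)
}

#' Parallel beta-content collective variable
#'
#' As [antibeta_cv()] but against the ideal parallel template.
#'
#' @inheritParams antibeta_cv
#' @return Scalar CV value (>= 0).
#' @export
parabeta_cv <- function(structure, r0 = 1.0, n = 8, m = 12, min_sep = 3) {
  beta_content_cv(structure, parallel = TRUE, r0, n, m, min_sep)
}

#' Standard collective-variable set of a conformation
#'
#' Computes the four CVs used as free-energy-surface axes: antiparallel
#' beta content (`beta`), parallel beta content (`pbeta`), the side-chain
#' AlphaBeta CV over chi1 of hydrophobic residues (`ab`), and the backbone
#' AlphaBeta CV over all defined phi/psi (`bbab`).
#'
#' @param structure An `agg_structure`.
#' @param reference A `dihedral_set` supplying the AlphaBeta reference
#'   angles (defaults to the conformation's own angles, giving the upper
#'   bound; pass the first conformation of an ensemble for trajectories).
#' @param r0,n,m Switching parameters for the beta-content CVs.
#' @return Named numeric vector `beta`, `pbeta`, `ab`, `bbab`.
#' @export
cv_values <- function(structure, reference = NULL, r0 = 1.0, n = 8, m = 12) {
  dh <- backbone_and_chi1_dihedrals(structure)
  if (is.null(reference)) reference <- dh
  hyd <- dh$hydrophobic & reference$hydrophobic
  c(beta = antibeta_cv(structure, r0, n, m),
    pbeta = parabeta_cv(structure, r0, n, m),
    ab = alphabeta_cv(dh$chi1[hyd], reference$chi1[hyd]),
    bbab = alphabeta_cv(c(dh$phi, dh$psi),
                        c(reference$phi, reference$psi)))
}
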