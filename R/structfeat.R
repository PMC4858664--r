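# Per-conformation geometric features: solvent accessibility, relative
# exposure, backbone/side-chain dihedrals, and Kabsch-Sander beta-bridge
# assignment.

#' Shrake-Rupley solvent accessible surface area
#'
#' Per-atom SASA from a deterministic golden-spiral point lattice: each
#' atom's sphere of radius `r + probe` is sampled at `n_points` points and
#' the exposed fraction scaled by the sphere area.  Hydrogens are excluded
#' by default (crystal structures lack them; radii stay comparable).
#'
#' @param structure An `agg_structure` with atomic radii assigned.
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4).
#' @param n_points Lattice points per atom, >= 32 (default 192).
#' @param include_hydrogens Include H atoms in the calculation.
#' @return A list with `atom` (per-atom areas, A^2, `NA` for excluded
#'   atoms) and `residue` (data frame `resno`, `sasa`).
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_points = 192, include_hydrogens = FALSE) {
  if (n_points < 32) parameter_error("n_points must be >= 32")
  if (probe_radius < 0) parameter_error("probe_radius must be >= 0")
  at <- structure$atoms
  use <- if (include_hydrogens) rep(TRUE, nrow(at)) else at$element != "H"
  co <- as.matrix(at[use, c("x", "y", "z")])
  a <- sasa_cpp(co, at$radius[use], probe_radius, as.integer(n_points))
  atom_area <- rep(NA_real_, nrow(at))
  atom_area[use] <- a
  res <- sort(unique(at$resno))
  rsasa <- vapply(res, function(r) {
    sum(atom_area[at$resno == r & use])
  }, 0)
  list(atom = atom_area,
       residue = data.frame(resno = res, sasa = rsasa))
}

#' Relative solvent exposure
#'
#' Per-residue SASA divided by the residue-type maximum (Gly-X-Gly
#' reference), clamped to [0, 1].
#'
#' @param residue_sasa Numeric per-residue SASA (A^2).
#' @param residue_code One-letter codes aligned to `residue_sasa`.
#' @param max_sasa_table Named maximum-SASA table covering the 20 codes.
#' @return Numeric vector in [0, 1].
#' @export
relative_exposure <- function(residue_sasa, residue_code,
                              max_sasa_table = MAX_SASA) {
  if (!all(residue_code %in% names(max_sasa_table))) {
    config_error("max-SASA table missing residue type(s)")
  }
  pmin(1, pmax(0, residue_sasa / unname(max_sasa_table[residue_code])))
}

#' Exposure profile of a structure
#'
#' Convenience wrapper combining [shrake_rupley_sasa()] and
#' [relative_exposure()].
#'
#' @inheritParams shrake_rupley_sasa
#' @return Data frame `resno`, `code`, `sasa`, `exposure`.
#' @export
exposure_profile <- function(structure, probe_radius = 1.4, n_points = 192) {
  s <- shrake_rupley_sasa(structure, probe_radius, n_points)
  rt <- residue_table(structure)
  if (anyNA(rt$code)) format_error("non-standard residues in structure")
  data.frame(resno = rt$resno, code = rt$code, sasa = s$residue$sasa,
             exposure = relative_exposure(s$residue$sasa, rt$code))
}

# First side-chain gamma atom for chi1, in PDB naming preference order.
GAMMA_ATOMS <- c("CG", "CG1", "OG", "OG1", "SG")

#' Backbone and chi1 dihedral angles
#'
#' Standard IUPAC quadruplets: phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1),
#' chi1 = N-CA-CB-G (first gamma atom).  The first phi and last psi are
#' undefined; any angle with a missing atom is `NA` and excluded from
#' collective variables downstream.  chi1 is undefined for Gly and Ala.
#'
#' @param structure An `agg_structure`.
#' @return A list of class `dihedral_set` with numeric vectors `phi`,
#'   `psi`, `chi1` (radians, `NA` where undefined) and the logical
#'   `hydrophobic` mask (chi1-bearing hydrophobic residues).
#' @export
backbone_and_chi1_dihedrals <- function(structure) {
  rt <- residue_table(structure)
  n <- nrow(rt)
  phi <- psi <- chi1 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni  <- atom_coord(structure, i, "N")
    CAi <- atom_coord(structure, i, "CA")
    Ci  <- atom_coord(structure, i, "C")
    if (i > 1) {
      Cm <- atom_coord(structure, i - 1, "C")
      if (!is.null(Cm) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
        phi[i] <- dihedral_angle(Cm, Ni, CAi, Ci)
      }
    }
    if (i < n) {
      Np <- atom_coord(structure, i + 1, "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Np)) {
        psi[i] <- dihedral_angle(Ni, CAi, Ci, Np)
      }
    }
    if (!(rt$code[i] %in% c("G", "A")) && !is.na(rt$code[i])) {
      CB <- atom_coord(structure, i, "CB")
      g <- NULL
      for (gn in GAMMA_ATOMS) {
        g <- atom_coord(structure, i, gn)
        if (!is.null(g)) break
      }
      if (!is.null(Ni) && !is.null(CAi) && !is.null(CB) && !is.null(g)) {
        chi1[i] <- dihedral_angle(Ni, CAi, CB, g)
      }
    }
  }
  structure(list(phi = phi, psi = psi, chi1 = chi1,
                 hydrophobic = rt$code %in% HYDROPHOBIC_CHI1),
            class = "dihedral_set")
}

#' AlphaBeta collective variable
#'
#' `AB = sum_k 0.5 * (1 + cos(theta_k - ref_k))` over aligned angle/
#' reference pairs; pairs where either value is `NA` are dropped.  Bounded
#' in [0, N] and invariant to 2*pi wrapping.
#'
#' @param angles Numeric vector of dihedral values (radians).
#' @param reference Aligned reference angles (radians).
#' @return Scalar CV value.
#' @export
alphabeta_cv <- function(angles, reference) {
  if (length(angles) != length(reference)) {
    input_error("angles and reference differ in length")
  }
  ok <- !is.na(angles) & !is.na(reference)
  sum(0.5 * (1 + cos(angles[ok] - reference[ok])))
}

# --- Kabsch-Sander hydrogen bonds and beta bridges -----------------------

# Reconstruct amide H: 1.0 A from N, opposite the bisector of the
# C(i-1)-N-CA angle (in-plane trans amide proton).
reconstruct_amide_h <- function(N, CA, Cprev) {
  u1 <- vunit(Cprev - N)
  u2 <- vunit(CA - N)
  N - vunit(u1 + u2)
}

# DSSP electrostatic H-bond energy (kcal/mol) between donor NH (i) and
# acceptor C=O (j).
ks_energy <- function(Ni, Hi, Cj, Oj) {
  rON <- vnorm(Oj - Ni); rCH <- vnorm(Cj - Hi)
  rOH <- vnorm(Oj - Hi); rCN <- vnorm(Cj - Ni)
  if (min(rON, rCH, rOH, rCN) < 0.5) return(Inf)  # clash: no bond
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# n x n logical matrix: hbond[i, j] = TRUE if the NH of residue i donates
# to the CO of residue j with E < cutoff.
ks_hbond_matrix <- function(structure, cutoff = -0.5) {
  rt <- residue_table(structure)
  n <- nrow(rt)
  Nc <- lapply(seq_len(n), function(i) atom_coord(structure, i, "N"))
  CAc <- lapply(seq_len(n), function(i) atom_coord(structure, i, "CA"))
  Cc <- lapply(seq_len(n), function(i) atom_coord(structure, i, "C"))
  Oc <- lapply(seq_len(n), function(i) atom_coord(structure, i, "O"))
  Hc <- vector("list", n)
  for (i in 2:max(2, n)) {
    if (i > n) break
    # use explicit amide H when present, else reconstruct
    h <- atom_coord(structure, i, "H")
    if (is.null(h) && !is.null(Nc[[i]]) && !is.null(CAc[[i]]) &&
        !is.null(Cc[[i - 1]])) {
      h <- reconstruct_amide_h(Nc[[i]], CAc[[i]], Cc[[i - 1]])
    }
    Hc[[i]] <- h
  }
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (is.null(Hc[[i]]) || is.null(Nc[[i]]) || rt$resid[i] == "PRO") next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (is.null(Cc[[j]]) || is.null(Oc[[j]])) next
      if (vnorm(Nc[[i]] - Oc[[j]]) > 5.5) next  # distance prefilter
      e <- ks_energy(Nc[[i]], Hc[[i]], Cc[[j]], Oc[[j]])
      hb[i, j] <- e < cutoff
    }
  }
  hb
}

#' Kabsch-Sander beta-bridge assignment
#'
#' Detects backbone hydrogen bonds with the DSSP electrostatic criterion
#' (E < -0.5 kcal/mol, with the amide H reconstructed 1.0 A from N
#' opposite the C(i-1)-N-CA bisector when absent) and assigns antiparallel
#' and parallel beta bridges by the Kabsch-Sander patterns:
#' antiparallel (i,j) if Hbond(i,j) and Hbond(j,i), or Hbond(i-1,j+1) and
#' Hbond(j-1,i+1); parallel (i,j) if Hbond(i-1,j) and Hbond(j,i+1), or
#' Hbond(j-1,i) and Hbond(i,j+1); pairs with |i-j| < 3 are excluded.
#'
#' @param structure An `agg_structure` with backbone N, CA, C, O.
#' @param cutoff H-bond energy cutoff, kcal/mol (default -0.5).
#' @return A list of class `ss_assignment`: `antiparallel` and `parallel`
#'   (two-column matrices of bridged residue pairs, i < j), `beta`
#'   (per-residue logical: participates in >= 1 bridge), and `hbond` (the
#'   donor -> acceptor logical matrix).
#' @export
kabsch_sander_bridges <- function(structure, cutoff = -0.5) {
  hb <- ks_hbond_matrix(structure, cutoff)
  n <- nrow(hb)
  anti <- par <- NULL
  hbond <- function(i, j) {
    i >= 1 && j >= 1 && i <= n && j <= n && hb[i, j]
  }
  # hb[d, a]: NH of d donates to CO of a.  In DSSP's CO-acceptor notation
  # Hb(a, d), the patterns below are the standard bridge definitions.
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 3) next
      if ((hbond(j, i) && hbond(i, j)) ||
          (hbond(j + 1, i - 1) && hbond(i + 1, j - 1))) {
        anti <- rbind(anti, c(i, j))
      }
      if ((hbond(j, i - 1) && hbond(i + 1, j)) ||
          (hbond(i, j - 1) && hbond(j + 1, i))) {
        par <- rbind(par, c(i, j))
      }
    }
  }
  beta <- rep(FALSE, n)
  for (m in list(anti, par)) {
    if (!is.null(m)) beta[unique(as.vector(m))] <- TRUE
  }
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  fix <- function(m) {
    if (is.null(m)) return(empty)
    colnames(m) <- c("i", "j")
    m
  }
  structure(list(antiparallel = fix(anti), parallel = fix(par),
                 beta = beta, hbond = hb),
            class = "ss_assignment")
}
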