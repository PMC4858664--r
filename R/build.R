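# Idealized structure builders: sequential internal-coordinate (NeRF)
# backbone construction, ideal two-strand beta templates, and a minimal
# antiparallel hairpin fixture.
#
# Standard backbone geometry (Engh-Huber-like defaults), one table:
#   bonds  N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231, CA-CB 1.530 (A)
#   angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 (deg)
#   omega  180 deg (trans)

BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.2 * pi / 180, a_ca_c_n = 116.2 * pi / 180,
  a_c_n_ca = 121.7 * pi / 180, a_ca_c_o = 120.8 * pi / 180,
  omega = pi)

# Ideal beta-strand backbone dihedrals (radians).
BETA_PHI <- -139 * pi / 180
BETA_PSI <-  135 * pi / 180
HELIX_PHI <- -57 * pi / 180
HELIX_PSI <- -47 * pi / 180

place_cb <- function(N, CA, C) {
  u1 <- vunit(N - CA)
  u2 <- vunit(C - CA)
  b <- vunit(u1 + u2)
  n <- vunit(vcross(u1, u2))
  # direction giving ~109.5 deg to both N and C for the ideal N-CA-C angle
  CA + BB_GEOM$b_ca_cb * vunit(-0.5908 * b + 0.8068 * n)
}

#' Build a polypeptide chain from backbone dihedrals
#'
#' Places backbone atoms N, CA, C, O (and CB for non-Gly residues) by
#' sequential internal-coordinate construction from standard bond lengths
#' and angles, with trans peptide bonds.  Dihedral recovery by
#' [backbone_and_chi1_dihedrals()] round-trips to ~1e-6 rad.
#'
#' @param sequence An `agg_sequence` or string of one-letter codes.
#' @param phi,psi Backbone dihedrals in radians; either scalars (recycled)
#'   or vectors of the sequence length.  `phi[1]` and the last `psi` only
#'   affect terminal-atom placement.
#' @param id Structure label.
#' @return An `agg_structure`.
#' @export
build_chain <- function(sequence, phi = BETA_PHI, psi = BETA_PSI,
                        id = "built") {
  if (!inherits(sequence, "agg_sequence")) sequence <- as_sequence(sequence)
  n <- length(sequence$residues)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  g <- BB_GEOM
  N <- CA <- C <- O <- CB <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  C[[1]] <- CA[[1]] + g$b_ca_c * c(-cos(g$a_n_ca_c), sin(g$a_n_ca_c), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[[i + 1]] <- nerf_place(N[[i]], CA[[i]], C[[i]],
                               g$b_c_n, g$a_ca_c_n, psi[i])
      CA[[i + 1]] <- nerf_place(CA[[i]], C[[i]], N[[i + 1]],
                                g$b_n_ca, g$a_c_n_ca, g$omega)
      C[[i + 1]] <- nerf_place(C[[i]], N[[i + 1]], CA[[i + 1]],
                               g$b_ca_c, g$a_n_ca_c, phi[i + 1])
    }
    O[[i]] <- nerf_place(N[[i]], CA[[i]], C[[i]],
                         g$b_c_o, g$a_ca_c_o, psi[i] + pi)
    if (sequence$residues[i] != "G") {
      CB[[i]] <- place_cb(N[[i]], CA[[i]], C[[i]])
    }
  }
  rows <- list()
  for (i in seq_len(n)) {
    code <- sequence$residues[i]
    names_i <- c("N", "CA", "C", "O")
    coords_i <- rbind(N[[i]], CA[[i]], C[[i]], O[[i]])
    if (!is.null(CB[[i]])) {
      names_i <- c(names_i, "CB")
      coords_i <- rbind(coords_i, CB[[i]])
    }
    rows[[i]] <- data.frame(
      resno = i, resid = unname(AA3[code]), elety = names_i,
      element = substr(names_i, 1, 1),
      x = coords_i[, 1], y = coords_i[, 2], z = coords_i[, 3],
      occ = 1, radius = unname(ELEMENT_RADII[substr(names_i, 1, 1)]),
      orig_resno = i, chain = "A", stringsAsFactors = FALSE)
  }
  new_structure(do.call(rbind, rows), id = id)
}

par_to_rt <- function(par) {
  rotvec <- par[1:3]
  theta <- vnorm(rotvec)
  rot <- if (theta < 1e-12) diag(3) else
    axis_angle_matrix(rotvec / theta, theta)
  list(rot = rot, trans = par[4:6])
}

# compose rigid transforms: returns "first then second"
compose_rt <- function(first, second) {
  list(rot = second$rot %*% first$rot,
       trans = as.vector(second$rot %*% first$trans) + second$trans)
}

transform_structure <- function(structure, rt) {
  at <- structure$atoms
  co <- apply_rigid(as.matrix(at[, c("x", "y", "z")]), rt$rot, rt$trans)
  at$x <- co[, 1]; at$y <- co[, 2]; at$z <- co[, 3]
  new_structure(at, id = structure$id)
}

# Screw transform of an ideal periodic strand: the rigid motion mapping
# residue i onto residue i+1 (backbone atoms, Kabsch fit).
screw_transform <- function(strand) {
  n <- max(strand$atoms$resno)
  bb <- c("N", "CA", "C", "O")
  x <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    do.call(rbind, lapply(bb, function(a) atom_coord(strand, i, a)))
  }))
  y <- do.call(rbind, lapply(seq_len(n - 1) + 1, function(i) {
    do.call(rbind, lapply(bb, function(a) atom_coord(strand, i, a)))
  }))
  cx <- colMeans(x); cy <- colMeans(y)
  r <- kabsch_rotation(sweep(x, 2, cx), sweep(y, 2, cy))
  # y ~ (x - cx) %*% r + cy  =>  rot = t(r), trans = cy - t(r) cx
  list(rot = t(r), trans = as.vector(cy - t(r) %*% cx))
}

# Sheet dyad: 180-degree rotation about an axis along u (perpendicular
# to the strand's 2-residue repeat vector) through point q.  Because the
# strand is almost exactly 2-residue periodic at the ideal strand
# dihedrals, this family propagates the inter-strand hydrogen-bond
# registry along the strands with only a small (~0.05 A/residue) drift.
flip_transform <- function(repeat_dir, theta, q) {
  d <- vunit(repeat_dir)
  e1 <- vunit(vcross(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- vcross(d, e1)
  u <- cos(theta) * e1 + sin(theta) * e2
  rot <- axis_angle_matrix(u, pi)
  list(rot = rot, trans = as.vector(q - rot %*% q))
}

# Canonical inter-strand H-bond geometry error for a candidate partner
# placement of the 3-residue anchor strand.  Antiparallel: mutual
# N-H...O=C narrow pairs at the outer residues (A1<->B3, A3<->B1), so
# that extended hairpins carry narrow pairs at odd ladder positions.
# Parallel: the offset ladder NH(A2)->CO(B1), NH(B3)->CO(A2).
pair_objective <- function(rt, strand, parallel) {
  b <- transform_structure(strand, rt)
  ca_a <- lapply(1:3, function(i) atom_coord(strand, i, "CA"))
  ca_b <- lapply(1:3, function(i) atom_coord(b, i, "CA"))
  n_a <- lapply(1:3, function(i) atom_coord(strand, i, "N"))
  n_b <- lapply(1:3, function(i) atom_coord(b, i, "N"))
  o_a <- lapply(1:3, function(i) atom_coord(strand, i, "O"))
  o_b <- lapply(1:3, function(i) atom_coord(b, i, "O"))
  h_a <- c(list(NULL), lapply(2:3, function(i) reconstruct_amide_h(
    atom_coord(strand, i, "N"), atom_coord(strand, i, "CA"),
    atom_coord(strand, i - 1, "C"))))
  h_b <- c(list(NULL), lapply(2:3, function(i) reconstruct_amide_h(
    atom_coord(b, i, "N"), atom_coord(b, i, "CA"),
    atom_coord(b, i - 1, "C"))))
  err <- 0
  if (!parallel) {
    err <- err + (vnorm(n_b[[3]] - o_a[[1]]) - 2.95)^2
    err <- err + (vnorm(n_a[[1]] - o_b[[3]]) - 2.95)^2
    err <- err + (vnorm(n_a[[3]] - o_b[[1]]) - 2.95)^2
    err <- err + (vnorm(n_b[[1]] - o_a[[3]]) - 2.95)^2
    err <- err + (vnorm(h_b[[3]] - o_a[[1]]) - 1.95)^2
    err <- err + (vnorm(h_a[[3]] - o_b[[1]]) - 1.95)^2
    for (k in 1:3) {
      err <- err + 0.2 * (vnorm(ca_a[[k]] - ca_b[[4 - k]]) - 5.0)^2
    }
  } else {
    err <- err + (vnorm(n_a[[2]] - o_b[[1]]) - 2.95)^2
    err <- err + (vnorm(n_b[[3]] - o_a[[2]]) - 2.95)^2
    err <- err + (vnorm(h_a[[2]] - o_b[[1]]) - 1.95)^2
    err <- err + (vnorm(h_b[[3]] - o_a[[2]]) - 1.95)^2
    for (k in 1:3) {
      err <- err + 0.2 * (vnorm(ca_a[[k]] - ca_b[[k]]) - 4.85)^2
    }
  }
  # soft clash penalty over heavy-atom pairs
  coa <- coords_of(strand)
  cob <- coords_of(b)
  for (i in seq_len(nrow(coa))) {
    d <- sqrt(rowSums(sweep(cob, 2, coa[i, ])^2))
    err <- err + sum(pmax(0, 2.7 - d)^2)
  }
  err
}

# Deterministic derivation of the pair transforms (development utility;
# the shipped constants ANTI_TRANSFORM / PAR_TRANSFORM come from this).
# The antiparallel transform is optimized within the 2-parameter family
# of screw-conjugating flips (position along and angle about the strand
# axis); the parallel one over free rigid placements.
optimize_pair_transform <- function(parallel = FALSE) {
  strand <- build_chain("VVV", BETA_PHI, BETA_PSI, id = "strand")
  if (!parallel) {
    s <- screw_transform(strand)
    tau <- compose_rt(s, s)$trans          # 2-residue repeat vector
    mid <- colMeans(coords_of(strand))
    obj <- function(p) pair_objective(
      flip_transform(tau, p[1], mid + p[2:4]), strand, FALSE)
    fit <- NULL
    # scan starting axis angles and lateral offsets to escape local minima
    for (th0 in seq(-pi, pi, length.out = 9)[-9]) {
      for (off in list(c(0, 4.8, 0), c(0, -4.8, 0), c(0, 0, 4.8),
                       c(0, 0, -4.8))) {
        f2 <- stats::optim(c(th0, off), obj, method = "Nelder-Mead",
                           control = list(maxit = 4000, reltol = 1e-14))
        if (is.null(fit) || f2$value < fit$value) fit <- f2
      }
    }
    return(flip_transform(tau, fit$par[1], mid + fit$par[2:4]))
  }
  axis0 <- vunit(atom_coord(strand, 3, "CA") - atom_coord(strand, 1, "CA"))
  perp <- vunit(vcross(axis0, c(0, 0, 1)))
  start <- c(1e-3, 1e-3, 1e-3, perp * 4.85)
  obj <- function(p) pair_objective(par_to_rt(p), strand, TRUE)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 8000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  par_to_rt(fit$par)
}

# Frozen pair transforms (rotation matrix + translation) derived once
# with optimize_pair_transform(); H-bond geometry error < 0.01 A^2.
ANTI_TRANSFORM <- list(
  rot = matrix(c(-0.549705914818656, -0.669973908041514,
                 -0.498957282497175, -0.669973908041514,
                 -0.0031735875996457, 0.74237786260457,
                 -0.498957282497175, 0.742377862604569,
                 -0.447120497581698), 3, 3),
  trans = c(6.7596040981428, 6.89867476518032, -3.16284059684585))
PAR_TRANSFORM <- list(
  rot = matrix(c(0.99672482553646, 0.0522245326131133,
                 0.0617431806166027, -0.0525727788416302,
                 0.998608971231001, 0.00402808910403022,
                 -0.0614469290052936, -0.00726090698899531,
                 0.998083941432541), 3, 3),
  trans = c(1.82475231250377, -3.09954500165927, 3.15525202841651))

pair_transform_params <- function(parallel = FALSE) {
  p <- if (parallel) PAR_TRANSFORM else ANTI_TRANSFORM
  if (is.null(p)) p <- optimize_pair_transform(parallel)
  p
}

#' Ideal two-strand beta template
#'
#' The internal reference geometry for the beta-content collective
#' variables: two 3-residue strands built at (phi, psi) = (-139, 135) deg
#' and placed in canonical inter-strand hydrogen-bond registry
#' (antiparallel: mutual N-H...O=C narrow pairs at the outer residues;
#' parallel: the offset ladder).  Residues 1-3 are strand one, 4-6
#' strand two.
#'
#' @param parallel Build the parallel (TRUE) or antiparallel (FALSE)
#'   template.
#' @return An `agg_structure` of 6 residues.
#' @export
beta_pair_template <- function(parallel = FALSE) {
  strand <- build_chain("VVV", BETA_PHI, BETA_PSI, id = "strand")
  b <- transform_structure(strand, pair_transform_params(parallel))
  at_a <- strand$atoms
  at_b <- b$atoms
  at_b$resno <- at_b$resno + 3L
  at_b$orig_resno <- at_b$resno
  new_structure(rbind(at_a, at_b),
                id = if (parallel) "parallel-template" else
                  "antiparallel-template")
}

# Two anchored turn residues joining A's C-terminus to B's N-terminus
# with proper local peptide geometry at both junctions (so the strand
# termini keep well-defined amide protons); the turn itself has one
# internal chain break.
turn_residues <- function(strand_a, strand_b, n, offset) {
  g <- BB_GEOM
  # turn residue 1: continues from A's last residue
  N1 <- nerf_place(atom_coord(strand_a, n, "N"),
                   atom_coord(strand_a, n, "CA"),
                   atom_coord(strand_a, n, "C"),
                   g$b_c_n, g$a_ca_c_n, BETA_PSI)
  CA1 <- nerf_place(atom_coord(strand_a, n, "CA"),
                    atom_coord(strand_a, n, "C"), N1,
                    g$b_n_ca, g$a_c_n_ca, g$omega)
  C1 <- nerf_place(atom_coord(strand_a, n, "C"), N1, CA1,
                   g$b_ca_c, g$a_n_ca_c, -80 * pi / 180)
  O1 <- nerf_place(N1, CA1, C1, g$b_c_o, g$a_ca_c_o, pi / 2)
  # turn residue 2: anchored backwards from B's first residue so that
  # B1 gets an ideally placed preceding carbonyl carbon
  C2 <- nerf_place(atom_coord(strand_b, 1, "C"),
                   atom_coord(strand_b, 1, "CA"),
                   atom_coord(strand_b, 1, "N"),
                   g$b_c_n, g$a_c_n_ca, BETA_PHI)
  CA2 <- nerf_place(atom_coord(strand_b, 1, "CA"),
                    atom_coord(strand_b, 1, "N"), C2,
                    g$b_ca_c, g$a_ca_c_n, g$omega)
  N2 <- nerf_place(atom_coord(strand_b, 1, "N"), C2, CA2,
                   g$b_n_ca, g$a_n_ca_c, 120 * pi / 180)
  O2 <- nerf_place(N2, CA2, C2, g$b_c_o, g$a_ca_c_o, pi)
  mk <- function(k, N, CA, C, O) {
    nm <- c("N", "CA", "C", "O")
    co <- rbind(N, CA, C, O)
    data.frame(resno = n + k + offset, resid = "GLY", elety = nm,
               element = substr(nm, 1, 1),
               x = co[, 1], y = co[, 2], z = co[, 3],
               occ = 1, radius = unname(ELEMENT_RADII[substr(nm, 1, 1)]),
               orig_resno = n + k + offset, chain = "A",
               stringsAsFactors = FALSE)
  }
  rbind(mk(1, N1, CA1, C1, O1), mk(2, N2, CA2, C2, O2))
}

#' Build an idealized antiparallel beta hairpin
#'
#' Two antiparallel strands of `n_per_strand` residues in canonical
#' inter-strand hydrogen-bond registry (the second strand is a
#' rigid-transformed copy of the first, the transform being the screw-
#' shifted pairing flip of [beta_pair_template()], so residue k of the
#' second strand pairs with residue `n + 1 - k` of the first), joined by
#' a two-residue glycine turn anchored with proper peptide geometry at
#' both strand junctions.
#'
#' @param n_per_strand Residues per strand, >= 3.
#' @param id Structure label.
#' @return An `agg_structure` of `2 * n_per_strand + 2` residues.
#' @export
build_hairpin <- function(n_per_strand = 5, id = "hairpin") {
  if (n_per_strand < 3) parameter_error("n_per_strand must be >= 3")
  n <- as.integer(n_per_strand)
  strand <- build_chain(strrep("V", n), BETA_PHI, BETA_PSI, id = "strand")
  # the frozen pair transform is anchored on residues 1-3 (B_k across
  # A_{4-k}); shifting it by the strand's screw symmetry n-3 times makes
  # B_k pair with A_{n+1-k}, i.e. a full-length hairpin registry
  rt <- pair_transform_params(parallel = FALSE)
  s <- screw_transform(strand)
  for (k in seq_len(n - 3)) rt <- compose_rt(rt, s)
  b <- transform_structure(strand, rt)
  at_a <- strand$atoms
  at_b <- b$atoms
  at_b$resno <- at_b$resno + n + 2L
  at_b$orig_resno <- at_b$resno
  turn <- turn_residues(strand, b, n, offset = 0L)
  new_structure(rbind(at_a, turn, at_b), id = id)
}
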