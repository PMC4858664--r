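# Residue-level physico-chemical tables and atomic constants.
#
# All per-residue scales are keyed by the canonical 20 one-letter codes.
# Scales are combined after z-normalisation over the alphabet (see
# raw_residue_scores), so their original units are irrelevant downstream.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- stats::setNames(names(AA3), AA3)

# Kyte-Doolittle hydropathy
HYDROPATHY <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Chou-Fasman conformational propensities
BETA_PROPENSITY <- c(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
                     Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
                     L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
                     S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

ALPHA_PROPENSITY <- c(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70,
                      Q = 1.11, E = 1.51, G = 0.57, H = 1.00, I = 1.08,
                      L = 1.21, K = 1.16, M = 1.45, F = 1.13, P = 0.57,
                      S = 0.77, T = 0.83, W = 1.08, Y = 0.69, V = 1.06)

# Net side-chain charge at pH 7.4; His carries a small fractional charge.
NET_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0,
                Q = 0, E = -1, G = 0, H = 0.1, I = 0,
                L = 0, K = 1, M = 0, F = 0, P = 0,
                S = 0, T = 0, W = 0, Y = 0, V = 0)

CHARGED_RESIDUES <- c("D", "E", "K", "R")

# Theoretical maximum accessible surface areas (A^2), Gly-X-Gly reference
# (Tien et al. 2013, theoretical column).
MAX_SASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
              Q = 225, E = 223, G = 104, H = 224, I = 197,
              L = 201, K = 236, M = 224, F = 240, P = 159,
              S = 155, T = 172, W = 285, Y = 263, V = 174)

# Bondi-type van der Waals radii (A) used for solvent accessibility.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Hydrophobic residues whose chi1 enters the side-chain AlphaBeta CV
# (chi1-bearing subset: no A or G).
HYDROPHOBIC_CHI1 <- c("V", "L", "I", "M", "F", "W", "C")

# Boltzmann constant, kJ/mol/K
KB_KJ <- 0.0083145

#' Default propensity scales
#'
#' Returns the per-amino-acid scales combined into the raw intrinsic
#' aggregation score: Kyte-Doolittle hydropathy, Chou-Fasman beta-sheet and
#' alpha-helix propensities, and net side-chain charge at pH 7.4 (His
#' fractional, +0.1).  Each component is a named numeric vector over the
#' canonical 20 one-letter codes.
#'
#' @return A list with components `hydropathy`, `beta`, `alpha`, `charge`,
#'   of class `propensity_scales`.
#' @export
default_scales <- function() {
  structure(list(hydropathy = HYDROPATHY,
                 beta       = BETA_PROPENSITY,
                 alpha      = ALPHA_PROPENSITY,
                 charge     = NET_CHARGE),
            class = "propensity_scales")
}
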