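# Shared fixtures, built in code.  Expensive objects are memoised per
# test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

deg <- function(x) x * pi / 180

# a single free atom as an agg_structure
atom_structure <- function(coords, radius = 1.7, element = "C") {
  n <- nrow(coords)
  aggscape:::new_structure(data.frame(
    resno = seq_len(n), resid = "ALA", elety = element, element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    occ = 1, radius = radius, orig_resno = seq_len(n), chain = "A",
    stringsAsFactors = FALSE), id = "atoms")
}

# small ensemble pair shared by several tests (fast settings)
test_pair <- function() {
  cached("pair", make_ensemble_pair(
    synth_spec(length = 34, hotspot_start = 14, hotspot_end = 20,
               n_conformations = 4, seed = 11)))
}

test_hairpin <- function() cached("hairpin", build_hairpin(5))

test_helix <- function() {
  cached("helix", build_chain(strrep("V", 12), deg(-57), deg(-47)))
}

# Monte-Carlo point-sampling SASA oracle (independent of the lattice
# implementation): random directions per atom, occlusion by neighbours.
mc_sasa <- function(coords, radii, probe = 1.4, n_dir = 8000) {
  n <- nrow(coords)
  er <- radii + probe
  total <- 0
  for (i in seq_len(n)) {
    u <- matrix(stats::rnorm(n_dir * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * er[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_dir)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      free <- free & d2 >= er[j]^2
    }
    total <- total + mean(free) * 4 * pi * er[i]^2
  }
  total
}
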