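# Free-energy surfaces over collective-variable space: weighted histogram
# on a homogeneous grid, F = -kB T ln p shifted so the occupied minimum
# is 0; empty bins are +Inf.  Marginalization integrates probabilities
# over dropped axes and re-shifts.

#' Free-energy surface from weighted CV samples
#'
#' Bins (possibly multi-dimensional) collective-variable samples on a
#' grid, accumulates the sample weights per bin, and converts to free
#' energies `F_k = -kB * T * ln p_k`, shifted so the minimum over
#' occupied bins is 0.  Empty bins are `Inf`.  The surface is invariant
#' under uniform rescaling of the weights.
#'
#' @param cv_samples Numeric matrix (n_samples x n_cv) or vector of CV
#'   values; column names become axis names.
#' @param bin_edges List of strictly increasing bin-edge vectors, one per
#'   CV (a single vector for 1-D).
#' @param weights Optional non-negative sample weights (default uniform).
#' @param temperature Temperature in K (default 310).
#' @return A list of class `free_energy_surface`: `F` (array of free
#'   energies, kJ/mol), `p` (normalized bin probabilities), `edges`,
#'   `axes` (names), `temperature`, and `n_out` (samples falling outside
#'   the grid, excluded with a warning).
#' @export
fes_from_samples <- function(cv_samples, bin_edges, weights = NULL,
                             temperature = 310) {
  if (is.null(dim(cv_samples))) cv_samples <- matrix(cv_samples, ncol = 1)
  cv_samples <- as.matrix(cv_samples)
  if (!all(is.finite(cv_samples))) input_error("non-finite CV samples")
  k <- ncol(cv_samples)
  if (!is.list(bin_edges)) bin_edges <- list(bin_edges)
  if (length(bin_edges) != k) {
    input_error("one bin-edge vector per CV dimension required")
  }
  for (e in bin_edges) {
    if (any(diff(e) <= 0)) parameter_error("bin edges must be increasing")
  }
  n <- nrow(cv_samples)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) input_error("one weight per sample required")
  weights <- normalize_weights(weights)

  axes <- colnames(cv_samples)
  if (is.null(axes)) axes <- paste0("cv", seq_len(k))
  nb <- vapply(bin_edges, function(e) length(e) - 1L, 0L)
  idx <- matrix(0L, n, k)
  inside <- rep(TRUE, n)
  for (d in seq_len(k)) {
    bi <- findInterval(cv_samples[, d], bin_edges[[d]],
                       rightmost.closed = TRUE)
    inside <- inside & bi >= 1 & bi <= nb[d]
    idx[, d] <- bi
  }
  n_out <- sum(!inside)
  if (n_out > 0) {
    warning(sprintf("%d sample(s) outside the grid excluded", n_out))
  }
  p <- array(0, dim = nb)
  if (any(inside)) {
    flat <- as.vector((idx[inside, , drop = FALSE] - 1L) %*%
                        cumprod(c(1L, nb[-k]))) + 1L
    tab <- rowsum(weights[inside], flat)
    p[as.integer(rownames(tab))] <- tab[, 1]
  }
  if (sum(p) <= 0) input_error("no samples inside the grid")
  p <- p / sum(p)
  F <- -KB_KJ * temperature * log(p)
  F <- F - min(F[p > 0])
  structure(list(F = F, p = p, edges = bin_edges, axes = axes,
                 temperature = temperature, n_out = n_out),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface> %s at %g K, %s bins, max finite F %.3f kJ/mol\n",
              paste(x$axes, collapse = " x "), x$temperature,
              paste(dim(x$F), collapse = " x "),
              max(x$F[is.finite(x$F)])))
  invisible(x)
}

#' Marginalize a free-energy surface
#'
#' Integrates out the axes not kept: bin probabilities are summed over
#' the dropped dimensions, converted back to free energies, and
#' re-shifted so the occupied minimum is 0.  Keeping all axes is the
#' identity.
#'
#' @param surface A `free_energy_surface`.
#' @param keep_axes Character names (or integer indices) of the axes to
#'   keep; must be a non-empty subset.
#' @return A `free_energy_surface` over the kept axes.
#' @export
marginalize_fes <- function(surface, keep_axes) {
  if (!inherits(surface, "free_energy_surface")) {
    input_error("expected a free_energy_surface")
  }
  if (is.character(keep_axes)) keep_axes <- match(keep_axes, surface$axes)
  keep_axes <- sort(unique(as.integer(keep_axes)))
  k <- length(dim(surface$p))
  if (length(keep_axes) == 0) input_error("keep_axes must be non-empty")
  if (anyNA(keep_axes) || any(keep_axes < 1) || any(keep_axes > k)) {
    input_error("keep_axes outside surface axes")
  }
  if (length(keep_axes) == k) return(surface)
  p <- apply(surface$p, keep_axes, sum)
  if (length(keep_axes) == 1) {
    p <- array(p, dim = length(p))
  }
  F <- -KB_KJ * surface$temperature * log(p)
  F <- F - min(F[p > 0])
  structure(list(F = F, p = p, edges = surface$edges[keep_axes],
                 axes = surface$axes[keep_axes],
                 temperature = surface$temperature, n_out = surface$n_out),
            class = "free_energy_surface")
}

#' Collective-variable table of an ensemble
#'
#' Evaluates [cv_values()] for every conformation, using the first
#' conformation as the AlphaBeta reference.
#'
#' @param ensemble An `agg_ensemble`.
#' @param ... Passed to [cv_values()].
#' @return Data frame with one row per conformation and columns `beta`,
#'   `pbeta`, `ab`, `bbab`.
#' @export
ensemble_cv_table <- function(ensemble, ...) {
  ref <- backbone_and_chi1_dihedrals(ensemble$structures[[1]])
  as.data.frame(t(vapply(ensemble$structures, function(s) {
    cv_values(s, reference = ref, ...)
  }, numeric(4))))
}
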