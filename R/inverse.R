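#' Inverse solution specification
#'
#' Parameters of the weighted minimum-norm estimator: Tikhonov regularization
#' `lambda2` (the conventional `1/SNR^2` with SNR = 3 gives the default 1/9),
#' depth-weighting exponent `depth_gamma` in `[0, 1]` (0 disables depth
#' weighting, recovering plain MNE), and an optional sensor noise covariance
#' (identity by default).
#'
#' @param lambda2 Regularization parameter (>= 0, default 1/9).
#' @param depth_gamma Depth-weighting exponent in `[0, 1]` (default 0.8).
#' @param noise_cov Optional sensors x sensors covariance matrix.
#' @return An object of class `inverse_spec`.
#' @export
inverse_spec <- function(lambda2 = 1 / 9, depth_gamma = 0.8, noise_cov = NULL) {
  if (lambda2 < 0) stop("lambda2 must be >= 0")
  if (depth_gamma < 0 || depth_gamma > 1) stop("depth_gamma must be in [0, 1]")
  structure(list(lambda2 = lambda2, depth_gamma = depth_gamma,
                 noise_cov = noise_cov),
            class = "inverse_spec")
}

#' Weighted minimum-norm inverse operator
#'
#' Computes the wMNE kernel `K = W G' (G W G' + lambda2 * s * C)^-1` with
#' diagonal source weights `w_j = ||g_j||^(-2 gamma)` (depth weighting by the
#' gain column norms), `C` the noise covariance, and `s` the mean diagonal of
#' `G W G'` so that `lambda2` is expressed on the conventional dimensionless
#' SNR scale regardless of lead-field units.
#'
#' @param lf A `lead_field`.
#' @param spec An [inverse_spec].
#' @return Object of class `inverse_operator` with the sources x sensors
#'   `kernel`.
#' @export
compute_wmne_operator <- function(lf, spec = inverse_spec()) {
  stopifnot(inherits(lf, "lead_field"), inherits(spec, "inverse_spec"))
  G <- lf$gain
  if (!all(is.finite(G))) stop("lead field must be finite")
  cn <- sqrt(colSums(G^2))
  if (any(cn == 0)) stop("lead field has an all-zero column")
  w <- cn^(-2 * spec$depth_gamma)
  GW <- sweep(G, 2, w, `*`)           # G W
  gram <- GW %*% t(G)                 # G W G'
  C <- spec$noise_cov
  if (is.null(C)) C <- diag(nrow(G))
  scale <- mean(diag(gram))
  reg <- gram + spec$lambda2 * scale * C
  inv <- tryCatch(solve(reg), error = function(e)
    stop("regularized Gram matrix is singular; use lambda2 > 0 ",
         "for a rank-deficient lead field"))
  structure(list(kernel = t(GW) %*% inv, spec = spec,
                 n_sources = ncol(G), n_sensors = nrow(G)),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> wMNE kernel %d sources x %d sensors (lambda2 = %.4g, gamma = %g)\n",
              x$n_sources, x$n_sensors, x$spec$lambda2, x$spec$depth_gamma))
  invisible(x)
}

#' Apply an inverse operator to a sensor recording
#'
#' Sample-by-sample matrix product `kernel %*% data`; linear, so
#' superposition holds.
#'
#' @param op An [compute_wmne_operator] result.
#' @param rec A [recording] with matching channel count.
#' @return Numeric matrix, sources x samples (vertex time series).
#' @export
apply_inverse <- function(op, rec) {
  stopifnot(inherits(op, "inverse_operator"), inherits(rec, "recording"))
  if (nrow(rec$data) != op$n_sensors)
    stop("channel count ", nrow(rec$data),
         " does not match inverse operator sensors ", op$n_sensors)
  op$kernel %*% rec$data
}

#' Parcellate vertex time series into atlas regions
#'
#' Aggregates member-vertex series into one series per region using a
#' sign-aligned mean: each vertex is flipped so that it correlates positively
#' with the region's first principal direction (first left singular vector of
#' the member block), then the flipped series are averaged. This avoids the
#' cancellation a naive mean suffers when dipole orientations alternate sign.
#'
#' @param vertex_ts Numeric matrix, vertices x samples.
#' @param atlas_labels Character (or factor) vector, one label per vertex;
#'   vertices labelled `NA` or `"unknown"` are excluded.
#' @param region_order Optional character vector fixing the output region
#'   order; defaults to [dk_region_labels()] when all labels belong to it,
#'   otherwise sorted unique labels.
#' @param fs Sampling rate recorded on the output (default 1).
#' @return A [source_activity] with one row per region.
#' @export
parcellate <- function(vertex_ts, atlas_labels, region_order = NULL, fs = 1) {
  vertex_ts <- as.matrix(vertex_ts)
  atlas_labels <- as.character(atlas_labels)
  if (length(atlas_labels) != nrow(vertex_ts))
    stop("one atlas label per vertex required")
  keep <- !is.na(atlas_labels) & atlas_labels != "unknown"
  labs <- atlas_labels[keep]
  if (is.null(region_order)) {
    dk <- dk_region_labels()
    region_order <- if (all(labs %in% dk)) dk[dk %in% labs] else sort(unique(labs))
  }
  missing_regions <- setdiff(region_order, labs)
  if (length(missing_regions))
    stop("empty region(s): ", paste(missing_regions, collapse = ", "))
  out <- matrix(0, length(region_order), ncol(vertex_ts))
  vts <- vertex_ts[keep, , drop = FALSE]
  for (r in seq_along(region_order)) {
    block <- vts[labs == region_order[r], , drop = FALSE]
    if (nrow(block) == 1L) { out[r, ] <- block[1, ]; next }
    sv <- svd(block, nu = 1, nv = 0)
    flip <- sign(sv$u[, 1])
    flip[flip == 0] <- 1
    ## the singular vector's global sign is arbitrary: anchor it so that the
    ## majority of vertices (first vertex on a tie) keep their polarity
    anchor <- if (abs(sum(flip)) > 0) sign(sum(flip)) else flip[1]
    flip <- flip * anchor
    out[r, ] <- colMeans(block * flip)
  }
  source_activity(out, fs, region_order)
}
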