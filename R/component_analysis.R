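# Geometry of spatial loadings: a Sobolev-type inner product and dissimilarity
# between depth profiles, hierarchical clustering of loadings across animals,
# current-source-density loadings, and volume-conduction detection.

#' Parameters of the loading dissimilarity
#'
#' @param kappa Dimensional constant (um^2) weighting the derivative terms of
#'   the inner product; default 150 um^2, chosen to magnify spatial-derivative
#'   differences at a large inter-electrode distance.
#' @param h Inter-electrode spacing (um); default 150.
#' @return Object of class `loading_distance_params`.
#' @export
loading_distance_params <- function(kappa = 150, h = 150) {
  if (kappa < 0) ll_stop("spec_error", "kappa must be >= 0")
  if (h <= 0) ll_stop("spec_error", "h must be > 0")
  structure(list(kappa = kappa, h = h,
                 scheme = "central, 2nd-order one-sided at boundaries"),
            class = "loading_distance_params")
}

# finite-difference first derivative, uniform grid (2nd-order at ends)
fd_first <- function(v, h) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * v[1] + 4 * v[2] - v[3]) / (2 * h)
  d[n] <- (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * h)
  d
}

# finite-difference second derivative (2nd-order one-sided at ends, n >= 4;
# for n == 3 the single interior value is replicated at the ends)
fd_second <- function(v, h) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / h^2
  if (n >= 4) {
    d[1] <- (2 * v[1] - 5 * v[2] + 4 * v[3] - v[4]) / h^2
    d[n] <- (2 * v[n] - 5 * v[n - 1] + 4 * v[n - 2] - v[n - 3]) / h^2
  } else {
    d[1] <- d[2]; d[n] <- d[2]
  }
  d
}

# trapezoid quadrature weights over the electrode span
trapz_w <- function(n, h) h * c(0.5, rep(1, n - 2), 0.5)

#' Sobolev-type inner product of two spatial loadings
#'
#' `<Vn,Vm> = int_Omega Vn Vm + kappa dVn dVm + kappa^2 d2Vn d2Vm dx` over the
#' electrode depth span, with central finite differences (second-order
#' one-sided stencils at the boundaries) and trapezoid integration. The
#' discrete form is a positive-semidefinite bilinear form, so Cauchy-Schwarz
#' holds for the induced norm.
#'
#' @param v_n,v_m Loadings on the same uniform depth grid, length >= 3.
#' @param params A [loading_distance_params()].
#' @return Scalar inner product.
#' @export
loading_inner <- function(v_n, v_m, params = loading_distance_params()) {
  n <- length(v_n)
  if (n < 3L || length(v_m) != n)
    ll_stop("insufficient_support_error",
            "loadings must have equal length >= 3")
  h <- params$h; kap <- params$kappa
  w <- trapz_w(n, h)
  sum(w * v_n * v_m) +
    kap * sum(w * fd_first(v_n, h) * fd_first(v_m, h)) +
    kap^2 * sum(w * fd_second(v_n, h) * fd_second(v_m, h))
}

#' Norm induced by the loading inner product
#' @inheritParams loading_inner
#' @param v A loading vector.
#' @return `sqrt(loading_inner(v, v, params))`.
#' @export
loading_norm <- function(v, params = loading_distance_params()) {
  sqrt(loading_inner(v, v, params))
}

#' Dissimilarity between two spatial loadings
#'
#' `d = 1 - |<Vn,Vm>| / (||Vn|| ||Vm||)`, in `[0, 1]` by Cauchy-Schwarz;
#' invariant to the scale and sign of either loading (the ICA ambiguities).
#'
#' @inheritParams loading_inner
#' @return Dissimilarity in `[0, 1]`.
#' @export
loading_distance <- function(v_n, v_m, params = loading_distance_params()) {
  nn <- loading_norm(v_n, params); nm <- loading_norm(v_m, params)
  if (nn == 0 || nm == 0)
    ll_stop("degenerate_error", "zero-norm loading")
  1 - abs(loading_inner(v_n, v_m, params)) / (nn * nm)
}

#' Hierarchical clustering of spatial loadings
#'
#' Groups loadings (e.g. the components recovered from several animals) into
#' `n_groups`. Two linkages are provided: `"ward_sobolev"` (default) embeds
#' each max-normalized loading into the feature space whose Euclidean inner
#' product equals the Sobolev inner product (the loading concatenated with its
#' suitably weighted first and second depth derivatives) and applies Ward's
#' minimum-variance linkage; `"average_distance"` applies average linkage
#' directly to the pairwise dissimilarity matrix.
#'
#' @param loadings Matrix channels x m, one loading per column.
#' @param n_groups Number of groups to cut the tree into.
#' @param method `"ward_sobolev"` or `"average_distance"`.
#' @param params A [loading_distance_params()].
#' @return List with `tree` (an [stats::hclust] object), `labels` (group per
#'   loading), `method`.
#' @export
cluster_loadings <- function(loadings, n_groups,
                             method = c("ward_sobolev", "average_distance"),
                             params = loading_distance_params()) {
  method <- match.arg(method)
  m <- ncol(loadings)
  if (is.null(m) || m < n_groups)
    ll_stop("spec_error", "need at least n_groups loadings")
  # max-normalize each profile; shape, not amplitude, defines identity
  L <- apply(loadings, 2L, function(v) v / max(abs(v)))
  n <- nrow(L); h <- params$h; kap <- params$kappa
  if (method == "ward_sobolev") {
    sw <- sqrt(trapz_w(n, h))
    feats <- apply(L, 2L, function(v)
      c(sw * v, sqrt(kap) * sw * fd_first(v, h), kap * sw * fd_second(v, h)))
    tree <- stats::hclust(stats::dist(t(feats)), method = "ward.D2")
  } else {
    D <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      D[i, j] <- D[j, i] <- loading_distance(L[, i], L[, j], params)
    tree <- stats::hclust(stats::as.dist(D), method = "average")
  }
  list(tree = tree, labels = stats::cutree(tree, k = n_groups), method = method)
}

#' Current-source-density loading of a component
#'
#' Discrete second spatial derivative of the voltage loading,
#' `I(k) = -sigma (V(k-1) - 2 V(k) + V(k+1)) / h^2`, evaluated at interior
#' electrodes only (strict interior policy). A linear (volume-conducted)
#' loading has zero CSD everywhere.
#'
#' @param v Voltage loading on a uniform depth grid, length >= 3.
#' @param h Inter-electrode spacing (um).
#' @param sigma Extracellular conductivity; fixed at 1 (arbitrary CSD units).
#' @param depths Optional depth grid; validated for uniform spacing when given.
#' @return Object of class `csd_loading`: `values` (length channels - 2),
#'   `channels` (interior indices), `boundary_policy`, `sigma`, `h`.
#' @export
csd_loading <- function(v, h, sigma = 1, depths = NULL) {
  n <- length(v)
  if (n < 3L) ll_stop("insufficient_support_error", "need >= 3 channels")
  if (!is.null(depths)) {
    dd <- diff(depths)
    if (max(dd) - min(dd) > 1e-6 * mean(dd))
      ll_stop("spacing_error", "electrode depths are not uniformly spaced")
  }
  I <- -sigma * (v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]) / h^2
  structure(list(values = I, channels = 2:(n - 1),
                 boundary_policy = "strict_interior", sigma = sigma, h = h),
            class = "csd_loading")
}

#' @export
print.csd_loading <- function(x, ...) {
  cat(sprintf("<csd_loading> %d interior channels, sigma = %g\n",
              length(x$values), x$sigma))
  invisible(x)
}

#' Detect a volume-conducted (depth-linear) component
#'
#' A remote generator produces a depth profile that is affine in depth, hence a
#' zero CSD loading. The dimensionless curvature score
#' `||I||_2 / (||V||_2 / h^2)` is ~0 for affine profiles; loadings scoring
#' below `threshold` are flagged as volume conducted.
#'
#' @param v Voltage loading.
#' @param h Inter-electrode spacing (um).
#' @param threshold Flagging threshold on the curvature score (default 0.05,
#'   calibrated on synthetic fixtures).
#' @return List with `volume_conducted` (logical) and `score`.
#' @export
is_volume_conducted <- function(v, h, threshold = 0.05) {
  I <- csd_loading(v, h)$values
  score <- sqrt(sum(I^2)) / (sqrt(sum(v^2)) / h^2)
  list(volume_conducted = score < threshold, score = score)
}
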