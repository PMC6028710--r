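# PCA dimensionality reduction and ICA unmixing of laminar LFPs, plus the
# component-level summaries: relative contribution to LFP variance, and the
# reconstructed (scale-unambiguous) component traces.

#' PCA reduction of a laminar recording
#'
#' Centers each channel and keeps the smallest number of principal components
#' whose cumulative explained variance reaches `var_frac`. Used to discard
#' noisy weak components and stabilize ICA convergence.
#'
#' @param rec A [laminar_recording()].
#' @param var_frac Fraction of variance to retain, in `(0, 1]` (default 0.99).
#' @return List with `scores` (k x time), `basis` (channels x k), `eigvals`,
#'   `center` (per-channel means), `var_retained`, `k`.
#' @export
pca_reduce <- function(rec, var_frac = 0.99) {
  if (!is_number(var_frac) || var_frac <= 0 || var_frac > 1)
    ll_stop("spec_error", "var_frac must be in (0, 1]")
  X <- rec$samples
  ctr <- rowMeans(X)
  Xc <- X - ctr
  C <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  tot <- sum(ev)
  if (tot <= 0)
    ll_stop("degenerate_error", "recording has zero variance")
  cum <- cumsum(ev) / tot
  k <- which(cum >= var_frac - 1e-12)[1]
  # drop numerically null directions even when var_frac = 1
  k <- min(k, sum(ev > tot * 1e-12))
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  list(scores = crossprod(U, Xc), basis = U, eigvals = ev[seq_len(k)],
       center = ctr, var_retained = cum[k], k = k)
}

#' Independent-component decomposition
#'
#' Holds the ICA model `LFP(t) = sum_n V_n s_n(t)`: spatial loadings `V`
#' (channels x components), time courses `s` (components x time), the
#' channel-space unmixing matrix `W` (`s = W (LFP - center)`), and the PCA
#' variance record. Components are ordered by descending relative contribution
#' and sign-flipped so each loading's largest-magnitude extremum is positive.
#'
#' @param V Spatial loadings, channels x components.
#' @param s Time courses, components x time.
#' @param W Unmixing matrix, components x channels.
#' @param var_retained PCA-retained variance fraction.
#' @param depths Per-channel depths (um).
#' @param fs Sampling rate (Hz).
#' @param center Per-channel means removed before ICA.
#' @return Object of class `ic_decomposition`.
#' @export
ic_decomposition <- function(V, s, W, var_retained, depths, fs, center) {
  if (!all(is.finite(V)) || any(colSums(abs(V)) == 0))
    ll_stop("validation_error", "columns of V must be finite and nonzero")
  structure(list(V = V, s = s, W = W, var_retained = var_retained,
                 depths = depths, fs = fs, center = center),
            class = "ic_decomposition")
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf("<ic_decomposition> %d components x %d samples (PCA variance retained: %.4f)\n",
              ncol(x$V), ncol(x$s), x$var_retained))
  wn <- relative_contribution(x)
  cat("  relative contributions:", paste(sprintf("%.3f", wn), collapse = " "), "\n")
  invisible(x)
}

# logistic infomax ICA with the natural gradient on whitened data.
# Full-batch updates W <- W + lr * (I - tanh(U/2) U'/T) W with learning-rate
# annealing when the update direction reverses. Near-Gaussian residual
# dimensions exert no rotational force, so convergence is well-defined even
# when PCA retains noise-dominated components.
infomax_core <- function(Z, W0, max_iter, tol, lr = 0.1, burn_in = 2500L,
                         anneal = 0.985) {
  infomax_core_cpp(Z, W0, as.integer(max_iter), tol, lr,
                   as.integer(burn_in), anneal)
}

# one FastICA pass: symmetric orthogonalization, logcosh contrast
fastica_core <- function(Z, W0, max_iter, tol) {
  sym_decor <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)),
                       nrow = length(e$values)) %*% t(e$vectors) %*% W
  }
  W <- sym_decor(W0)
  Tn <- ncol(Z)
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    Wn <- G %*% t(Z) / Tn - diag(rowMeans(1 - G^2), nrow = nrow(W)) %*% W
    Wn <- sym_decor(Wn)
    delta <- max(abs(1 - abs(rowSums(Wn * W))))
    W <- Wn
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it, delta = delta))
  }
  list(W = W, converged = FALSE, iter = max_iter, delta = delta)
}

#' Run ICA on a laminar recording
#'
#' Centers and whitens the recording (always), reduces dimensionality by PCA
#' (keeping `var_frac` of the variance), then unmixes with logistic infomax
#' ICA (natural-gradient, full-batch, annealed learning rate; the default) or
#' fixed-point FastICA (symmetric orthogonalization, logcosh contrast; mainly
#' useful as an independent cross-check, since maximum-non-Gaussianity
#' algorithms are theoretically equivalent). The spatial loadings are the
#' (pseudo)inverse of the unmixing transform mapped back to channel space, so
#' `V %*% s` reproduces the PCA-retained, centered signal to numerical
#' precision. Components are ordered by descending relative contribution; each
#' loading is sign-flipped so its largest-magnitude extremum is positive.
#'
#' @param rec A [laminar_recording()].
#' @param var_frac PCA variance fraction to retain (default 0.99).
#' @param seed RNG seed for the random initialization.
#' @param algorithm `"infomax"` (default) or `"fastica"`.
#' @param max_iter Maximum iterations per restart (default 5000).
#' @param tol Convergence tolerance on the relative unmixing-weight change
#'   (default 1e-6).
#' @param restarts Reinitializations attempted before failing (default 5).
#' @param max_samples Maximum number of time points used to fit the unmixing
#'   matrix (default 20000; longer recordings are evenly strided for the fit,
#'   while loadings and time courses always use the full data).
#' @return An [ic_decomposition()].
#' @export
run_ica <- function(rec, var_frac = 0.99, seed = 1L,
                    algorithm = c("infomax", "fastica"), max_iter = 5000L,
                    tol = 1e-6, restarts = 5L, max_samples = 20000L) {
  algorithm <- match.arg(algorithm)
  if (nrow(rec$samples) < 2L)
    ll_stop("validation_error", "ICA needs at least 2 channels")
  pc <- pca_reduce(rec, var_frac)
  k <- pc$k
  Z <- pc$scores / sqrt(pc$eigvals)        # whitened: unit-variance rows
  Zfit <- if (ncol(Z) > max_samples)
    Z[, round(seq(1L, ncol(Z), length.out = max_samples)), drop = FALSE]
  else Z
  set.seed(seed)
  res <- NULL
  for (r in seq_len(restarts)) {
    W0 <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
    res <- if (algorithm == "infomax") infomax_core(Zfit, W0, max_iter, tol)
           else fastica_core(Zfit, W0, max_iter, tol)
    if (res$converged) break
  }
  if (!res$converged)
    ll_stop("convergence_error", sprintf(
      "ICA (%s) did not converge after %d restarts x %d iterations (last delta %.3g)",
      algorithm, restarts, max_iter, res$delta))
  W <- res$W
  s <- W %*% Z
  # back-projection: Xc_retained = U D^(1/2) W^(-1) s
  V <- pc$basis %*% (sqrt(pc$eigvals) * solve(W))
  # channel-space unmixing: s = W D^(-1/2) U' Xc
  W_ch <- W %*% diag(1 / sqrt(pc$eigvals), nrow = k) %*% t(pc$basis)
  dec <- ic_decomposition(V, s, W_ch, pc$var_retained, rec$depths, rec$fs,
                          pc$center)
  # canonical order (descending contribution) and sign convention
  ord <- order(relative_contribution(dec), decreasing = TRUE)
  V <- V[, ord, drop = FALSE]; s <- s[ord, , drop = FALSE]
  W_ch <- W_ch[ord, , drop = FALSE]
  for (n in seq_len(k)) {
    kmax <- which.max(abs(V[, n]))
    if (V[kmax, n] < 0) { V[, n] <- -V[, n]; s[n, ] <- -s[n, ]; W_ch[n, ] <- -W_ch[n, ] }
  }
  ic_decomposition(V, s, W_ch, pc$var_retained, rec$depths, rec$fs, pc$center)
}

#' Relative contribution of each component to the LFP
#'
#' `W_n = ||V_n||^2 var(s_n) / sum_m ||V_m||^2 var(s_m)`; the contributions
#' sum to 1 and are invariant to the ICA scale ambiguity.
#'
#' @param dec An [ic_decomposition()].
#' @return Numeric vector of contributions summing to 1.
#' @export
relative_contribution <- function(dec) {
  num <- colSums(dec$V^2) * apply(dec$s, 1L, var)
  if (sum(num) <= 0)
    ll_stop("degenerate_error", "all components have zero power")
  num / sum(num)
}

#' Reconstruct the virtual LFP of one component
#'
#' Removes the ICA scale/sign ambiguity by multiplying the component's time
#' course by its loading at the electrode of maximum absolute loading
#' (`IC_n(t) = V_n(k*) s_n(t)`, in mV). Ties in `|V_n|` resolve to the
#' smallest channel index.
#'
#' @param dec An [ic_decomposition()].
#' @param n Component index.
#' @return Object of class `component_profile`: `index`, `loading`,
#'   `timecourse`, `contribution`, `max_electrode`, `ic` (the reconstructed
#'   trace), `fs`, `depths`.
#' @export
reconstruct_ic <- function(dec, n) {
  if (n < 1L || n > ncol(dec$V))
    ll_stop("validation_error", sprintf("component index %d out of range", n))
  kstar <- which.max(abs(dec$V[, n]))      # first maximum = smallest index
  structure(list(index = n, loading = dec$V[, n], timecourse = dec$s[n, ],
                 contribution = relative_contribution(dec)[n],
                 max_electrode = kstar,
                 ic = dec$V[kstar, n] * dec$s[n, ],
                 fs = dec$fs, depths = dec$depths),
            class = "component_profile")
}

#' @export
print.component_profile <- function(x, ...) {
  cat(sprintf("<component_profile> IC%d: max electrode %d (depth %g um), contribution %.3f\n",
              x$index, x$max_electrode, x$depths[x$max_electrode], x$contribution))
  invisible(x)
}

# all permutations of 1..n (n <= 8 in practice)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (i in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}

#' Match recovered loadings to ground-truth loadings
#'
#' Optimal one-to-one assignment minimizing the total spatial-loading
#' dissimilarity (exhaustive search over permutations; counts are at most the
#' channel count, so this is exact and fast). When the counts differ, the
#' surplus components are flagged unmatched (dummy cost 1).
#'
#' @param V Recovered loadings, channels x components.
#' @param V_star Ground-truth loadings, channels x sources.
#' @param params A [loading_distance_params()].
#' @return List with `assignment` (per recovered component, the matched truth
#'   index or NA), `distances` (matched dissimilarities), `total`, and the full
#'   `dist_matrix`.
#' @export
match_components <- function(V, V_star, params = loading_distance_params()) {
  if (is.null(dim(V)) || is.null(dim(V_star)) || ncol(V) == 0 || ncol(V_star) == 0)
    ll_stop("spec_error", "V and V_star must be non-empty matrices")
  nr <- ncol(V); nt <- ncol(V_star)
  D <- matrix(1, nr, nt)
  for (i in seq_len(nr)) for (j in seq_len(nt))
    D[i, j] <- loading_distance(V[, i], V_star[, j], params)
  m <- max(nr, nt)
  Dp <- matrix(1, m, m)                    # dummy rows/cols cost 1
  Dp[seq_len(nr), seq_len(nt)] <- D
  best <- NULL; best_cost <- Inf
  for (p in all_perms(m)) {
    cost <- sum(Dp[cbind(seq_len(m), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  assignment <- best[seq_len(nr)]
  assignment[assignment > nt] <- NA_integer_
  dist <- rep(NA_real_, nr)
  ok <- !is.na(assignment)
  dist[ok] <- D[cbind(which(ok), assignment[ok])]
  list(assignment = assignment, distances = dist,
       total = sum(dist[ok]), dist_matrix = D)
}
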