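# Loading geometry: Sobolev-type inner product and distance, clustering,
# CSD loadings, and volume-conduction detection.

test_that("loading_inner reduces to the L2 inner product at kappa = 0", {
  set.seed(1)
  v <- rnorm(8); w <- rnorm(8)
  h <- 150
  tw <- h * c(0.5, rep(1, 6), 0.5)
  expect_equal(loading_inner(v, w, loading_distance_params(kappa = 0)),
               sum(tw * v * w), tolerance = 1e-12)
  expect_error_class(loading_inner(v[1:2], w[1:2], loading_distance_params()),
                     "insufficient_support_error")
})

test_that("affine loadings have exactly vanishing curvature terms", {
  h <- 150; x <- seq(550, 1600, by = h)
  v <- 2 + 0.003 * x
  w <- -1 + 0.001 * x
  tw <- h * c(0.5, rep(1, 6), 0.5)
  kap <- 150
  # second-derivative term is exactly zero; first derivatives are constants
  expected <- sum(tw * v * w) + kap * sum(tw * 0.003 * 0.001)
  expect_equal(loading_inner(v, w, loading_distance_params(kappa = kap)),
               expected, tolerance = 1e-10)
})

test_that("8-point inner product matches a dense spline-refined oracle within 5%", {
  x8 <- default_depths()
  V <- make_loadings(default_source_specs(), x8)
  fine <- seq(min(x8), max(x8), length.out = 1000)
  hf <- diff(fine)[1]
  dense_inner <- function(a, b) {
    fa <- stats::splinefun(x8, a); fb <- stats::splinefun(x8, b)
    va <- fa(fine); vb <- fb(fine)
    d1a <- fa(fine, deriv = 1); d1b <- fb(fine, deriv = 1)
    d2a <- fa(fine, deriv = 2); d2b <- fb(fine, deriv = 2)
    trap <- function(y) sum((y[-1] + y[-length(y)]) / 2) * hf
    trap(va * vb) + 150 * trap(d1a * d1b) + 150^2 * trap(d2a * d2b)
  }
  for (pair in list(c(1, 2), c(1, 4), c(2, 3))) {
    coarse <- loading_inner(V[, pair[1]], V[, pair[2]],
                            loading_distance_params())
    expect_equal(coarse, dense_inner(V[, pair[1]], V[, pair[2]]),
                 tolerance = 0.05)
  }
})

test_that("loading_distance has the metric invariances and bounds", {
  set.seed(2)
  v <- rnorm(8)
  pars <- loading_distance_params()
  expect_equal(loading_distance(v, v, pars), 0, tolerance = 1e-12)
  expect_equal(loading_distance(v, -3 * v, pars), 0, tolerance = 1e-12)
  expect_error_class(loading_distance(v, rep(0, 8), pars), "degenerate_error")
  # sampled sine and cosine over one closed period are exactly orthogonal
  # under the plain L2 (kappa = 0) trapezoid rule: their product sin(2x)/2
  # has equal endpoint values, so the trapezoid sum telescopes to zero
  th <- seq(0, 2 * pi, length.out = 65)
  expect_equal(loading_distance(sin(th), cos(th),
                                loading_distance_params(kappa = 0, h = 1)),
               1, tolerance = 1e-10)
  # Cauchy-Schwarz bounds on random pairs
  set.seed(3)
  d <- replicate(2000, loading_distance(rnorm(8), rnorm(8), pars))
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
  # orthogonal perturbation increases d monotonically
  base <- rnorm(8)
  w <- rnorm(8)
  w <- w - base * loading_inner(base, w, pars) / loading_inner(base, base, pars)
  dd <- vapply(c(0.1, 0.5, 1, 2), function(eps)
    loading_distance(base, base + eps * w, pars), numeric(1))
  expect_true(!is.unsorted(dd))
})

test_that("clustering groups jittered archetype replicates perfectly", {
  V <- make_loadings(default_source_specs())
  set.seed(7)
  reps <- do.call(cbind, lapply(1:10, function(r)
    V * (1 + 0.02 * matrix(rnorm(length(V)), nrow(V))) +
      0.02 * matrix(rnorm(length(V)), nrow(V))))
  truth_lab <- rep(1:4, times = 10)
  for (m in c("ward_sobolev", "average_distance")) {
    cl <- cluster_loadings(reps, 4, method = m)
    purity <- mean(vapply(1:4, function(g) {
      tab <- table(truth_lab[cl$labels == g])
      max(tab) / sum(tab)
    }, numeric(1)))
    expect_equal(purity, 1.0)
  }
  # identical copies collapse into one cluster at height 0
  same <- cbind(V[, 1], V[, 1], V[, 1])
  cl1 <- cluster_loadings(same, 1)
  expect_equal(max(cl1$tree$height), 0, tolerance = 1e-10)
  expect_error_class(cluster_loadings(V, 5), "spec_error")
})

test_that("csd_loading is the exact interior second difference", {
  # affine profile -> identically zero CSD
  x <- default_depths()
  aff <- 0.3 + 0.002 * x
  expect_equal(csd_loading(aff, 150)$values, rep(0, 6), tolerance = 1e-15)
  # quadratic with h = 1: I = -2 sigma at every interior point
  k <- 1:8
  expect_equal(csd_loading(k^2, h = 1)$values, rep(-2, 6), tolerance = 1e-12)
  # linear operator
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(csd_loading(2 * a + 3 * b, 150)$values,
               2 * csd_loading(a, 150)$values + 3 * csd_loading(b, 150)$values,
               tolerance = 1e-12)
  expect_error_class(csd_loading(a, 150, depths = c(100, 250, 500, 600, 700, 800, 900, 1000)),
                     "spacing_error")
  expect_error_class(csd_loading(a[1:2], 150), "insufficient_support_error")
})

test_that("CSD of the deep reversing archetype shows a sink/source pair at the reversal", {
  x <- default_depths()
  v <- make_loadings(default_source_specs())[, 2]
  csd <- csd_loading(v, 150)
  # oracle: analytic second derivative of the closed-form loading
  f <- function(z) exp(-(z - 1450)^2 / (2 * 200^2)) -
    exp(-(1000 - 1450)^2 / (2 * 200^2) + (1000 - 550)^2 / (2 * 250^2)) *
    exp(-(z - 550)^2 / (2 * 250^2))
  scale <- max(abs(f(x)))
  num2 <- function(z) (f(z - 1) - 2 * f(z) + f(z + 1)) / 1
  analytic <- -vapply(x[2:7], num2, numeric(1)) / scale
  expect_gt(cor(csd$values, analytic), 0.95)
  # opposite-signed extrema flank the 1000 um reversal
  deep_side <- csd$values[x[2:7] > 1000]
  sup_side <- csd$values[x[2:7] <= 1000]
  expect_true(max(abs(deep_side)) > 0 && max(abs(sup_side)) > 0)
  expect_lt(sign(deep_side[which.max(abs(deep_side))]) *
              sign(sup_side[which.max(abs(sup_side))]), 0)
})

test_that("volume conduction is detected from the curvature score", {
  x <- default_depths()
  aff <- 1 - 0.0006 * x
  r <- is_volume_conducted(aff, 150)
  expect_true(r$volume_conducted)
  expect_equal(r$score, 0, tolerance = 1e-10)
  v2 <- make_loadings(default_source_specs())[, 2]
  expect_false(is_volume_conducted(v2, 150)$volume_conducted)
  # affine plus noise at amplitude SNR 100 still flags as volume conducted
  set.seed(8)
  rms <- sqrt(mean(aff^2))
  flags <- replicate(50, {
    noisy <- aff + rms / 100 * rnorm(8)
    is_volume_conducted(noisy, 150)$volume_conducted
  })
  expect_true(mean(flags) > 0.9)
})
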