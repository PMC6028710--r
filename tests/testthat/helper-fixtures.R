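# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default synthetic session: 18 trials at 500 Hz (the suite's workhorse)
fixture_session <- function() {
  cached("session", function() synth_session(n_trials = 18, fs = 500, seed = 11))
}

# its infomax decomposition
fixture_decomposition <- function() {
  cached("decomposition", function() run_ica(fixture_session()$recording, seed = 3))
}

# a tiny clean recording: known loadings, independent Laplacian sources
fixture_laplacian <- function(seed = 2, n = 20000L) {
  set.seed(seed)
  V <- qr.Q(qr(matrix(rnorm(8 * 4), 8, 4)))      # orthonormal loadings
  S <- matrix(rexp(4 * n) * sign(runif(4 * n) - 0.5), 4, n)
  list(rec = laminar_recording(V %*% S, default_depths(), 1000),
       V = V, S = S)
}

# small recording helper
make_rec <- function(samples, fs = 1000) {
  laminar_recording(samples, seq(550, by = 150, length.out = nrow(samples)), fs)
}

expect_error_class <- function(expr, class) {
  expect_error(expr, class = class)
}
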