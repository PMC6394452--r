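# Shared fixtures, all generated in code.

# Tiny two-condition dataset: condition 2 carries `signal` on
# `signal_channels` over the second half of the epoch.
tiny_dataset <- function(n_timepoints = 20, n_channels = 6, n_epochs = 30,
                         signal = 0, signal_channels = 1:3, n_runs = 1,
                         seed = 1) {
  noise <- simulate_signal_dataset(synthetic_spec(
    n_timepoints = n_timepoints, n_channels = n_channels, n_epochs = n_epochs,
    signal_value = 0, n_runs = n_runs, rng_seed = seed))
  sig <- simulate_signal_dataset(synthetic_spec(
    n_timepoints = n_timepoints, n_channels = n_channels, n_epochs = n_epochs,
    signal_value = signal, signal_channels = signal_channels,
    signal_timepoints = (n_timepoints %/% 2 + 1):n_timepoints,
    n_runs = n_runs, rng_seed = seed + 1000))
  combine_conditions(noise, sig)
}

# Independently coded projected-gradient solver for the same augmented-bias
# dual problems, used as the optimisation oracle on tiny inputs.
qp_svc_oracle <- function(x, y, C, iters = 20000, lr = NULL) {
  xs <- cbind(x, 1)
  n <- nrow(xs)
  K <- xs %*% t(xs)
  Q <- (y %*% t(y)) * K
  lr <- lr %||% (1 / max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values))
  a <- rep(0, n)
  for (i in seq_len(iters)) {
    g <- drop(Q %*% a) - 1
    a <- pmin(pmax(a - lr * g, 0), C)
  }
  drop(t(xs) %*% (a * y))
}

qp_svr_oracle <- function(x, y, C, eps = 0.1, iters = 20000, lr = NULL) {
  xs <- cbind(x, 1)
  K <- xs %*% t(xs)
  lr <- lr %||% (1 / max(eigen(K, symmetric = TRUE, only.values = TRUE)$values))
  b <- rep(0, nrow(xs))
  for (i in seq_len(iters)) {
    g <- drop(K %*% b) - y
    z <- b - lr * g
    thr <- lr * eps
    b <- pmin(pmax(sign(z) * pmax(abs(z) - thr, 0), -C), C)
  }
  drop(t(xs) %*% b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a small python oracle script, returning its stdout lines.
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  system2("python", f, stdout = TRUE, stderr = FALSE)
}
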