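## Shared fixtures, memoized across test files (helpers are sourced once
## per test run). All sessions are generated in code; nothing is stored.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

## Small paired session (enough trials for structural tests, cheap).
small_pair <- function() memo("small_pair", {
  generate_session(synth_config(duration_s = 90, seed = 101))
})

## Study-scale paired session: the generator defaults (~400 trials).
default_pair <- function() memo("default_pair", {
  generate_session(synth_config(duration_s = 240, seed = 42))
})

## Full pipeline report on the study-scale pair.
default_report <- function() memo("default_report", {
  gs <- default_pair()
  run_all(gs$flash, gs$flash_ac, analysis_config(seed = 7))
})

## Minimal hand-built session: deterministic signals on 3+ contacts.
toy_session <- function(signals, fs = 2000, onsets = numeric(0),
                        condition = "FLASH", ...) {
  recording_session(signals, fs, onsets, condition, ...)
}

## Hand-built epoch set for the cluster statistics tests.
make_epochs <- function(n_tr, nc, nt, seed, delta = 0, contacts = NULL,
                        times = NULL, t0_ms = -50) {
  set.seed(seed)
  d <- array(stats::rnorm(n_tr * nc * nt), c(n_tr, nc, nt))
  if (!is.null(contacts))
    d[, contacts, times] <- d[, contacts, times] + delta
  structure(list(data = d, t_ms = seq(t0_ms, length.out = nt),
                 baseline_corrected = TRUE, keep_mask = rep(TRUE, n_tr),
                 condition = "FLASH", trial_index = seq_len(n_tr)),
            class = "epoch_set")
}

## von Mises sampler (Best & Fisher rejection scheme) for circular
## power checks; independent of the package's statistics.
rvonmises <- function(n, mu_deg, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      out[i] <- sign(u[3] - 0.5) * acos(f)
    }
  }
  lamtacs::wrap_deg(mu_deg + out * 180 / pi)
}
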