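# Fixtures built in code: small separable window sets and tiny cohorts.

# Trivially separable binary windows: class 0 is low-amplitude noise, class 1
# a strong two-harmonic oscillation. Labels are 0/1 as in the walking task.
make_separable_windows <- function(n = 64L, len = 64L, rate_hz = len / 2,
                                   seed = 1L, sd_noise = 0.3) {
  set.seed(seed)
  x <- array(0, c(n, len, 3L))
  y <- rep(c(0L, 1L), length.out = n)
  tt <- (seq_len(len) - 1L) / rate_hz
  for (i in seq_len(n)) {
    for (j in 1:3) {
      x[i, , j] <- stats::rnorm(len, sd = sd_noise) +
        if (y[i] == 1L) sin(2 * pi * 2 * tt + j) + 0.4 * sin(2 * pi * 4 * tt) else 0
    }
  }
  harshift:::.window_set(x, y, rep(1L, n), "toy", rate_hz)
}

# Small cohort with short sessions for pipeline tests.
tiny_cohort <- function(n_subjects = 4L, sidebar_ids = 2L, seed = 7L,
                        walk_min = 0.1, nonwalk_min = 1) {
  simulate_cohort(make_cohort(n_subjects, sidebar_ids, seed = seed),
                  harvar_sensors(), walk_min_per_speed = walk_min,
                  nonwalk_min = nonwalk_min)
}

# Quick training profile for tests.
test_train_config <- function(...) {
  fast_train_config(max_epochs = 6L, early_stop_patience = 4,
                    anneal_patience = 2L, batch_size = 64L, ...)
}
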