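# Shared fixtures, built in code at test time.

# Small multi-state study spec used across files.
tiny_spec <- function(n_subjects = 3, n_sessions = 2, n_parcels = 12,
                      n_networks = 3, seed = 7, ...) {
  synth_spec(n_subjects = n_subjects, n_sessions = n_sessions,
             n_parcels = n_parcels, n_networks = n_networks,
             frames_per_run = c(rest = 120, motor = 100),
             runs_per_state = c(rest = 1L, motor = 1L),
             seed = seed, ...)
}

# One simulated dataset on disk, built once per test run.
tiny_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.json"))) {
      dir <<- file.path(tempdir(), "fcreliab-tiny-ds")
      simulate_dataset(tiny_spec(), dir, overwrite = TRUE)
    }
    dir
  }
})

# Brute-force Pearson r between two vectors.
pearson_loop <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) /
    sqrt(sum((a - am)^2) * sum((b - bm)^2))
}
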