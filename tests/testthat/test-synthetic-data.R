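test_that("ground truth builds the planted block structure", {
  # equal within/between -> uniform off-diagonal, no block structure
  sp <- tiny_spec(within_network_r = 0.3, between_network_r = 0.3)
  gt <- build_ground_truth(sp)
  off <- gt$base_covariance[upper.tri(gt$base_covariance)]
  expect_true(all(off == 0.3))
  expect_true(all(diag(gt$base_covariance) == 1))

  # zero subject perturbation -> all subject matrices equal base
  sp0 <- tiny_spec(subject_edge_sd = 0)
  gt0 <- build_ground_truth(sp0)
  for (m in gt0$subject_covariances)
    expect_identical(m, gt0$base_covariance)

  # partition has exactly n_networks non-empty groups; matrices PD
  sp2 <- tiny_spec(n_parcels = 60, n_networks = 3,
                   within_network_r = 0.5, between_network_r = 0.05)
  gt2 <- build_ground_truth(sp2)
  expect_equal(length(unique(gt2$partition)), 3L)
  expect_true(all(tabulate(gt2$partition) > 0))
  for (m in gt2$subject_covariances) {
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("planted partition maximizes modularity on a 12-parcel downscale", {
  # brute force: enumerate every partition of 12 parcels into <= 3 blocks
  # (restricted growth strings) and compute weighted modularity from first
  # principles; the planted partition must attain the unique maximum.
  sp <- synth_spec(n_subjects = 1, n_sessions = 1, n_parcels = 12,
                   n_networks = 3, frames_per_run = c(rest = 50),
                   runs_per_state = c(rest = 1L),
                   within_network_r = 0.5, between_network_r = 0.05, seed = 1)
  gt <- build_ground_truth(sp)
  W <- gt$base_covariance; diag(W) <- 0
  two_m <- sum(W)
  k <- rowSums(W)
  B <- W - outer(k, k) / two_m
  qmod <- function(a) sum(B[outer(a, a, "==")]) / two_m
  planted <- gt$partition
  q0 <- qmod(planted)
  # iterate restricted growth strings with at most 3 labels
  a <- rep(1L, 12)
  best <- -Inf; best_a <- NULL
  repeat {
    q <- qmod(a)
    if (q > best) { best <- q; best_a <- a }
    # next RGS: a[i] may rise to min(max(a[1..i-1]) + 1, 3)
    i <- 12L
    while (i > 1L) {
      cap <- min(max(a[seq_len(i - 1L)]) + 1L, 3L)
      if (a[i] < cap) { a[i] <- a[i] + 1L; a[seq_len(12L - i) + i] <- 1L; break }
      i <- i - 1L
    }
    if (i == 1L) break
  }
  expect_equal(best, q0, tolerance = 1e-12)
  expect_equal(adjusted_rand(best_a, planted), 1)
  # and community detection on the noiseless matrix recovers it exactly
  part <- detect_communities(density_threshold(gt$base_covariance, 0.3),
                             n_reps = 10, seed = 3)
  expect_equal(adjusted_rand(part$membership, planted), 1)
})

test_that("non-positive-definite targets are rejected with a diagnostic", {
  expect_error(
    build_ground_truth(
      synth_spec(n_parcels = 12, n_networks = 6,
                 frames_per_run = c(rest = 50),
                 runs_per_state = c(rest = 1L),
                 within_network_r = 0, between_network_r = -0.4, seed = 1)),
    "eigenvalue")
})

test_that("simulated runs are deterministic and converge to the target", {
  sp <- tiny_spec()
  gt <- build_ground_truth(sp)
  a <- simulate_run(gt, 2, 1, "motor", sp)
  b <- simulate_run(gt, 2, 1, "motor", sp)
  expect_identical(a$run$data, b$run$data)
  expect_identical(a$motion, b$motion)
  # different run index differs
  c2 <- simulate_run(gt, 2, 1, "motor", sp, run = 2L)
  expect_false(identical(a$run$data, c2$run$data))
  # rest has an empty event table
  expect_equal(nrow(simulate_run(gt, 1, 1, "rest", sp)$events), 0L)
  expect_error(simulate_run(gt, 1, 1, "swimming", sp), "unknown state")

  # covariance fidelity: per-edge error strictly decreases with length,
  # and the 50k-frame run is within 0.02 per edge
  sp6 <- synth_spec(n_subjects = 1, n_sessions = 1, n_parcels = 6,
                    n_networks = 2, frames_per_run = c(rest = 50000),
                    runs_per_state = c(rest = 1L), subject_edge_sd = 0,
                    motion_spike_prob = 0, seed = 5)
  gt6 <- build_ground_truth(sp6)
  target <- gt6$base_covariance
  errs <- sapply(c(500, 5000, 50000), function(T) {
    sp_t <- sp6; sp_t$frames_per_run <- c(rest = T)
    Y <- simulate_run(gt6, 1, 1, "rest", sp_t)$run$data
    max(abs(stats::cor(Y) - target))
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("parcel means are recovered and the evoked term is local", {
  sp <- synth_spec(n_subjects = 1, n_sessions = 1, n_parcels = 8,
                   n_networks = 2,
                   frames_per_run = c(rest = 4000, motor = 400),
                   runs_per_state = c(rest = 1L, motor = 1L),
                   parcel_mean_profile = c(800, rep(700, 7)),
                   parcel_sd_profile = rep(10, 8),
                   motion_spike_prob = 0, seed = 9)
  gt <- build_ground_truth(sp)
  Y <- simulate_run(gt, 1, 1, "rest", sp)$run$data
  se <- sd(Y[, 1]) / sqrt(nrow(Y))
  expect_lt(abs(mean(Y[, 1]) - 800), 3 * se)

  # evoked locality: amplitude-0 run equals the task run exactly in
  # non-engaged parcels (same seed), differs in engaged ones
  eng <- sp$engaged_parcels$motor
  sp0 <- sp; sp0$task_designs$motor$amplitude <- 0
  y1 <- simulate_run(gt, 1, 1, "motor", sp)$run$data
  y0 <- simulate_run(gt, 1, 1, "motor", sp0)$run$data
  expect_identical(y1[, -eng], y0[, -eng])
  expect_true(all(colSums(abs(y1[, eng, drop = FALSE] -
                                y0[, eng, drop = FALSE])) > 0))
})

test_that("simulate_dataset writes the declared tree deterministically", {
  sp <- synth_spec(n_subjects = 2, n_sessions = 3, n_parcels = 6,
                   n_networks = 2, frames_per_run = c(rest = 40, motor = 40),
                   runs_per_state = c(rest = 1L, motor = 1L), seed = 3)
  d1 <- file.path(tempdir(), "ds-count")
  man <- simulate_dataset(sp, d1, overwrite = TRUE)
  # 2 subjects x 3 sessions x (1 rest + 1 motor) = 12 runs
  expect_equal(length(man$runs), 12L)
  expect_equal(sum(grepl("_bold\\.tsv$", list.files(d1))), 12L)
  # manifest refuses to clobber
  expect_error(simulate_dataset(sp, d1), "overwrite")
  # variance components pass through the spec values exactly
  expect_equal(man$variance_components$sigma_lambda2, sp$subject_edge_sd^2)
  # different seed -> at least one run file differs byte-wise
  sp2 <- sp; sp2$seed <- 4L
  d2 <- file.path(tempdir(), "ds-count2")
  simulate_dataset(sp2, d2, overwrite = TRUE)
  f <- "sub-01_ses-01_task-rest_run-01_bold.tsv"
  expect_false(identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f))))
  # same spec re-simulated reproduces bit-identical output
  d3 <- file.path(tempdir(), "ds-count3")
  simulate_dataset(sp, d3, overwrite = TRUE)
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d3, f)))
})

test_that("edge-level generator hits the requested reliability ratio", {
  arr <- simulate_icc_edges(20, rho = 0.5, n_edges = 300, seed = 8)
  # empirical between/total variance ratio across subjects/halves
  ratios <- apply(arr, 3, function(tab) {
    lam_hat <- rowMeans(tab)
    v_b <- stats::var(lam_hat) - stats::var(tab[, 1] - tab[, 2]) / 4
    v_w <- stats::var(tab[, 1] - tab[, 2]) / 2
    v_b / (v_b + v_w)
  })
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})
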