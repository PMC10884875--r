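test_that("FIR designs have the standard bin geometry", {
  tbl <- default_fir_table()
  # motor: 5 conditions x 7 bins of 2.2 s in a 15.4 s window
  expect_equal(nrow(tbl$motor), 5L)
  expect_true(all(tbl$motor$n_bins == 7L))
  expect_true(all(tbl$motor$bin_width == 2.2))
  expect_equal(tbl$motor$window, rep(15.4, 5))
  # language events: 8 x 1.5 s = 12 s; sustained 1 x 121 s; cues 1 x 2.2 s
  lang <- tbl$language
  expect_equal(lang$window[lang$condition == "noun"], 12)
  expect_equal(lang$n_bins[lang$condition == "sustained_verbal"], 1L)
  expect_equal(lang$bin_width[lang$condition == "sustained_verbal"], 121)
  expect_equal(lang$bin_width[lang$condition == "cue_start"], 2.2)
  # memory: 9 stimulus x repetition conditions at 8 x 1.5 s
  expect_equal(nrow(tbl$memory), 9L)
  expect_true(all(tbl$memory$n_bins == 8L))
  # one motor condition contributes exactly 7 design columns
  ev <- data.frame(onset = 11, duration = 2.2, trial_type = "tongue")
  des <- build_fir_design(ev, tbl$motor, n_frames = 40, tr = 2.2)
  expect_equal(sum(des$condition == "tongue"), 7L)
  expect_equal(ncol(des$design), 35L)   # 5 conditions x 7 bins
})

test_that("frame-aligned bins give shifted unit impulses", {
  tr <- 2
  ev <- data.frame(onset = 0, duration = 2, trial_type = "a")
  sp <- fir_spec("a", n_bins = 3L, bin_width = tr)
  des <- build_fir_design(ev, sp, n_frames = 10, tr = tr, microtime_dt = tr)
  X <- des$design
  expect_equal(X[1:3, ], diag(3), ignore_attr = TRUE)
  expect_true(all(X[4:10, ] == 0))
})

test_that("sub-frame bins equal fractional coverage (dense-grid oracle)", {
  tr <- 2.2
  ev <- data.frame(onset = c(3.1, 20.4), duration = 0.5,
                   trial_type = "stim")
  sp <- fir_spec("stim", n_bins = 8L, bin_width = 1.5)
  des <- build_fir_design(ev, sp, n_frames = 20, tr = tr, microtime_dt = 0.1)
  # independent oracle: integrate coverage on a 1 ms grid
  dt <- 0.001
  n_micro <- round(20 * tr / dt)
  mid <- (seq_len(n_micro) - 0.5) * dt
  frame_of <- pmin(floor(mid / tr) + 1, 20)
  for (b in 0:7) {
    col <- numeric(n_micro)
    for (onset in ev$onset) {
      lo <- onset + b * 1.5; hi <- onset + (b + 1) * 1.5
      col[mid >= lo & mid < hi] <- col[mid >= lo & mid < hi] + 1
    }
    want <- as.numeric(tapply(col, frame_of, mean))
    expect_equal(des$design[, b + 1], want, tolerance = 0.03)
  }
  # events past the run end are truncated and counted
  ev2 <- data.frame(onset = 20 * tr - 3, duration = 0.5, trial_type = "stim")
  des2 <- build_fir_design(ev2, sp, n_frames = 20, tr = tr)
  expect_gt(des2$n_truncated, 0)
  expect_error(build_fir_design(
    data.frame(onset = 1, duration = 1, trial_type = "zzz"), sp, 20, tr),
    "unknown condition")
  expect_error(build_fir_design(ev, fir_spec("stim", 2L, 0.05), 20, tr),
               "microtime_dt")
})

test_that("the GLM recovers exact betas and matches normal equations", {
  set.seed(14)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  B <- matrix(c(2, -1, 0.5, 1, 0, 3), 3, 2)
  Y <- X %*% B + 5   # intercept 5
  fit <- fit_glm(Y, X)
  expect_lt(max(abs(fit$betas[1:3, ] - B)), 1e-10)
  expect_lt(max(abs(fit$betas[4, ] - 5)), 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # residuals orthogonal to the design
  expect_lt(max(abs(t(cbind(X, 1)) %*% fit$residuals)), 1e-8 * max(abs(Y)))
  # random case vs explicit (X'X)^-1 X'y
  Y2 <- matrix(rnorm(n * 2), n, 2)
  fit2 <- fit_glm(Y2, X)
  Xi <- cbind(X, 1)
  want <- solve(t(Xi) %*% Xi, t(Xi) %*% Y2)
  expect_lt(max(abs(fit2$betas - want)), 1e-10)
  # series orthogonal to regressors -> betas ~ 0
  q <- qr.Q(qr(cbind(X, 1)))
  y_perp <- (diag(n) - q %*% t(q)) %*% rnorm(n)
  fit3 <- fit_glm(y_perp, X)
  expect_lt(max(abs(fit3$betas)), 1e-10)
  # censored frames are row-deleted and get NA residuals
  cens <- rep(TRUE, n); cens[c(3, 9)] <- FALSE
  fit4 <- fit_glm(Y2, X, censor = cens)
  expect_true(all(is.na(fit4$residuals[c(3, 9), ])))
  want4 <- solve(t(Xi[cens, ]) %*% Xi[cens, ], t(Xi[cens, ]) %*% Y2[cens, ])
  expect_lt(max(abs(fit4$betas - want4)), 1e-10)
  # rank-deficient design flagged, fit still returned
  Xdup <- cbind(X, X[, 1])
  fit5 <- fit_glm(Y2, Xdup)
  expect_true(any(fit5$aliased))
})

test_that("averaged contrasts weight bins uniformly", {
  tr <- 2
  ev <- data.frame(onset = c(4, 30), duration = 2, trial_type = "a")
  sp <- fir_spec("a", n_bins = 8L, bin_width = 2)
  des <- build_fir_design(ev, sp, n_frames = 40, tr = tr)
  set.seed(15)
  Y <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_glm(Y, des)
  got <- average_contrast(fit, "a")
  # 8 bins -> weight 1/8 = 0.125 each
  want <- as.numeric(rep(0.125, 8) %*% fit$betas[1:8, ])
  expect_equal(got, want, tolerance = 1e-12)
  # bins all equal to 2 -> PE 2; bins [1, -1] -> PE 0
  fit_const <- fit
  fit_const$betas[1:8, 1] <- 2
  expect_equal(average_contrast(fit_const, "a")[1], 2)
  sp2 <- fir_spec("b", n_bins = 2L, bin_width = 2)
  des2 <- build_fir_design(data.frame(onset = 4, duration = 2,
                                      trial_type = "b"), sp2, 40, tr)
  fit2 <- fit_glm(Y, des2)
  fit2$betas[1:2, 1] <- c(1, -1)
  expect_equal(average_contrast(fit2, "b")[1], 0)
  expect_error(average_contrast(fit, "zzz"), "not in design")
})

test_that("residualization removes modeled signal and never adds variance", {
  tr <- 2
  ev <- data.frame(onset = c(4, 30), duration = 2, trial_type = "a")
  des <- build_fir_design(ev, fir_spec("a", 4L, 2), n_frames = 40, tr = tr)
  # noiseless evoked signal -> residuals ~ 0
  amp <- c(1, 2, 2, 1)
  y_evoked <- des$design %*% amp + 3
  expect_lt(max(abs(residualize(y_evoked, des))), 1e-8)
  # intercept-only design -> residual = centered series
  y <- rnorm(40)
  res0 <- residualize(cbind(y), matrix(0, 40, 0))
  expect_equal(as.numeric(res0), y - mean(y), tolerance = 1e-10)
  # projection property: residual variance <= input variance per unit
  set.seed(16)
  Y <- matrix(rnorm(40 * 5), 40, 5)
  res <- residualize(Y, des)
  expect_true(all(apply(res, 2, var) <= apply(Y, 2, var) + 1e-12))
})

test_that("PE aggregation is a nested mean over the hierarchy", {
  rec <- function(s, d, cond, pe) list(subject = s, session = d,
                                       condition = cond, pe = pe)
  # identical run PEs -> all levels equal that value
  same <- list(rec(1, 1, "a", c(2, 2)), rec(1, 1, "a", c(2, 2)),
               rec(1, 2, "a", c(2, 2)))
  agg <- aggregate_pes(same)
  expect_equal(agg$group, c(2, 2))
  expect_equal(agg$subject[["1"]], c(2, 2))
  # two subjects with PEs 1 and 3 -> group 2
  two <- list(rec(1, 1, "a", 1), rec(2, 1, "a", 3))
  expect_equal(aggregate_pes(two)$group, 2)
  # random hierarchy vs the nested-mean loop oracle
  set.seed(17)
  recs <- list()
  for (s in 1:2) for (d in 1:2) for (cond in c("a", "b")) for (r in 1:2)
    recs[[length(recs) + 1L]] <- rec(s, d, cond, rnorm(3))
  agg2 <- aggregate_pes(recs)
  oracle_subject <- lapply(1:2, function(s) {
    conds <- sapply(c("a", "b"), function(cond) {
      sess <- sapply(1:2, function(d) {
        sel <- Filter(function(x) x$subject == s && x$session == d &&
                        x$condition == cond, recs)
        rowMeans(sapply(sel, `[[`, "pe"))
      })
      rowMeans(sess)
    })
    rowMeans(conds)
  })
  expect_equal(agg2$subject[["1"]], oracle_subject[[1]], tolerance = 1e-12)
  expect_equal(agg2$subject[["2"]], oracle_subject[[2]], tolerance = 1e-12)
  expect_equal(agg2$group, (oracle_subject[[1]] + oracle_subject[[2]]) / 2,
               tolerance = 1e-12)
})

test_that("group PEs localize to engaged parcels on synthetic data", {
  sp <- synth_spec(n_subjects = 3, n_sessions = 1, n_parcels = 16,
                   n_networks = 4, frames_per_run = c(rest = 100, motor = 150),
                   runs_per_state = c(rest = 1L, motor = 1L),
                   motion_spike_prob = 0, seed = 18)
  gt <- build_ground_truth(sp)
  recs <- list()
  for (s in 1:3) {
    sim <- simulate_run(gt, s, 1, "motor", sp)
    des <- build_fir_design(sim$events,
                            fir_spec("motor", sp$task_designs$motor$n_bins,
                                     sp$task_designs$motor$bin_width),
                            n_frames = nrow(sim$run$data), tr = sp$tr)
    fit <- fit_glm(sim$run, des)
    recs[[s]] <- list(subject = s, session = 1, condition = "motor",
                      pe = average_contrast(fit, "motor"))
  }
  grp <- aggregate_pes(recs)$group
  eng <- sp$engaged_parcels$motor
  expect_gt(min(grp[eng]), max(abs(grp[-eng])))
})
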