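test_that("pearson connectome matches the element-wise loop oracle", {
  a <- rnorm(4)
  m <- cbind(a, 2 * a, -a + 1e-14 * rnorm(4))
  cn <- pearson_connectome(m)
  expect_equal(cn$matrix[1, 2], 1, tolerance = 1e-9)
  expect_equal(cn$matrix[1, 3], -1, tolerance = 1e-9)
  set.seed(5)
  Y <- matrix(rnorm(12), 4, 3)
  got <- pearson_connectome(Y)$matrix
  for (i in 1:3) for (j in 1:3) {
    want <- if (i == j) 1 else pearson_loop(Y[, i], Y[, j])
    expect_equal(got[i, j], want, tolerance = 1e-12)
  }
  expect_equal(got, t(got), tolerance = 1e-15)
  # zero-variance unit becomes a missing sentinel, not silent zero
  Y2 <- cbind(Y, 0)
  cn2 <- pearson_connectome(Y2)
  expect_true(all(is.na(cn2$matrix[4, -4])))
  expect_equal(cn2$n_missing_units, 1L)
  expect_error(pearson_connectome(Y[1:2, ]), "3 retained frames")
})

test_that("session splitting uses first-half/last-half session order", {
  sess <- lapply(1:10, function(i) matrix(rnorm(40), 10, 4))
  pair <- split_half(sess)
  expect_equal(pair$sessions, list(1:5, 6:10))
  expect_equal(split_half(sess[1:2])$sessions, list(1L, 2L))
  expect_error(split_half(sess[1:3]), "even")
  # explicit split accepted for odd counts
  pr <- split_half(sess[1:3], split = list(1:2, 3))
  expect_equal(pr$sessions, list(1:2, 3))
  expect_error(split_half(sess, split = list(1:5, 4:10)), "disjoint")
  # identical data in every session -> identical half connectomes
  same <- lapply(1:4, function(i) sess[[1]])
  pr2 <- split_half(same)
  expect_equal(pr2$first$matrix, pr2$second$matrix, tolerance = 1e-12)
})

test_that("FC-TRC equals the per-row correlation excluding self-entries", {
  set.seed(6)
  Y1 <- matrix(rnorm(200), 50, 4)
  Y2 <- matrix(rnorm(200), 50, 4)
  pair <- list(first = pearson_connectome(Y1), second = pearson_connectome(Y2))
  got <- fc_trc(pair)
  for (u in 1:4)
    expect_equal(as.numeric(got)[u],
                 pearson_loop(pair$first$matrix[u, -u],
                              pair$second$matrix[u, -u]),
                 tolerance = 1e-12)
  # identical connectomes -> 1 everywhere
  pid <- list(first = pair$first, second = pair$first)
  expect_equal(as.numeric(fc_trc(pid)), rep(1, 4), tolerance = 1e-12)
  # negated off-diagonal -> -1 everywhere
  neg <- pair$first
  neg$matrix <- -pair$first$matrix
  diag(neg$matrix) <- 1
  pneg <- list(first = pair$first, second = neg)
  expect_equal(as.numeric(fc_trc(pneg)), rep(-1, 4), tolerance = 1e-12)
  # missing unit excluded pairwise, exclusions counted
  miss <- pair$second
  miss$matrix[2, ] <- NA; miss$matrix[, 2] <- NA
  pm <- list(first = pair$first, second = miss)
  gm <- fc_trc(pm)
  expect_true(is.na(as.numeric(gm)[2]))
  expect_gt(attr(gm, "n_excluded"), 0)
})

test_that("ICC(2,1) matches an independent ANOVA oracle and its identities", {
  # halves identical, subjects differ -> ICC 1
  expect_equal(icc_2_1(cbind(1:3, 1:3))$value, 1)
  # all entries equal -> undefined with reason
  out0 <- icc_2_1(matrix(2, 4, 2))
  expect_true(is.na(out0$value))
  expect_match(out0$reason, "zero total variance")
  # random 5 x 2 table vs explicit mean-squares oracle via aov
  set.seed(7)
  tab <- matrix(rnorm(10, 0.4, 0.2), 5, 2)
  got <- icc_2_1(tab)
  d <- data.frame(y = as.vector(tab),
                  subj = factor(rep(1:5, 2)),
                  half = factor(rep(1:2, each = 5)))
  ms <- anova(stats::lm(y ~ subj + half, d))[["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  want <- (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / 5)
  expect_equal(got$value, want, tolerance = 1e-12)
  expect_equal(got$ms[["MSR"]], MSR, tolerance = 1e-12)
  expect_equal(got$sigma_eps2, MSE, tolerance = 1e-12)
  # invariance: adding a constant and positive scaling leave ICC unchanged
  expect_equal(icc_2_1(tab + 5)$value, got$value, tolerance = 1e-12)
  expect_equal(icc_2_1(tab * 3)$value, got$value, tolerance = 1e-12)
  # negative estimates reported as computed, flagged
  tab_neg <- cbind(c(1, 2), c(2, 1))
  got_neg <- icc_2_1(tab_neg)
  expect_lt(got_neg$value, 0)
  expect_true(got_neg$negative_components)
  expect_gte(icc_2_1(tab_neg, truncate = TRUE)$sigma_lambda2, 0)
})

test_that("edge-wise ICC vectorizes the upper triangle per subject", {
  set.seed(8)
  mk_pair <- function() {
    list(first = pearson_connectome(matrix(rnorm(80), 20, 4)),
         second = pearson_connectome(matrix(rnorm(80), 20, 4)))
  }
  pairs <- lapply(1:5, function(i) mk_pair())
  res <- icc_edgewise(pairs)
  expect_equal(length(res$edge_icc), 6L)      # 4 choose 2
  # spot-check one edge against icc_2_1 directly
  e <- 3
  i <- res$edge_index[e, 1]; j <- res$edge_index[e, 2]
  tab <- t(sapply(pairs, function(p)
    c(p$first$matrix[i, j], p$second$matrix[i, j])))
  expect_equal(res$edge_icc[e], icc_2_1(tab)$value, tolerance = 1e-12)
  # parcel aggregation is the mean over incident edges
  p <- 2
  inc <- res$edge_index[, 1] == p | res$edge_index[, 2] == p
  expect_equal(res$parcel_icc[p], mean(res$edge_icc[inc]), tolerance = 1e-12)
})

test_that("ICC bands follow the conventional ranges with closed gaps", {
  expect_equal(classify_icc(c(0.3, 0.65, 0.75)),
               c("poor", "good", "excellent"))
  expect_equal(classify_icc(c(-0.2, 0, 0.4)), rep("poor", 3))
  expect_equal(classify_icc(c(0.41, 0.59, 0.599)), rep("fair", 3))
  expect_equal(classify_icc(c(0.6, 0.74, 0.749)), rep("good", 3))
  expect_equal(classify_icc(c(0.8, 1)), rep("excellent", 2))
  expect_true(is.na(classify_icc(NA_real_)))
})

test_that("delta maps and group summaries reduce as stated", {
  a <- structure(runif(6), class = "reliability_map")
  expect_equal(unclass(delta_map(a, a)), rep(0, 6))
  b <- structure(rep(0.5, 6), class = "reliability_map")
  d <- structure(rep(0.7, 6), class = "reliability_map")
  expect_equal(unclass(delta_map(d, b)), rep(0.2, 6))
  set.seed(9)
  x <- structure(rnorm(6), class = "reliability_map")
  y <- structure(rnorm(6), class = "reliability_map")
  expect_equal(unclass(delta_map(x, y)), unclass(x) - unclass(y))
  expect_error(delta_map(a, structure(1:3, class = "reliability_map")),
               "mismatch")
  # group summary: identical maps -> SD 0; two maps give closed-form SD
  gs0 <- group_summary(list(a, a, a))
  expect_equal(gs0$sd, rep(0, 6))
  g2 <- group_summary(list(structure(rep(0.2, 3), class = "reliability_map"),
                           structure(rep(0.6, 3), class = "reliability_map")))
  expect_equal(g2$mean, rep(0.4, 3))
  expect_equal(g2$sd, rep(sqrt(2 * 0.2^2 / 1), 3), tolerance = 1e-12)
  # mean invariant to subject order
  gs1 <- group_summary(list(x, y))
  gs2 <- group_summary(list(y, x))
  expect_equal(gs1$mean, gs2$mean)
})
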