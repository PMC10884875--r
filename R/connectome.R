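#' Pearson functional connectome
#'
#' Unit-by-unit Pearson correlation over retained frames, symmetric with
#' diagonal stored as 1 (the diagonal is excluded from all downstream
#' statistics). Zero-variance units get a missing (NA) row/column rather
#' than a silent zero, and the count of such units is attached.
#'
#' @param series frames x units matrix (already censored/centered), or a
#'   [bold_run] whose retained frames are used.
#' @return object of class `connectome`: list with `matrix`, `n_frames`,
#'   `n_missing_units`.
#' @export
pearson_connectome <- function(series) {
  if (inherits(series, "bold_run")) series <- retained_frames(series)
  series <- as.matrix(series)
  if (nrow(series) < 3L)
    stop("pearson_connectome: need at least 3 retained frames")
  sds <- apply(series, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(series))
  if (length(bad)) {
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(list(matrix = r, n_frames = nrow(series),
                 n_missing_units = length(bad)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d x %d units from %d frames", nrow(x$matrix),
              ncol(x$matrix), x$n_frames))
  if (x$n_missing_units) cat(sprintf(" (%d missing units)", x$n_missing_units))
  cat("\n")
  invisible(x)
}

#' Split sessions into two half connectomes
#'
#' Divides an ordered list of per-session series into a first and second
#' half by session order (with 10 sessions: 1-5 versus 6-10), builds one
#' connectome per half from the concatenated frames.
#'
#' @param session_series ordered list of frames x units matrices, one per
#'   session (already censored and centered per run).
#' @param split optional list of two integer vectors of session indices;
#'   defaults to first half / last half, requiring an even count.
#' @return list of class `split_half_pair` with `first` and `second`
#'   [pearson_connectome()] results and the session index sets.
#' @export
split_half <- function(session_series, split = NULL) {
  n <- length(session_series)
  if (is.null(split)) {
    if (n < 2L || n %% 2L != 0L)
      stop("split_half: need an even number of sessions >= 2, or an explicit split")
    split <- list(seq_len(n / 2), seq(n / 2 + 1, n))
  }
  stopifnot(length(split) == 2L)
  if (length(intersect(split[[1]], split[[2]])) ||
      !setequal(c(split[[1]], split[[2]]), seq_len(n)))
    stop("split_half: split must partition the sessions disjointly and exhaustively")
  half <- function(idx)
    pearson_connectome(do.call(rbind, session_series[idx]))
  structure(list(first = half(split[[1]]), second = half(split[[2]]),
                 sessions = split),
            class = "split_half_pair")
}

#' FC test-retest correlation (FC-TRC)
#'
#' For each unit, the spatial Pearson correlation between that unit's
#' connectivity row in the first-half connectome and the same row in the
#' second-half connectome, excluding the self-correlation entry from
#' both vectors. Raw r values are correlated (no Fisher z). Units that
#' are missing in either half are excluded pairwise from every row
#' correlation that touches them; the exclusion count is recorded.
#'
#' @param pair a [split_half] result (or any list with `first`/`second`
#'   connectomes on the same unit space).
#' @return object of class `reliability_map`: numeric per-unit vector
#'   with attribute `n_excluded`.
#' @export
fc_trc <- function(pair) {
  A <- pair$first$matrix
  B <- pair$second$matrix
  if (!all(dim(A) == dim(B)))
    stop("fc_trc: half connectomes have mismatched unit spaces")
  P <- nrow(A)
  out <- numeric(P)
  n_excl <- 0L
  for (u in seq_len(P)) {
    a <- A[u, -u]
    b <- B[u, -u]
    ok <- is.finite(a) & is.finite(b)
    n_excl <- n_excl + sum(!ok)
    out[u] <- if (sum(ok) >= 3L) stats::cor(a[ok], b[ok]) else NA_real_
  }
  structure(out, class = "reliability_map", n_excluded = n_excl)
}

#' @export
print.reliability_map <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<reliability_map> %d units, mean %.3f [%.3f, %.3f]\n",
              length(v), mean(v, na.rm = TRUE), min(v, na.rm = TRUE),
              max(v, na.rm = TRUE)))
  invisible(x)
}

#' ICC(2,1) for one edge
#'
#' Two-way random-effects, single-measurement, absolute-agreement
#' intraclass correlation from the ANOVA mean squares of a subjects x
#' raters table (here raters = the two session halves):
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Equivalently the between-subject variance over the total of the
#' between-subject, rater and residual components. Variance components
#' are returned alongside; negative method-of-moments components are
#' reported as computed (with a flag) unless `truncate = TRUE`.
#'
#' @param table n_subjects x k matrix of edge weights (k = 2 halves).
#' @param truncate logical; truncate negative variance components to 0.
#' @return list of class `icc` with `value`, `sigma_lambda2` (subjects),
#'   `sigma_pi2` (raters/halves), `sigma_eps2` (residual), `ms`
#'   (MSR/MSC/MSE), `negative_components` flag; `value` is `NA` with a
#'   `reason` when total variance is zero.
#' @export
icc_2_1 <- function(table, truncate = FALSE) {
  m <- as.matrix(table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("icc_2_1: need >= 2 subjects and >= 2 columns")
  if (anyNA(m)) stop("icc_2_1: missing entries not supported")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST == 0)
    return(structure(list(value = NA_real_, reason = "zero total variance",
                          sigma_lambda2 = 0, sigma_pi2 = 0, sigma_eps2 = 0,
                          ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                          negative_components = FALSE),
                     class = "icc"))
  s_lam <- (MSR - MSE) / k
  s_pi <- (MSC - MSE) / n
  s_eps <- MSE
  neg <- (s_lam < 0) || (s_pi < 0)
  if (truncate) {
    s_lam <- max(s_lam, 0)
    s_pi <- max(s_pi, 0)
  }
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  structure(list(value = icc, sigma_lambda2 = s_lam, sigma_pi2 = s_pi,
                 sigma_eps2 = s_eps,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 negative_components = neg, reason = NULL),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  if (is.na(x$value))
    cat("<icc> undefined:", x$reason, "\n")
  else
    cat(sprintf("<icc> ICC(2,1) = %.4f (sigma^2: subj %.4g, half %.4g, resid %.4g)\n",
                x$value, x$sigma_lambda2, x$sigma_pi2, x$sigma_eps2))
  invisible(x)
}

#' Edge-wise ICC(2,1) across subjects' split halves
#'
#' Vectorizes each subject's two half connectomes over the upper
#' triangle and computes [icc_2_1()] per edge.
#'
#' @param pairs list (one per subject) of [split_half] results on a
#'   common parcel space.
#' @param truncate passed to [icc_2_1()].
#' @return list with `edge_icc` (per-edge values), `edge_index` (2-column
#'   matrix of parcel pairs), and `parcel_icc`: per-parcel mean of the
#'   ICCs over that parcel's incident edges.
#' @export
icc_edgewise <- function(pairs, truncate = FALSE) {
  stopifnot(length(pairs) >= 2L)
  P <- nrow(pairs[[1]]$first$matrix)
  ut <- which(upper.tri(diag(P)))
  half1 <- vapply(pairs, function(p) p$first$matrix[ut], numeric(length(ut)))
  half2 <- vapply(pairs, function(p) p$second$matrix[ut], numeric(length(ut)))
  vals <- vapply(seq_along(ut), function(e) {
    tab <- cbind(half1[e, ], half2[e, ])
    if (anyNA(tab)) return(NA_real_)
    icc_2_1(tab, truncate = truncate)$value
  }, numeric(1))
  idx <- arrayInd(ut, c(P, P))
  parcel_icc <- vapply(seq_len(P), function(p)
    mean(vals[idx[, 1] == p | idx[, 2] == p], na.rm = TRUE), numeric(1))
  list(edge_icc = vals, edge_index = idx, parcel_icc = parcel_icc)
}

#' Classify an ICC value into the conventional reliability bands
#'
#' Bands: poor (<= 0.4, including negative estimates), fair (0.4, 0.6),
#' good [0.6, 0.75), excellent (>= 0.75). The conventional printed upper
#' edges 0.59 and 0.74 leave gaps that are closed here at 0.6 and 0.75.
#'
#' @param value numeric vector of ICC values.
#' @return character vector of band labels; `NA` in gives `NA` out.
#' @export
classify_icc <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v <= 0.4) "poor"
    else if (v < 0.6) "fair"
    else if (v < 0.75) "good"
    else "excellent"
  }, character(1))
}

#' Task-minus-rest difference map
#'
#' @param task_map,rest_map per-unit maps on the same unit space (both
#'   computed on volume-matched data).
#' @return per-unit `task - rest` difference, same class as the inputs.
#' @export
delta_map <- function(task_map, rest_map) {
  if (length(task_map) != length(rest_map))
    stop("delta_map: unit-space mismatch")
  out <- unclass(task_map) - unclass(rest_map)
  class(out) <- class(task_map)
  out
}

#' Across-subject mean and SD maps
#'
#' @param maps list of per-subject per-unit maps (equal lengths).
#' @return list with `mean` and `sd` per-unit vectors (sample SD).
#' @export
group_summary <- function(maps) {
  stopifnot(length(maps) >= 2L)
  m <- do.call(rbind, lapply(maps, unclass))
  list(mean = colMeans(m, na.rm = TRUE),
       sd = apply(m, 2, stats::sd, na.rm = TRUE))
}
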