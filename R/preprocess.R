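#' Framewise displacement from six motion parameters
#'
#' FD for frame i is the sum of absolute frame-to-frame differences of
#' the three translations (mm) plus the three rotations converted to arc
#' length at a nominal head radius (default 50 mm). FD of the first
#' frame is 0 by convention.
#'
#' @param motion data.frame or matrix with 6 columns: three translations
#'   (mm) then three rotations (radians), one row per frame.
#' @param head_radius radius in mm used to convert rotations to mm.
#' @return numeric vector of per-frame FD (mm).
#' @export
compute_fd <- function(motion, head_radius = 50) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) stop("compute_fd: expected 6 motion parameter columns")
  if (!all(is.finite(m))) stop("compute_fd: non-finite motion values")
  if (nrow(m) == 1L) return(0)
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Censor high-motion frames
#'
#' Marks frames with FD above the threshold as censored in the run's
#' logical mask. The data matrix is untouched; frames are dropped only
#' when a statistic extracts retained frames. Censoring composes with an
#' existing mask (a frame stays censored once censored), which makes the
#' operation idempotent.
#'
#' @param run a [bold_run].
#' @param fd per-frame framewise displacement (mm).
#' @param threshold censoring threshold in mm (field default 0.20).
#' @return the run with an updated censor mask.
#' @export
censor_frames <- function(run, fd, threshold = 0.20) {
  stopifnot(inherits(run, "bold_run"))
  if (length(fd) != nrow(run$data))
    stop("censor_frames: fd length ", length(fd), " != frame count ",
         nrow(run$data))
  run$censor <- run$censor & (fd <= threshold)
  run
}

#' Detrend, band-pass filter and regress confounds from a run
#'
#' Per unit: ordinary least squares removal of an intercept, linear and
#' quadratic time trend plus any confound columns, with the fit computed
#' on retained frames only (censored frames receive the same projection
#' but do not influence it); then an optional zero-phase band-pass
#' (forward-backward order-2 Butterworth) applied on the full frame grid
#' with censored frames linearly interpolated beforehand so motion
#' spikes cannot ring through the filter; finally per-unit mean removal
#' over retained frames.
#'
#' With `gsr = TRUE` the global signal (mean over units of the
#' detrended series) is appended as one extra confound column.
#'
#' @param run a [bold_run].
#' @param confounds optional frames x k numeric matrix of nuisance
#'   regressors. Rank-deficient columns are dropped with a warning.
#' @param band length-2 numeric, band-pass edges in Hz, or `NULL` to
#'   skip filtering. Default `c(0.01, 0.08)`.
#' @param gsr logical, include global signal regression (default TRUE).
#' @return the cleaned [bold_run]; retained-frame means are ~0 per unit.
#' @export
clean_timeseries <- function(run, confounds = NULL, band = c(0.01, 0.08),
                             gsr = TRUE) {
  stopifnot(inherits(run, "bold_run"))
  Y <- run$data
  n <- nrow(Y)
  keep <- run$censor
  if (sum(keep) < 2L) stop("clean_timeseries: fewer than 2 retained frames")
  t0 <- seq_len(n) - (n + 1) / 2       # centered time for conditioning
  X <- cbind(1, t0, t0^2)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      stop("clean_timeseries: confounds must have one row per frame")
    X <- cbind(X, confounds)
  }
  if (gsr) X <- cbind(X, rowMeans(Y))
  # drop linearly dependent columns (on retained frames)
  qrX <- qr(X[keep, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    warning("clean_timeseries: dropping ", length(drop_cols),
            " linearly dependent regressor column(s)")
    X <- X[, -drop_cols, drop = FALSE]
  }
  beta <- qr.coef(qr(X[keep, , drop = FALSE]), Y[keep, , drop = FALSE])
  resid <- Y - X %*% beta

  if (!is.null(band)) {
    fs <- 1 / run$tr
    nyq <- fs / 2
    if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
      stop("clean_timeseries: band must satisfy 0 < lo < hi < Nyquist (",
           signif(nyq, 3), " Hz)")
    # interpolate censored frames so spikes don't ring through the IIR
    if (any(!keep)) {
      idx <- seq_len(n)
      resid <- apply(resid, 2, function(col) {
        col[!keep] <- stats::approx(idx[keep], col[keep], xout = idx[!keep],
                                    rule = 2)$y
        col
      })
    }
    bf <- signal::butter(2, band / nyq, type = "pass")
    resid <- apply(resid, 2, function(col)
      signal::filtfilt(bf, col))
  }
  mu <- colMeans(resid[keep, , drop = FALSE])
  run$data <- sweep(resid, 2, mu)
  run
}

#' Average units into parcels
#'
#' Each parcel's series is the unweighted per-frame mean of its member
#' units.
#'
#' @param run a dense-level [bold_run].
#' @param parc a [parcellation] covering the run's units.
#' @return a parcel-level [bold_run] with `n_parcels` columns.
#' @export
parcellate <- function(run, parc) {
  stopifnot(inherits(run, "bold_run"), inherits(parc, "parcellation"))
  if (ncol(run$data) != length(parc$unit_parcel))
    stop("parcellate: run has ", ncol(run$data), " units but parcellation maps ",
         length(parc$unit_parcel))
  P <- parc$n_parcels
  counts <- tabulate(parc$unit_parcel, P)
  if (any(counts == 0L)) stop("parcellate: empty parcel")
  # frames x P sums via indicator matrix
  M <- matrix(0, length(parc$unit_parcel), P)
  M[cbind(seq_along(parc$unit_parcel), parc$unit_parcel)] <- 1
  out <- run$data %*% M
  out <- sweep(out, 2, counts, "/")
  run$data <- out
  run$unit_level <- "parcel"
  run
}

#' Match data quantity across states by truncation
#'
#' Computes, per subject, the retained-frame total of the reference
#' state (concatenated across sessions), takes the global minimum over
#' subjects as the target length, and truncates every subject x state
#' retained, concatenated series to exactly that many frames, keeping
#' the earliest frames. This removes scan-length differences as a
#' confound when comparing FC or reliability between states.
#'
#' @param runs list of [bold_run]s covering all subjects, sessions and
#'   states.
#' @param reference_state state whose minimum retained total defines the
#'   target (field convention: the shortest task, e.g. `"motor"`).
#' @param floor smallest acceptable target length (default 50 frames).
#' @return list with `target` (frames) and `series`: a nested list
#'   `series[[subject]][[state]]` of truncated retained-frame matrices,
#'   each run mean-centered before concatenation (see
#'   [concat_mean_centered()]).
#' @export
volume_match <- function(runs, reference_state, floor = 50L) {
  stopifnot(length(runs) > 0)
  subjects <- sort(unique(vapply(runs, function(r) r$subject, numeric(1))))
  states <- unique(vapply(runs, function(r) r$state, character(1)))
  if (!reference_state %in% states)
    stop("volume_match: reference state ", reference_state, " absent")
  ref_totals <- vapply(subjects, function(s) {
    sum(vapply(runs, function(r)
      if (r$subject == s && r$state == reference_state) sum(r$censor) else 0L,
      integer(1)))
  }, numeric(1))
  target <- min(ref_totals)
  if (target < floor)
    stop("volume_match: target length ", target, " below floor ", floor)
  series <- lapply(subjects, function(s) {
    per_state <- lapply(states, function(st) {
      sel <- Filter(function(r) r$subject == s && r$state == st, runs)
      if (!length(sel)) return(NULL)
      mat <- concat_mean_centered(sel)
      if (nrow(mat) < target)
        stop(sprintf(
          "volume_match: subject %s state %s has %d retained frames < target %d",
          s, st, nrow(mat), target))
      mat[seq_len(target), , drop = FALSE]
    })
    names(per_state) <- states
    per_state
  })
  names(series) <- paste0("sub", subjects)
  list(target = target, series = series)
}

#' Concatenate runs after per-run mean centering
#'
#' Extracts each run's retained frames, removes each run's per-unit mean,
#' and stacks the runs in (session, run) order.
#'
#' @param runs list of [bold_run]s on the same unit space.
#' @return a frames x units matrix of centered retained frames.
#' @export
concat_mean_centered <- function(runs) {
  stopifnot(length(runs) > 0)
  ncols <- vapply(runs, function(r) ncol(r$data), integer(1))
  if (length(unique(ncols)) != 1L)
    stop("concat_mean_centered: unit-count mismatch across runs")
  ord <- order(vapply(runs, function(r) as.numeric(r$session), numeric(1)),
               vapply(runs, function(r) as.numeric(r$run), numeric(1)))
  pieces <- lapply(runs[ord], function(r) {
    m <- retained_frames(r)
    if (nrow(m) < 2L)
      stop("concat_mean_centered: run with <2 retained frames")
    sweep(m, 2, colMeans(m))
  })
  do.call(rbind, pieces)
}
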