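#' Finite impulse response (FIR) basis specification
#'
#' One FIR basis per condition: `n_bins` free regressors of width
#' `bin_width` seconds, spanning a post-onset window of
#' `n_bins * bin_width` seconds, with no assumption about the
#' hemodynamic response shape.
#'
#' @param conditions character vector of condition labels.
#' @param n_bins integer, bins per condition (recycled).
#' @param bin_width bin width in seconds (recycled).
#' @return object of class `fir_spec`: data.frame with one row per
#'   condition and columns `condition`, `n_bins`, `bin_width`, `window`.
#' @export
fir_spec <- function(conditions, n_bins, bin_width) {
  stopifnot(length(conditions) >= 1L, all(n_bins >= 1L), all(bin_width > 0))
  out <- data.frame(condition = as.character(conditions),
                    n_bins = as.integer(rep_len(n_bins, length(conditions))),
                    bin_width = rep_len(bin_width, length(conditions)),
                    stringsAsFactors = FALSE)
  out$window <- out$n_bins * out$bin_width
  class(out) <- c("fir_spec", "data.frame")
  out
}

#' Standard FIR design table for the three task states
#'
#' The conventional designs for the motor, mixed block/event language,
#' and incidental-encoding memory tasks: motor conditions (left/right
#' hand, left/right foot, tongue) at 7 bins x 2.2 s (15.4 s window);
#' language sustained blocks at 1 bin x 121 s, block cues at 1 bin x
#' 2.2 s, and trial events (coherent, random, noun, verb) at 8 bins x
#' 1.5 s (12 s window); memory stimulus x repetition conditions at
#' 8 bins x 1.5 s.
#'
#' @return named list of [fir_spec] objects (`motor`, `language`,
#'   `memory`).
#' @export
default_fir_table <- function() {
  list(
    motor = fir_spec(
      c("left_hand", "right_hand", "left_foot", "right_foot", "tongue"),
      n_bins = 7L, bin_width = 2.2),
    language = fir_spec(
      c("sustained_verbal", "sustained_spatial", "cue_start", "cue_end",
        "coherent_50", "coherent_0", "noun", "verb"),
      n_bins = c(1L, 1L, 1L, 1L, 8L, 8L, 8L, 8L),
      bin_width = c(121, 121, 2.2, 2.2, 1.5, 1.5, 1.5, 1.5)),
    memory = fir_spec(
      as.vector(outer(c("face", "scene", "word"),
                      c("rep1", "rep2", "rep3"), paste, sep = "_")),
      n_bins = 8L, bin_width = 1.5))
}

#' Build an FIR design matrix on the frame grid
#'
#' Each event of a condition contributes an indicator of 1 to bin `b`
#' over the microtime interval
#' `[onset + b * bin_width, onset + (b+1) * bin_width)`; overlapping
#' events of the same condition sum. The microtime columns are then
#' box-car averaged onto the frame grid (each frame's value is the
#' fraction of that frame covered by the bin, times the indicator
#' height), which handles bins narrower than a frame exactly up to the
#' microtime resolution. Windows running past the end of the run are
#' truncated and counted.
#'
#' @param events data.frame with columns `onset`, `duration`,
#'   `trial_type` (seconds, 0-based from run start).
#' @param spec a [fir_spec] covering every modeled condition.
#' @param n_frames number of frames in the run.
#' @param tr sampling interval, seconds.
#' @param microtime_dt microtime resolution, seconds (default 0.1).
#' @return object of class `fir_design`: list with `design` (frames x
#'   regressors), `condition`/`bin` column labels, `microtime_dt`, and
#'   `n_truncated` (events whose window was clipped at run end).
#' @export
build_fir_design <- function(events, spec, n_frames, tr, microtime_dt = 0.1) {
  stopifnot(inherits(spec, "fir_spec"), n_frames >= 1L, tr > 0)
  if (any(spec$bin_width < microtime_dt))
    stop("build_fir_design: bin_width smaller than microtime_dt")
  unknown <- setdiff(unique(events$trial_type), spec$condition)
  if (length(unknown))
    stop("build_fir_design: unknown condition(s): ",
         paste(unknown, collapse = ", "))
  run_dur <- n_frames * tr
  n_micro <- as.integer(round(run_dur / microtime_dt))
  micro_mid <- (seq_len(n_micro) - 0.5) * microtime_dt
  frame_of <- pmin(as.integer(floor(micro_mid / tr)) + 1L, n_frames)

  cols <- list()
  labels_cond <- character(0)
  labels_bin <- integer(0)
  n_trunc <- 0L
  for (ci in seq_len(nrow(spec))) {
    cond <- spec$condition[ci]
    nb <- spec$n_bins[ci]
    bw <- spec$bin_width[ci]
    ev <- events[events$trial_type == cond, , drop = FALSE]
    for (b in seq_len(nb) - 1L) {
      micro <- numeric(n_micro)
      for (ei in seq_len(nrow(ev))) {
        lo <- ev$onset[ei] + b * bw
        hi <- ev$onset[ei] + (b + 1) * bw
        if (lo >= run_dur) { n_trunc <- n_trunc + 1L; next }
        if (hi > run_dur) { n_trunc <- n_trunc + 1L; hi <- run_dur }
        sel <- micro_mid >= lo & micro_mid < hi
        micro[sel] <- micro[sel] + 1
      }
      # box-car average onto frames
      col <- as.numeric(tapply(micro, frame_of, mean))
      cols[[length(cols) + 1L]] <- col
      labels_cond <- c(labels_cond, cond)
      labels_bin <- c(labels_bin, b + 1L)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste0(labels_cond, ".bin", labels_bin)
  structure(list(design = X, condition = labels_cond, bin = labels_bin,
                 microtime_dt = microtime_dt, n_truncated = n_trunc),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("<fir_design> %d frames x %d regressors (%d conditions)\n",
              nrow(x$design), ncol(x$design), length(unique(x$condition))))
  invisible(x)
}

#' Fit a per-unit ordinary least squares GLM
#'
#' Fits `series ~ design + intercept` per unit by OLS on retained
#' frames (censored frames are row-deleted from the fit and their
#' residuals set to missing). Rank-deficient designs are fit by
#' pseudo-inverse with the aliased columns flagged.
#'
#' @param series frames x units matrix or a [bold_run].
#' @param design a [fir_design] or plain numeric matrix (an intercept
#'   column is always appended internally).
#' @param censor optional logical retained-frame mask; taken from the
#'   `bold_run` if one is supplied.
#' @return object of class `glm_fit`: `betas` (regressors x units, named
#'   rows, intercept last), `residuals` (frames x units, `NA` at
#'   censored frames), `condition`/`bin` labels when the design carries
#'   them, `aliased` flag vector.
#' @export
fit_glm <- function(series, design, censor = NULL) {
  if (inherits(series, "bold_run")) {
    if (is.null(censor)) censor <- series$censor
    series <- series$data
  }
  series <- as.matrix(series)
  n <- nrow(series)
  if (is.null(censor)) censor <- rep(TRUE, n)
  cond <- NULL; bin <- NULL
  if (inherits(design, "fir_design")) {
    cond <- design$condition; bin <- design$bin
    design <- design$design
  }
  design <- as.matrix(design)
  if (nrow(design) != n) stop("fit_glm: design/frame mismatch")
  X <- cbind(design, intercept = 1)
  p <- ncol(X)
  if (sum(censor) < p + 2L)
    stop("fit_glm: fewer retained frames than regressors + 2")
  Xr <- X[censor, , drop = FALSE]
  Yr <- series[censor, , drop = FALSE]
  qrX <- qr(Xr)
  aliased <- rep(FALSE, p)
  if (qrX$rank < p) {
    aliased[qrX$pivot[-seq_len(qrX$rank)]] <- TRUE
    sv <- svd(Xr)
    keep <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% Yr) / sv$d[keep])
  } else {
    beta <- qr.coef(qrX, Yr)
  }
  rownames(beta) <- colnames(X)
  resid <- series - X %*% beta
  resid[!censor, ] <- NA_real_
  structure(list(betas = beta, residuals = resid, condition = cond,
                 bin = bin, aliased = aliased, censor = censor),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors (+intercept) x %d units%s\n",
              nrow(x$betas) - 1L, ncol(x$betas),
              if (any(x$aliased)) sprintf(", %d aliased", sum(x$aliased)) else ""))
  invisible(x)
}

#' Averaged-bin contrast (parameter estimate, PE)
#'
#' The PE for a condition is the mean of that condition's FIR bin betas
#' — each bin weighted 1/n_bins (e.g., 1/8 = 0.125 for an 8-bin
#' condition).
#'
#' @param fit a [fit_glm] result on an FIR design.
#' @param condition condition label present in the design.
#' @return per-unit numeric vector of PEs.
#' @export
average_contrast <- function(fit, condition) {
  if (is.null(fit$condition)) stop("average_contrast: fit has no FIR labels")
  rows <- which(fit$condition == condition)
  if (!length(rows)) stop("average_contrast: condition ", condition,
                          " not in design")
  w <- rep(1 / length(rows), length(rows))
  as.numeric(w %*% fit$betas[rows, , drop = FALSE])
}

#' Residualize time courses against a task design
#'
#' Convenience wrapper over [fit_glm()] returning the residual series
#' (the input with the modeled task-evoked response removed), ready for
#' concatenation and task-residualized connectomes.
#'
#' @inheritParams fit_glm
#' @return for a [bold_run] input, the run with residual data (censored
#'   frames zeroed in the matrix but still censored in the mask);
#'   otherwise the residual matrix.
#' @export
residualize <- function(series, design, censor = NULL) {
  is_run <- inherits(series, "bold_run")
  fit <- fit_glm(series, design, censor)
  res <- fit$residuals
  if (is_run) {
    res[!fit$censor, ] <- 0   # frames stay censored; value is never used
    series$data <- res
    series
  } else res
}

#' Aggregate parameter estimates across the analysis hierarchy
#'
#' Fixed-effects averaging of run-level PEs: runs are averaged within
#' subject x session x condition, sessions within subject x condition,
#' conditions within subject (one task-level PE map per subject), and
#' subjects into the group map. Missing runs are averaged over what is
#' available.
#'
#' @param records list of records, each
#'   `list(subject=, session=, condition=, pe = per-unit vector)`.
#' @return list with `subject_condition` (named list of per-unit
#'   vectors, `sub<j>.<condition>`), `subject` (task-level per-subject
#'   maps) and `group` (single per-unit vector).
#' @export
aggregate_pes <- function(records) {
  stopifnot(length(records) > 0)
  key3 <- vapply(records, function(r)
    paste(r$subject, r$session, r$condition, sep = "."), character(1))
  ses_maps <- lapply(split(records, key3), function(g)
    Reduce(`+`, lapply(g, `[[`, "pe")) / length(g))
  ses_meta <- do.call(rbind, lapply(strsplit(names(ses_maps), ".", fixed = TRUE),
                                    function(p) data.frame(subject = p[1],
                                                           condition = p[3])))
  key2 <- paste(ses_meta$subject, ses_meta$condition, sep = ".")
  subcond <- lapply(split(seq_along(ses_maps), key2), function(ix)
    Reduce(`+`, ses_maps[ix]) / length(ix))
  sub_key <- vapply(strsplit(names(subcond), ".", fixed = TRUE), `[[`, "",
                    1L)
  subject <- lapply(split(seq_along(subcond), sub_key), function(ix)
    Reduce(`+`, subcond[ix]) / length(ix))
  group <- Reduce(`+`, subject) / length(subject)
  list(subject_condition = subcond,
       subject = subject,
       group = group)
}
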