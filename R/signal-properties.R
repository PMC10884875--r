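#' Temporal signal properties: tMean, tSD, tSNR
#'
#' Per-unit temporal statistics of the BOLD signal, computed per run
#' over retained frames and then averaged run -> session -> subject
#' (unweighted means at each level; a frame-weighted alternative is
#' available). tSNR is the per-run ratio mean/SD averaged across runs —
#' not the ratio of the averaged mean to the averaged SD — following the
#' convention of averaging the per-scan ratio across sessions.
#'
#' `signal_property_map()` is the common engine; `tmean_map()`,
#' `tsd_map()` and `tsnr_map()` are the user-facing wrappers.
#'
#' @param runs list of [bold_run]s for one or more subjects (censored
#'   and, if comparing states, volume matched).
#' @param measure one of `"tmean"`, `"tsd"`, `"tsnr"`.
#' @param level `"subject"` (one map per subject) or `"group"` (mean
#'   over subjects).
#' @param weight_by_frames logical; weight run averages by retained
#'   frame counts instead of the default unweighted mean.
#' @return for `level = "subject"` a list of per-unit vectors named by
#'   subject; for `"group"` a single per-unit vector. Units with a
#'   zero-SD run yield `NA` tSNR for that subject (logged via attribute
#'   `n_undefined`).
#' @export
signal_property_map <- function(runs, measure = c("tmean", "tsd", "tsnr"),
                                level = c("subject", "group"),
                                weight_by_frames = FALSE) {
  measure <- match.arg(measure)
  level <- match.arg(level)
  stopifnot(length(runs) > 0)
  subjects <- unique(vapply(runs, function(r) r$subject, numeric(1)))
  n_undef <- 0L
  per_subject <- lapply(subjects, function(s) {
    sel <- Filter(function(r) r$subject == s, runs)
    vals <- lapply(sel, function(r) {
      m <- retained_frames(r)
      if (nrow(m) < 2L) stop("signal_property_map: run with <2 retained frames")
      mu <- colMeans(m)
      sdv <- apply(m, 2, stats::sd)
      switch(measure,
             tmean = mu,
             tsd = sdv,
             tsnr = {
               out <- mu / sdv
               out[sdv == 0] <- NA_real_
               out
             })
    })
    w <- if (weight_by_frames)
      vapply(sel, function(r) sum(r$censor), numeric(1))
    else rep(1, length(sel))
    vm <- do.call(rbind, vals)
    n_undef <<- n_undef + sum(is.na(vm))
    out <- colSums(vm * (w / sum(w)))
    out
  })
  names(per_subject) <- paste0("sub", subjects)
  res <- if (level == "group") {
    Reduce(`+`, lapply(per_subject, function(v) ifelse(is.na(v), 0, v))) /
      Reduce(`+`, lapply(per_subject, function(v) as.numeric(!is.na(v))))
  } else per_subject
  attr(res, "n_undefined") <- n_undef
  attr(res, "measure") <- measure
  res
}

#' @rdname signal_property_map
#' @export
tmean_map <- function(runs, level = "subject", weight_by_frames = FALSE)
  signal_property_map(runs, "tmean", level, weight_by_frames)

#' @rdname signal_property_map
#' @export
tsd_map <- function(runs, level = "subject", weight_by_frames = FALSE)
  signal_property_map(runs, "tsd", level, weight_by_frames)

#' @rdname signal_property_map
#' @export
tsnr_map <- function(runs, level = "subject", weight_by_frames = FALSE)
  signal_property_map(runs, "tsnr", level, weight_by_frames)

#' Task-minus-rest difference of a signal property
#'
#' @param task,rest per-unit maps of the same measure on the same unit
#'   space, computed on volume-matched inputs.
#' @return per-unit `task - rest`.
#' @export
delta_signal <- function(task, rest) {
  mt <- attr(task, "measure"); mr <- attr(rest, "measure")
  if (!is.null(mt) && !is.null(mr) && !identical(mt, mr))
    stop("delta_signal: measure mismatch (", mt, " vs ", mr, ")")
  if (length(task) != length(rest)) stop("delta_signal: unit-space mismatch")
  out <- as.numeric(task) - as.numeric(rest)
  attr(out, "measure") <- mt
  out
}
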