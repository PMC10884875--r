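#' BOLD run container
#'
#' A `bold_run` holds one scan run's frames-by-units signal matrix together
#' with its sampling interval, identifying labels and a per-frame censor
#' mask. The mask is logical with `TRUE` marking retained (low-motion)
#' frames; masking is purely logical until frames are extracted for a
#' statistic, so the data matrix always keeps the full frame grid.
#'
#' @param data numeric matrix, frames x units (arbitrary units).
#' @param tr sampling interval in seconds (the repetition time).
#' @param subject,session,run,state identifying labels. `state` is `"rest"`
#'   or a task name such as `"motor"`.
#' @param censor logical vector, one per frame; `TRUE` = retained. Defaults
#'   to all retained.
#' @param unit_level `"parcel"` or `"dense"`.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, tr, subject = 1L, session = 1L, run = 1L,
                     state = "rest", censor = NULL,
                     unit_level = c("parcel", "dense")) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("bold_run: non-finite values in data")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("bold_run: tr must be a positive scalar (seconds)")
  if (is.null(censor)) censor <- rep(TRUE, nrow(data))
  censor <- as.logical(censor)
  if (length(censor) != nrow(data))
    stop("bold_run: censor mask length ", length(censor),
         " != frame count ", nrow(data))
  structure(
    list(data = data, tr = tr, subject = subject, session = session,
         run = run, state = state, censor = censor,
         unit_level = match.arg(unit_level)),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf(
    "<bold_run> sub %s ses %s run %s state %s: %d frames x %d units, TR %.3g s, %d retained\n",
    x$subject, x$session, x$run, x$state,
    nrow(x$data), ncol(x$data), x$tr, sum(x$censor)))
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

#' Retained frames of a run
#'
#' @param run a [bold_run].
#' @return the data matrix restricted to retained (uncensored) frames.
#' @export
retained_frames <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  run$data[run$censor, , drop = FALSE]
}

#' Parcellation mapping
#'
#' Maps measurement units (vertices or already-parcellated columns) to
#' parcels and parcels to named functional networks. Parcel labels must be
#' contiguous 1..P.
#'
#' @param unit_parcel integer vector, one entry per unit, parcel id in 1..P.
#' @param parcel_network integer or character vector of length P giving each
#'   parcel's network; optional names.
#' @param network_names optional character vector naming network ids.
#' @return an object of class `parcellation`.
#' @export
parcellation <- function(unit_parcel, parcel_network = NULL,
                         network_names = NULL) {
  unit_parcel <- as.integer(unit_parcel)
  P <- max(unit_parcel)
  if (!setequal(unique(unit_parcel), seq_len(P)))
    stop("parcellation: parcel labels must be contiguous 1..P with no empty parcel")
  if (!is.null(parcel_network) && length(parcel_network) != P)
    stop("parcellation: parcel_network must have one entry per parcel")
  structure(list(unit_parcel = unit_parcel,
                 parcel_network = parcel_network,
                 network_names = network_names,
                 n_parcels = P),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d units -> %d parcels", length(x$unit_parcel),
              x$n_parcels))
  if (!is.null(x$parcel_network))
    cat(sprintf(" -> %d networks", length(unique(x$parcel_network))))
  cat("\n")
  invisible(x)
}
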