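#' Parcel-wise linear regression between two maps
#'
#' OLS of `y` on `x` across parcels, optionally excluding parcels whose
#' consensus network is in an exclusion set (the conventional exclusion
#' is the low-reliability limbic networks). Reports the slope,
#' intercept, R-squared, two-sided p for the slope, and the
#' standardized beta (which for simple regression equals the Pearson
#' correlation, so beta_std^2 = R^2).
#'
#' @param x,y per-parcel numeric maps of equal length.
#' @param assignment optional integer/character vector of network labels
#'   per parcel (e.g., a consensus partition), required when `exclude`
#'   is given.
#' @param exclude networks to drop before fitting.
#' @param p_adjust optional method for [stats::p.adjust] applied by the
#'   caller across multiple calls; stored for bookkeeping only (the
#'   conventional report is uncorrected p).
#' @return object of class `ols_summary`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `beta_std`, `n`, `excluded_networks`.
#' @export
parcelwise_ols <- function(x, y, assignment = NULL, exclude = NULL,
                           p_adjust = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(exclude)) {
    if (is.null(assignment)) stop("parcelwise_ols: exclusion needs an assignment")
    stopifnot(length(assignment) == length(x))
    keep <- keep & !(assignment %in% exclude)
  }
  xs <- x[keep]; ys <- y[keep]
  n <- length(xs)
  if (n < 3L) stop("parcelwise_ols: fewer than 3 included parcels")
  if (stats::sd(xs) == 0) stop("parcelwise_ols: predictor is constant")
  fit <- stats::lm(ys ~ xs)
  sm <- suppressWarnings(summary(fit))   # exact fits trip a precision warning
  slope <- unname(stats::coef(fit)[2])
  beta_std <- slope * stats::sd(xs) / stats::sd(ys)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 beta_std = beta_std, n = n,
                 excluded_networks = exclude),
            class = "ols_summary")
}

#' @export
print.ols_summary <- function(x, ...) {
  cat(sprintf("<ols_summary> beta = %.4g, R^2 = %.3f, p = %.3g (n = %d%s)\n",
              x$slope, x$r_squared, x$p_value, x$n,
              if (length(x$excluded_networks))
                paste0(", excluding ",
                       paste(x$excluded_networks, collapse = ",")) else ""))
  invisible(x)
}

#' Network-wise standardized betas
#'
#' One within-network simple regression of `y` on `x` per network,
#' returning each network's standardized beta. Networks in `exclude`
#' or with fewer than `min_parcels` members are skipped (skips are
#' reported).
#'
#' @inheritParams parcelwise_ols
#' @param min_parcels smallest network size fitted (default 3).
#' @return data.frame with columns `network`, `beta_std`, `r_squared`,
#'   `p_value`, `n`; attribute `skipped` lists skipped networks. Rows
#'   follow the sorted unique network labels.
#' @export
networkwise_betas <- function(x, y, assignment, exclude = NULL,
                              min_parcels = 3L) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(assignment) == length(x))
  nets <- sort(unique(assignment))
  nets <- nets[!(nets %in% exclude)]
  rows <- list(); skipped <- character(0)
  for (nw in nets) {
    sel <- assignment == nw & is.finite(x) & is.finite(y)
    if (sum(sel) < min_parcels || stats::sd(x[sel]) == 0) {
      skipped <- c(skipped, as.character(nw))
      next
    }
    fit <- parcelwise_ols(x[sel], y[sel])
    rows[[length(rows) + 1L]] <- data.frame(
      network = nw, beta_std = fit$beta_std, r_squared = fit$r_squared,
      p_value = fit$p_value, n = fit$n)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(network = character(0), beta_std = numeric(0),
               r_squared = numeric(0), p_value = numeric(0), n = integer(0))
  attr(out, "skipped") <- skipped
  out
}

#' Monotone-trend diagnostic
#'
#' Spearman rank correlation between two maps, for relationships judged
#' nonlinear where a linear fit would be inappropriate (e.g., tSNR
#' versus reliability over all networks).
#'
#' @param x,y per-parcel maps.
#' @return list with `rho` and `p_value` (two-sided).
#' @export
monotone_trend <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  ct <- suppressWarnings(
    stats::cor.test(x[ok], y[ok], method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-parcel mixed model attributing reliability to signal properties
#'
#' For each parcel, fits the random-intercept linear mixed model
#' `reliability ~ tmean + tsd + pe + (1 | subject)` by REML over the
#' subject x state observations, with all predictors standardized to
#' mean 0, SD 1 across the whole fitting table and PE fixed at 0 for
#' rest observations (standardization is applied after that zeroing,
#' globally, not per subject). Singular fits are flagged per parcel,
#' not fatal.
#'
#' @param table long-format data.frame with columns `parcel`, `subject`,
#'   `state`, `reliability`, `tmean`, `tsd`, `pe` (PE may be `NA` or 0
#'   for rest; it is forced to 0 before standardization).
#' @return object of class `mixed_model_maps`: data.frame `betas` with
#'   one row per parcel and columns `parcel`, `beta_tmean`, `beta_tsd`,
#'   `beta_pe`, `intercept`, `re_sd` (random-intercept SD), `singular`;
#'   plus `n_obs` per parcel.
#' @export
fit_mixed_model <- function(table) {
  req <- c("parcel", "subject", "state", "reliability", "tmean", "tsd", "pe")
  if (!all(req %in% names(table)))
    stop("fit_mixed_model: table must have columns ",
         paste(req, collapse = ", "))
  tab <- table
  tab$pe[tab$state == "rest" | is.na(tab$pe)] <- 0
  if (length(unique(tab$subject)) < 2L || length(unique(tab$state)) < 2L)
    stop("fit_mixed_model: need >= 2 subjects and >= 2 states")
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(v * 0)
    (v - mean(v)) / s
  }
  tab$tmean <- zscore(tab$tmean)
  tab$tsd <- zscore(tab$tsd)
  tab$pe <- zscore(tab$pe)
  parcels <- sort(unique(tab$parcel))
  rows <- lapply(parcels, function(p) {
    d <- tab[tab$parcel == p, , drop = FALSE]
    fit <- tryCatch(suppressMessages(suppressWarnings(
      lme4::lmer(reliability ~ tmean + tsd + pe + (1 | subject),
                 data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(parcel = p, beta_tmean = NA_real_,
                        beta_tsd = NA_real_, beta_pe = NA_real_,
                        intercept = NA_real_, re_sd = NA_real_,
                        singular = TRUE, n_obs = nrow(d)))
    fe <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    data.frame(parcel = p,
               beta_tmean = unname(fe["tmean"]),
               beta_tsd = unname(fe["tsd"]),
               beta_pe = unname(fe["pe"]),
               intercept = unname(fe["(Intercept)"]),
               re_sd = vc$sdcor[vc$grp == "subject"],
               singular = lme4::isSingular(fit),
               n_obs = nrow(d))
  })
  betas <- do.call(rbind, rows)
  structure(list(betas = betas, standardized = TRUE), class = "mixed_model_maps")
}

#' @export
print.mixed_model_maps <- function(x, ...) {
  b <- x$betas
  cat(sprintf(
    "<mixed_model_maps> %d parcels; mean beta: tMean %.3f, tSD %.3f, PE %.3f (%d singular)\n",
    nrow(b), mean(b$beta_tmean), mean(b$beta_tsd), mean(b$beta_pe),
    sum(b$singular)))
  invisible(x)
}
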