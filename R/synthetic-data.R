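#' Specification for a synthetic multi-session BOLD study
#'
#' Describes a densely sampled fMRI study: several subjects scanned over
#' many sessions in a rest state plus task states, on a parcellated
#' cortex with a planted functional-network structure. Defaults emulate
#' the layout of a densely sampled precision-fMRI study: 9 subjects,
#' 10 sessions, a 2.2 s sampling interval, one rest run plus two motor,
#' two language and three memory runs per session.
#'
#' Network structure is planted as a block correlation matrix:
#' `within_network_r` on edges inside a network, `between_network_r`
#' elsewhere, unit diagonal. Each subject receives a stable perturbation
#' of that matrix (SD `subject_edge_sd` per edge), which is what makes
#' edge weights identifiable across subjects and hence gives ICC a
#' recoverable target.
#'
#' Per-parcel temporal mean and SD profiles default to deterministic
#' ramps spanning a plausible BOLD intensity range (means 600-1000 a.u.,
#' SDs 5-30 a.u.); they are free parameters, not estimates from any real
#' dataset.
#'
#' @param n_subjects,n_sessions,n_parcels,n_networks study dimensions.
#' @param frames_per_run named integer vector, frames per run for each
#'   state. Defaults approximate a 30-min rest run and 4-7-min task runs
#'   at TR 2.2 s.
#' @param tr sampling interval, seconds.
#' @param within_network_r,between_network_r target correlations inside /
#'   outside network blocks; must yield a positive-definite matrix.
#' @param subject_edge_sd SD of subject-specific edge perturbations.
#' @param parcel_mean_profile,parcel_sd_profile per-parcel baseline mean
#'   and temporal SD (a.u.); length `n_parcels`.
#' @param task_designs named list (one per task state) with elements
#'   `events` (data.frame onset/duration/trial_type, seconds), `n_bins`,
#'   `bin_width` (s) and `amplitude` (scalar or per-bin vector, a.u.).
#'   `NULL` builds simple block designs via [default_task_designs()].
#' @param engaged_parcels named list: task state -> integer parcel subset
#'   receiving the evoked response. Default assigns network 1 to motor,
#'   2 to language, 3 to memory.
#' @param runs_per_state named integer vector of runs per session.
#' @param motion_spike_prob per-frame probability of a motion spike.
#' @param ar1 lag-1 autocorrelation applied to the noise (0 = white).
#' @param seed integer master seed; all run-level seeds derive from it.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 9L, n_sessions = 10L,
                       n_parcels = 170L, n_networks = 17L,
                       frames_per_run = NULL, tr = 2.2,
                       within_network_r = 0.35, between_network_r = 0.05,
                       subject_edge_sd = 0.06,
                       parcel_mean_profile = NULL, parcel_sd_profile = NULL,
                       task_designs = NULL, engaged_parcels = NULL,
                       runs_per_state = c(rest = 1L, motor = 2L,
                                          language = 2L, memory = 3L),
                       motion_spike_prob = 0.05, ar1 = 0.4, seed = 1L) {
  if (is.null(frames_per_run))
    frames_per_run <- c(rest = 818L, motor = 106L, language = 194L,
                        memory = 119L)
  states <- names(runs_per_state)
  if (is.null(states) || anyNA(states))
    stop("runs_per_state must be a named vector")
  if (!all(states %in% names(frames_per_run)))
    stop("frames_per_run must cover every state in runs_per_state")
  if (n_parcels < n_networks)
    stop("need at least one parcel per network")
  if (within_network_r < between_network_r)
    stop("within_network_r must be >= between_network_r")
  if (abs(within_network_r) > 1 || abs(between_network_r) > 1)
    stop("target correlations must lie in [-1, 1]")
  if (is.null(parcel_mean_profile))
    parcel_mean_profile <- seq(600, 1000, length.out = n_parcels)
  if (is.null(parcel_sd_profile))
    parcel_sd_profile <- seq(5, 30, length.out = n_parcels)
  stopifnot(length(parcel_mean_profile) == n_parcels,
            length(parcel_sd_profile) == n_parcels,
            all(parcel_sd_profile > 0))
  partition <- planted_partition(n_parcels, n_networks)
  task_states <- setdiff(states, "rest")
  if (is.null(engaged_parcels)) {
    engaged_parcels <- lapply(seq_along(task_states), function(i)
      which(partition == ((i - 1L) %% n_networks + 1L)))
    names(engaged_parcels) <- task_states
  }
  for (st in names(engaged_parcels))
    if (!all(engaged_parcels[[st]] %in% seq_len(n_parcels)))
      stop("engaged_parcels for ", st, " outside 1..n_parcels")
  spec <- structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         n_parcels = as.integer(n_parcels),
         n_networks = as.integer(n_networks),
         frames_per_run = frames_per_run, tr = tr,
         within_network_r = within_network_r,
         between_network_r = between_network_r,
         subject_edge_sd = subject_edge_sd,
         parcel_mean_profile = parcel_mean_profile,
         parcel_sd_profile = parcel_sd_profile,
         task_designs = task_designs,
         engaged_parcels = engaged_parcels,
         runs_per_state = runs_per_state,
         motion_spike_prob = motion_spike_prob,
         ar1 = ar1, seed = as.integer(seed)),
    class = "synth_spec")
  if (is.null(spec$task_designs))
    spec$task_designs <- default_task_designs(spec)
  missing_designs <- setdiff(task_states, names(spec$task_designs))
  if (length(missing_designs))
    stop("no task design for state(s): ",
         paste(missing_designs, collapse = ", "))
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %d subjects x %d sessions, %d parcels / %d networks, TR %.3g s, seed %d\n",
    x$n_subjects, x$n_sessions, x$n_parcels, x$n_networks, x$tr, x$seed))
  cat("  states:", paste(sprintf("%s x%d (%d frames)",
                                 names(x$runs_per_state), x$runs_per_state,
                                 x$frames_per_run[names(x$runs_per_state)]),
                         collapse = ", "), "\n")
  invisible(x)
}

# Contiguous near-equal-size network blocks over 1..P.
planted_partition <- function(n_parcels, n_networks) {
  sort(rep_len(seq_len(n_networks), n_parcels))
}

#' Default block task designs for the synthetic generator
#'
#' Builds one simple blocked event schedule per task state, with FIR bin
#' geometry matching the field-standard designs: motor conditions at
#' 7 bins x 2.2 s, language and memory events at 8 bins x 1.5 s. Events
#' are spaced so every FIR window fits inside the run.
#'
#' @param spec a [synth_spec] (frames_per_run and tr are read from it).
#' @return named list of designs, one per task state.
#' @export
default_task_designs <- function(spec) {
  designs <- list()
  fir <- list(motor = list(n_bins = 7L, bin_width = 2.2),
              language = list(n_bins = 8L, bin_width = 1.5),
              memory = list(n_bins = 8L, bin_width = 1.5))
  for (st in setdiff(names(spec$runs_per_state), "rest")) {
    fs <- if (st %in% names(fir)) fir[[st]] else
      list(n_bins = 8L, bin_width = 1.5)
    run_dur <- spec$frames_per_run[[st]] * spec$tr
    window <- fs$n_bins * fs$bin_width
    # block onsets every 2 windows, leaving one full window of slack at end
    onsets <- seq(window, run_dur - 2 * window, by = 2 * window)
    if (!length(onsets))
      stop("run too short for the FIR window in state ", st)
    events <- data.frame(onset = onsets,
                         duration = rep(fs$bin_width, length(onsets)),
                         trial_type = st,
                         stringsAsFactors = FALSE)
    designs[[st]] <- list(events = events, n_bins = fs$n_bins,
                          bin_width = fs$bin_width, amplitude = 10)
  }
  designs
}

#' Build the planted ground truth for a synthetic study
#'
#' Constructs the block target correlation matrix (within-network value
#' inside blocks, between-network value elsewhere, unit diagonal), the
#' parcel-to-network partition, and one stable perturbed correlation
#' matrix per subject: base plus a symmetric Gaussian edge perturbation
#' of SD `subject_edge_sd`, projected back to the nearest
#' positive-definite correlation matrix by eigenvalue clipping (floor
#' 1e-6) and rescaling to unit diagonal.
#'
#' @param spec a [synth_spec].
#' @return object of class `ground_truth` with elements `base_covariance`,
#'   `subject_covariances` (list), `partition`, `sigma_lambda2`
#'   (nominal between-subject edge variance, `subject_edge_sd^2`) and
#'   `sigma_eps2` (residual edge variance used by the edge-level ICC
#'   generator; see [simulate_icc_edges()]).
#' @export
build_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  P <- spec$n_parcels
  part <- planted_partition(P, spec$n_networks)
  same <- outer(part, part, "==")
  base <- ifelse(same, spec$within_network_r, spec$between_network_r)
  diag(base) <- 1
  ev <- eigen(base, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf(
      "target block matrix not positive definite (min eigenvalue %.3g); raise between_network_r",
      min(ev)))
  rng <- local_rng(spec$seed)
  subject_cov <- lapply(seq_len(spec$n_subjects), function(s) {
    if (spec$subject_edge_sd == 0) return(base)
    noise <- matrix(rng$rnorm(P * P, sd = spec$subject_edge_sd), P, P)
    noise <- (noise + t(noise)) / sqrt(2)   # symmetric, edge SD preserved
    diag(noise) <- 0
    nearest_correlation(base + noise)
  })
  structure(list(base_covariance = base,
                 subject_covariances = subject_cov,
                 partition = part,
                 sigma_lambda2 = spec$subject_edge_sd^2,
                 sigma_eps2 = 0.01),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d parcels, %d networks, %d subjects\n",
              nrow(x$base_covariance), length(unique(x$partition)),
              length(x$subject_covariances)))
  invisible(x)
}

# Project a symmetric matrix to the nearest positive-definite correlation
# matrix: clip eigenvalues at 1e-6, rebuild, rescale to unit diagonal.
nearest_correlation <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / tcrossprod(d)
  diag(m2) <- 1
  (m2 + t(m2)) / 2
}

# Deterministic per-run seed below 2^31, derived from the master seed.
run_seed <- function(seed, subject, session, state, run) {
  si <- sum(utf8ToInt(state))
  as.integer((as.double(seed) * 1000003 + subject * 97561 +
                session * 7919 + si * 331 + run * 17) %% 2147483629)
}

# Small closure-based RNG so generator calls do not disturb the caller's
# global RNG stream ordering guarantees beyond set.seed discipline.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
       runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max))
}

#' Simulate one BOLD run with motion and (for tasks) evoked responses
#'
#' The signal model is
#' `Y = mean_profile + diag(sd_profile) . (L z) + evoked`,
#' where `L` is a Cholesky factor of the subject's planted correlation
#' matrix, `z` is unit-variance noise with optional AR(1) temporal
#' autocorrelation, and the evoked term is the FIR design of the task's
#' event schedule times its per-bin amplitudes, added only in the task's
#' engaged parcels. The motion trace carries a baseline framewise
#' displacement ~ |N(0.05, 0.02)| mm with spikes of magnitude
#' U(0.25, 1.0) mm at the configured probability; the six motion
#' parameters are constructed so that recomputing FD from them
#' reproduces the trace.
#'
#' @param gt a [build_ground_truth()] result.
#' @param subject,session,run indices (1-based).
#' @param state `"rest"` or a task state configured in `spec`.
#' @param spec the [synth_spec].
#' @param seed optional override for the run seed (defaults to a
#'   deterministic function of `spec$seed` and the indices).
#' @return list with elements `run` ([bold_run]), `events` (data.frame,
#'   empty for rest) and `motion` (data.frame with trans/rot columns and
#'   `fd`).
#' @export
simulate_run <- function(gt, subject, session, state, spec, run = 1L,
                         seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), inherits(spec, "synth_spec"))
  if (!state %in% names(spec$runs_per_state))
    stop("unknown state: ", state)
  if (subject < 1 || subject > length(gt$subject_covariances))
    stop("subject index out of range")
  n_frames <- spec$frames_per_run[[state]]
  P <- spec$n_parcels
  if (is.null(seed)) seed <- run_seed(spec$seed, subject, session, state, run)
  rng <- local_rng(seed)

  z <- matrix(rng$rnorm(n_frames * P), n_frames, P)
  if (spec$ar1 != 0) {
    a <- spec$ar1
    z <- apply(z, 2, function(col) {
      out <- numeric(length(col))
      out[1] <- col[1]
      for (t in 2:length(col)) out[t] <- a * out[t - 1] + sqrt(1 - a^2) * col[t]
      out
    })
  }
  L <- chol(gt$subject_covariances[[subject]])
  noise <- z %*% L   # frames x P with target correlation
  Y <- sweep(noise, 2, spec$parcel_sd_profile, "*")
  Y <- sweep(Y, 2, spec$parcel_mean_profile, "+")

  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       trial_type = character(0), stringsAsFactors = FALSE)
  if (state != "rest") {
    des <- spec$task_designs[[state]]
    window <- des$n_bins * des$bin_width
    if (n_frames * spec$tr < window)
      stop("run shorter than the FIR window for state ", state)
    events <- des$events
    fir <- build_fir_design(events,
                            fir_spec(conditions = unique(events$trial_type),
                                     n_bins = des$n_bins,
                                     bin_width = des$bin_width),
                            n_frames = n_frames, tr = spec$tr)
    amp <- des$amplitude
    if (length(amp) == 1L) amp <- rep(amp, ncol(fir$design))
    if (length(amp) != ncol(fir$design))
      stop("amplitude must be scalar or one per FIR column")
    evoked_course <- as.vector(fir$design %*% amp)
    engaged <- spec$engaged_parcels[[state]]
    Y[, engaged] <- Y[, engaged] + evoked_course
  }

  fd <- abs(rng$rnorm(n_frames, 0.05, 0.02))
  spikes <- rng$runif(n_frames) < spec$motion_spike_prob
  fd[spikes] <- fd[spikes] + rng$runif(sum(spikes), 0.25, 1.0)
  fd[1] <- 0
  # encode fd as x-translation steps so compute_fd() round-trips exactly
  trans_x <- cumsum(c(0, fd[-1]))
  motion <- data.frame(trans_x = trans_x, trans_y = 0, trans_z = 0,
                       rot_x = 0, rot_y = 0, rot_z = 0, fd = fd)

  run_obj <- bold_run(Y, tr = spec$tr, subject = subject, session = session,
                      run = run, state = state,
                      censor = fd <= 0.20, unit_level = "parcel")
  list(run = run_obj, events = events, motion = motion)
}

#' Simulate and write a full synthetic dataset to disk
#'
#' Writes one signal matrix, one events table and one motion table per
#' (subject, session, state, run) as tab-separated text, plus a JSON
#' manifest echoing the spec, the per-run seeds and the ground-truth
#' files (base correlation matrix, partition, variance components).
#'
#' @param spec a [synth_spec].
#' @param dir output directory (created if needed).
#' @param overwrite logical; refuse to clobber an existing manifest
#'   unless `TRUE`.
#' @return the manifest, invisibly.
#' @export
simulate_dataset <- function(spec, dir, overwrite = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- build_ground_truth(spec)
  write_matrix_tsv(gt$base_covariance, file.path(dir, "ground_truth_base_correlation.tsv"))
  utils::write.table(
    data.frame(parcel = seq_along(gt$partition), network = gt$partition),
    file.path(dir, "ground_truth_partition.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)

  runs <- list()
  for (s in seq_len(spec$n_subjects)) for (d in seq_len(spec$n_sessions))
    for (st in names(spec$runs_per_state))
      for (r in seq_len(spec$runs_per_state[[st]])) {
        sim <- simulate_run(gt, s, d, st, spec, run = r)
        stem <- sprintf("sub-%02d_ses-%02d_task-%s_run-%02d", s, d, st, r)
        bold_path <- file.path(dir, paste0(stem, "_bold.tsv"))
        write_matrix_tsv(sim$run$data, bold_path)
        write_sidecar(sim$run, paste0(bold_path, ".json"))
        utils::write.table(sim$events, file.path(dir, paste0(stem, "_events.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        utils::write.table(sim$motion, file.path(dir, paste0(stem, "_motion.tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        runs[[length(runs) + 1L]] <- list(
          subject = s, session = d, state = st, run = r,
          seed = run_seed(spec$seed, s, d, st, r),
          bold = basename(bold_path))
      }
  manifest <- list(
    spec = unclass(spec)[c("n_subjects", "n_sessions", "n_parcels",
                           "n_networks", "tr", "within_network_r",
                           "between_network_r", "subject_edge_sd",
                           "motion_spike_prob", "ar1", "seed")],
    frames_per_run = as.list(spec$frames_per_run),
    runs_per_state = as.list(spec$runs_per_state),
    variance_components = list(sigma_lambda2 = gt$sigma_lambda2,
                               sigma_eps2 = gt$sigma_eps2),
    ground_truth = list(base_correlation = "ground_truth_base_correlation.tsv",
                        partition = "ground_truth_partition.tsv"),
    runs = runs)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate edge weights with a known reliability ratio
#'
#' Direct edge-level generator for validating ICC(2,1): each subject has
#' a latent true edge weight with between-subject variance
#' `sigma_lambda2`; each observed half adds independent residual noise
#' with variance `sigma_eps2`. The population ICC(2,1) (no half/rater
#' effect) is `sigma_lambda2 / (sigma_lambda2 + sigma_eps2)`.
#'
#' @param n_subjects number of subjects (rows).
#' @param rho target between/total variance ratio in (0, 1).
#' @param n_edges number of independent edges to simulate.
#' @param sigma_total total edge-weight variance (split between the
#'   subject and residual components according to `rho`).
#' @param mean grand mean edge weight.
#' @param seed integer seed.
#' @return a 3-d array, `n_subjects` x 2 halves x `n_edges`.
#' @export
simulate_icc_edges <- function(n_subjects, rho, n_edges = 200L,
                               sigma_total = 0.04, mean = 0.3, seed = 1L) {
  stopifnot(rho > 0, rho < 1, n_subjects >= 2)
  rng <- local_rng(seed)
  s_lam <- sqrt(rho * sigma_total)
  s_eps <- sqrt((1 - rho) * sigma_total)
  out <- array(NA_real_, dim = c(n_subjects, 2L, n_edges))
  for (e in seq_len(n_edges)) {
    lam <- rng$rnorm(n_subjects, mean, s_lam)
    out[, 1, e] <- lam + rng$rnorm(n_subjects, 0, s_eps)
    out[, 2, e] <- lam + rng$rnorm(n_subjects, 0, s_eps)
  }
  out
}
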