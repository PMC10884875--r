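#' Write / read a numeric matrix as tab-separated text
#'
#' Plain TSV with a header row of column ids; the shared on-disk matrix
#' form for signal matrices, connectomes and probability matrices.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  colnames(m) <- if (is.null(colnames(m))) paste0("V", seq_len(ncol(m)))
  else colnames(m)
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_matrix_tsv: empty file ", path)
  widths <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(widths)) != 1L)
    stop("read_matrix_tsv: ragged row at line ",
         which(widths != widths[1])[1], " of ", path)
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

# JSON sidecar carrying a run's metadata next to its matrix file.
write_sidecar <- function(run, path) {
  jsonlite::write_json(
    list(tr_seconds = run$tr, subject = run$subject, session = run$session,
         run = run$run, state = run$state, unit_level = run$unit_level),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BOLD time-series matrix with its JSON sidecar
#'
#' Reads a frames x units TSV plus the `<file>.json` sidecar written by
#' [simulate_dataset()] (fields `tr_seconds`, `subject`, `session`,
#' `run`, `state`). The censor mask starts all-retained; apply
#' [censor_frames()] with the motion trace afterwards.
#'
#' @param path path to the `_bold.tsv` matrix.
#' @return a [bold_run].
#' @export
read_timeseries <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("read_timeseries: missing sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("tr_seconds", "subject", "session", "run", "state"))
    if (is.null(meta[[f]]))
      stop("read_timeseries: sidecar missing field '", f, "'")
  m <- read_matrix_tsv(path)
  bold_run(m, tr = meta$tr_seconds, subject = meta$subject,
           session = meta$session, run = meta$run, state = meta$state,
           unit_level = if (identical(meta$unit_level, "dense")) "dense"
           else "parcel")
}

#' Read a BIDS-style events table
#'
#' TSV with columns `onset`, `duration`, `trial_type` (seconds, 0-based
#' from run start). Rows are returned sorted by onset (with a warning
#' if the file was unsorted); `n/a` durations parse as missing but the
#' event is retained.
#'
#' @param path events TSV path.
#' @return data.frame with `onset`, `duration`, `trial_type`.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "n/a", stringsAsFactors = FALSE)
  req <- c("onset", "duration", "trial_type")
  missing_cols <- setdiff(req, names(ev))
  if (length(missing_cols))
    stop("read_events: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(ev) && any(ev$onset < 0)) stop("read_events: negative onset")
  if (nrow(ev) && is.unsorted(ev$onset)) {
    warning("read_events: onsets unsorted; sorting")
    ev <- ev[order(ev$onset), , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev[, req]
}

#' Read a motion-parameters table
#'
#' TSV with either a precomputed `fd` column, six motion parameter
#' columns (three translations in mm then three rotations in radians),
#' or both. FD is computed via [compute_fd()] when absent.
#'
#' @param path motion TSV path.
#' @param head_radius passed to [compute_fd()] when FD must be derived.
#' @return data.frame including an `fd` column.
#' @export
read_motion <- function(path, head_radius = 50) {
  mo <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"fd" %in% names(mo)) {
    if (ncol(mo) < 6L)
      stop("read_motion: need an fd column or 6 motion parameter columns")
    mo$fd <- compute_fd(mo[, 1:6])
  }
  mo
}

#' Write / read a per-unit map as two-column TSV
#'
#' @param map numeric per-unit vector.
#' @param path file path.
#' @return `path` (write) or named numeric vector (read).
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(
    data.frame(unit = seq_along(map), value = as.numeric(map)),
    path, sep = "\t", row.names = FALSE, quote = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a")
  stats::setNames(d$value, d$unit)
}

#' Pipeline configuration
#'
#' Bundles the analysis constants: the framewise-displacement censoring
#' threshold (0.20 mm), the temporal band-pass (0.01-0.08 Hz), global
#' signal regression, the edge-density grid for network detection
#' (2-5%), the reference state for volume matching, the session split,
#' and whether task-evoked responses are regressed before task
#' connectomes.
#'
#' @param fd_threshold censoring threshold, mm.
#' @param band band-pass edges, Hz.
#' @param gsr logical, global signal regression.
#' @param densities edge-density grid (fractions).
#' @param reference_state state defining the volume-matching target
#'   (`NULL` = shortest task present, by retained total).
#' @param split optional explicit session split (list of two index
#'   vectors).
#' @param task_regress regress FIR task effects before task connectomes.
#' @param consensus_seed,infomap_reps community-detection controls.
#' @param max_networks network cap for excess reassignment.
#' @param fir named list per task state: `n_bins`, `bin_width`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fd_threshold = 0.20, band = c(0.01, 0.08),
                            gsr = TRUE, densities = c(0.02, 0.03, 0.04, 0.05),
                            reference_state = NULL, split = NULL,
                            task_regress = TRUE, consensus_seed = 1L,
                            infomap_reps = 20L, max_networks = 17L,
                            fir = NULL) {
  stopifnot(fd_threshold > 0, all(band > 0), all(densities > 0))
  structure(list(fd_threshold = fd_threshold, band = band, gsr = gsr,
                 densities = densities, reference_state = reference_state,
                 split = split, task_regress = task_regress,
                 consensus_seed = as.integer(consensus_seed),
                 infomap_reps = as.integer(infomap_reps),
                 max_networks = as.integer(max_networks), fir = fir),
            class = "pipeline_config")
}

# Censor frames beyond a cumulative retained target (earliest kept),
# walking runs in (session, run) order. Used to volume-match run-level
# statistics without re-slicing matrices.
truncate_runs <- function(runs, target) {
  ord <- order(vapply(runs, function(r) as.numeric(r$session), numeric(1)),
               vapply(runs, function(r) as.numeric(r$run), numeric(1)))
  used <- 0L
  for (i in ord) {
    r <- runs[[i]]
    keep_idx <- which(r$censor)
    room <- max(0L, target - used)
    if (length(keep_idx) > room)
      r$censor[keep_idx[seq.int(room + 1L, length(keep_idx))]] <- FALSE
    used <- used + min(length(keep_idx), room)
    runs[[i]] <- r
  }
  runs
}

#' Run the full reliability pipeline on a simulated dataset
#'
#' Chains every stage end to end on a dataset directory written by
#' [simulate_dataset()]: reads runs, censors by framewise displacement,
#' cleans (detrend + band-pass + confound/global-signal regression),
#' optionally residualizes task runs against their FIR designs,
#' volume-matches states to the reference state, builds split-half
#' connectomes and FC-TRC maps per subject and state, edge-wise
#' ICC(2,1) at rest, tMean/tSD/tSNR maps with task-minus-rest deltas,
#' a consensus network assignment from the group rest connectome, the
#' parcel-wise map regressions, and the per-parcel mixed model. Rerun
#' with the same inputs and config reproduces identical numbers.
#'
#' @param dataset_dir directory holding the manifest and run files.
#' @param config a [pipeline_config].
#' @param out_dir optional directory for result tables (maps, partition,
#'   stats, a JSON log with censoring counts and the truncation target).
#' @param neighbors optional parcel adjacency for excess reassignment;
#'   defaults to a chain over parcel ids.
#' @param mixed_model fit the per-parcel mixed model (default TRUE; the
#'   slowest stage).
#' @return list of class `fc_pipeline_result` with components
#'   `fc_trc` (per state: subject maps + group mean/sd), `delta_fc_trc`,
#'   `icc` (rest edge/parcel ICC), `signal` (per measure/state),
#'   `delta_signal`, `networks` (consensus assignment), `associations`,
#'   `mixed_model`, `log`.
#' @export
run_pipeline <- function(dataset_dir, config = pipeline_config(),
                         out_dir = NULL, neighbors = NULL,
                         mixed_model = TRUE) {
  manifest_path <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("run_pipeline: no manifest at ", manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  recs <- manifest$runs
  states <- names(manifest$runs_per_state)
  task_states <- setdiff(states, "rest")

  raw_runs <- list()      # censored, un-cleaned (for tMean/tSD/tSNR)
  clean_runs <- list()    # censored + cleaned (for FC)
  resid_runs <- list()    # cleaned + task-residualized
  censor_log <- list()
  for (i in seq_len(nrow(recs))) {
    stem <- sub("_bold\\.tsv$", "", recs$bold[i])
    run <- read_timeseries(file.path(dataset_dir, recs$bold[i]))
    motion <- read_motion(file.path(dataset_dir, paste0(stem, "_motion.tsv")))
    run <- censor_frames(run, motion$fd, config$fd_threshold)
    censor_log[[stem]] <- sum(!run$censor)
    raw_runs[[stem]] <- run
    cleaned <- clean_timeseries(run, band = config$band, gsr = config$gsr)
    clean_runs[[stem]] <- cleaned
    if (run$state != "rest" && config$task_regress) {
      ev <- read_events(file.path(dataset_dir, paste0(stem, "_events.tsv")))
      fir_par <- config$fir[[run$state]]
      if (is.null(fir_par))
        fir_par <- if (run$state == "motor")
          list(n_bins = 7L, bin_width = 2.2) else
            list(n_bins = 8L, bin_width = 1.5)
      des <- build_fir_design(
        ev, fir_spec(unique(ev$trial_type), fir_par$n_bins, fir_par$bin_width),
        n_frames = nrow(run$data), tr = run$tr)
      resid_runs[[stem]] <- residualize(cleaned, des)
    } else {
      resid_runs[[stem]] <- cleaned
    }
  }

  subjects <- sort(unique(vapply(raw_runs, function(r) r$subject, numeric(1))))
  sessions <- sort(unique(vapply(raw_runs, function(r) r$session, numeric(1))))

  # volume-matching target from the reference state's retained totals
  ref <- config$reference_state
  if (is.null(ref))
    ref <- if (length(task_states)) task_states[[1]] else "rest"
  ref_totals <- vapply(subjects, function(s)
    sum(vapply(clean_runs, function(r)
      if (r$subject == s && r$state == ref) sum(r$censor) else 0L,
      integer(1))), numeric(1))
  target <- min(ref_totals)
  half_target <- floor(target / 2)

  pick <- function(pool, s, st)
    Filter(function(r) r$subject == s && r$state == st, pool)

  # per-subject, per-state split-half FC-TRC on volume-matched halves
  session_half_series <- function(pool, s, st) {
    sess_series <- lapply(sessions, function(d) {
      sel <- Filter(function(r) r$session == d, pick(pool, s, st))
      if (!length(sel)) NULL else concat_mean_centered(sel)
    })
    sess_series <- sess_series[!vapply(sess_series, is.null, logical(1))]
    n <- length(sess_series)
    split <- config$split
    if (is.null(split)) split <- list(seq_len(floor(n / 2)),
                                      seq(floor(n / 2) + 1, n))
    halves <- lapply(split, function(idx) {
      m <- do.call(rbind, sess_series[idx])
      m[seq_len(min(nrow(m), half_target)), , drop = FALSE]
    })
    halves
  }

  trc <- list(); trc_resid <- list()
  for (st in states) {
    maps <- list(); maps_r <- list()
    for (s in subjects) {
      halves <- session_half_series(clean_runs, s, st)
      pair <- list(first = pearson_connectome(halves[[1]]),
                   second = pearson_connectome(halves[[2]]))
      maps[[paste0("sub", s)]] <- fc_trc(pair)
      if (st != "rest" && config$task_regress) {
        halves_r <- session_half_series(resid_runs, s, st)
        pair_r <- list(first = pearson_connectome(halves_r[[1]]),
                       second = pearson_connectome(halves_r[[2]]))
        maps_r[[paste0("sub", s)]] <- fc_trc(pair_r)
      }
    }
    trc[[st]] <- c(list(subject = maps), group_summary(maps))
    if (length(maps_r))
      trc_resid[[st]] <- c(list(subject = maps_r), group_summary(maps_r))
  }
  delta_trc <- lapply(task_states, function(st)
    delta_map(trc[[st]]$mean, trc$rest$mean))
  names(delta_trc) <- task_states

  # rest edge-wise ICC across subjects
  icc_res <- NULL
  if (length(subjects) >= 2L && "rest" %in% states) {
    pairs <- lapply(subjects, function(s) {
      halves <- session_half_series(clean_runs, s, "rest")
      list(first = pearson_connectome(halves[[1]]),
           second = pearson_connectome(halves[[2]]))
    })
    icc_res <- icc_edgewise(pairs)
  }

  # signal properties on raw censored runs, volume matched by truncation
  signal <- list(); delta_sig <- list()
  for (meas in c("tmean", "tsd", "tsnr")) {
    per_state <- list()
    for (st in states) {
      runs_st <- list()
      for (s in subjects)
        runs_st <- c(runs_st, truncate_runs(pick(raw_runs, s, st), target))
      # truncation can fully censor trailing runs; drop them
      runs_st <- Filter(function(r) sum(r$censor) >= 2L, runs_st)
      per_state[[st]] <- list(
        subject = signal_property_map(runs_st, meas, "subject"),
        group = signal_property_map(runs_st, meas, "group"))
    }
    signal[[meas]] <- per_state
    delta_sig[[meas]] <- lapply(task_states, function(st)
      delta_signal(per_state[[st]]$group, per_state$rest$group))
    names(delta_sig[[meas]]) <- task_states
  }

  # consensus networks from the group-mean rest connectome
  networks <- NULL
  if ("rest" %in% states) {
    conns <- lapply(subjects, function(s) {
      series <- do.call(rbind, lapply(sessions, function(d) {
        sel <- Filter(function(r) r$session == d, pick(clean_runs, s, "rest"))
        if (!length(sel)) NULL else concat_mean_centered(sel)
      }))
      pearson_connectome(series)$matrix
    })
    group_conn <- Reduce(`+`, conns) / length(conns)
    P <- nrow(group_conn)
    parts <- lapply(seq_along(config$densities), function(i)
      detect_communities(density_threshold(group_conn, config$densities[i]),
                         n_reps = config$infomap_reps,
                         seed = config$consensus_seed + i))
    cons <- consensus_partition(parts, seed = config$consensus_seed)
    if (is.null(neighbors))
      neighbors <- cbind(seq_len(P - 1), seq_len(P - 1) + 1L)
    final <- reassign_excess(cons$partition, config$max_networks, neighbors)
    networks <- list(group_connectome = group_conn, partitions = parts,
                     consensus = cons, assignment = final$membership,
                     n_reassigned = final$n_reassigned)
  }

  # map associations at rest
  associations <- NULL
  if (!is.null(networks) && "rest" %in% states) {
    assoc <- list(
      tmean_vs_trc = parcelwise_ols(signal$tmean$rest$group, trc$rest$mean),
      tsd_vs_trc = parcelwise_ols(signal$tsd$rest$group, trc$rest$mean),
      tsnr_trend = monotone_trend(signal$tsnr$rest$group, trc$rest$mean))
    associations <- assoc
  }

  # long table + per-parcel mixed model across states
  mm <- NULL
  if (mixed_model && length(task_states)) {
    pe_by_sub_state <- list()
    for (st in task_states) {
      recs_pe <- list()
      for (s in subjects) for (r in pick(clean_runs, s, st)) {
        stem <- sprintf("sub-%02d_ses-%02d_task-%s_run-%02d",
                        r$subject, r$session, st, r$run)
        ev <- read_events(file.path(dataset_dir, paste0(stem, "_events.tsv")))
        fir_par <- config$fir[[st]]
        if (is.null(fir_par))
          fir_par <- if (st == "motor") list(n_bins = 7L, bin_width = 2.2)
        else list(n_bins = 8L, bin_width = 1.5)
        des <- build_fir_design(
          ev, fir_spec(unique(ev$trial_type), fir_par$n_bins,
                       fir_par$bin_width),
          n_frames = nrow(r$data), tr = r$tr)
        fit <- fit_glm(r, des)
        pe <- Reduce(`+`, lapply(unique(ev$trial_type), function(cc)
          average_contrast(fit, cc))) / length(unique(ev$trial_type))
        recs_pe[[length(recs_pe) + 1L]] <-
          list(subject = r$subject, session = r$session, condition = st,
               pe = pe)
      }
      agg <- aggregate_pes(recs_pe)
      pe_by_sub_state[[st]] <- agg$subject
    }
    long <- do.call(rbind, lapply(states, function(st)
      do.call(rbind, lapply(subjects, function(s) {
        sub_key <- paste0("sub", s)
        data.frame(
          parcel = seq_along(trc[[st]]$subject[[sub_key]]),
          subject = s, state = st,
          reliability = as.numeric(trc[[st]]$subject[[sub_key]]),
          tmean = as.numeric(signal$tmean[[st]]$subject[[sub_key]]),
          tsd = as.numeric(signal$tsd[[st]]$subject[[sub_key]]),
          pe = if (st == "rest") 0 else
            as.numeric(pe_by_sub_state[[st]][[as.character(s)]]))
      }))))
    mm <- fit_mixed_model(long)
    mm$table <- long
  }

  log <- list(fd_threshold = config$fd_threshold,
              censored_frames = censor_log,
              volume_match_target = target,
              half_target = half_target,
              reference_state = ref,
              densities = config$densities,
              gsr = config$gsr, task_regress = config$task_regress)

  result <- structure(
    list(fc_trc = trc, fc_trc_residualized = trc_resid,
         delta_fc_trc = delta_trc, icc = icc_res, signal = signal,
         delta_signal = delta_sig, networks = networks,
         associations = associations, mixed_model = mm, log = log),
    class = "fc_pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (st in states)
      write_map_tsv(trc[[st]]$mean,
                    file.path(out_dir, paste0("fc_trc_group_", st, ".tsv")))
    for (st in task_states)
      write_map_tsv(delta_trc[[st]],
                    file.path(out_dir, paste0("delta_fc_trc_", st, ".tsv")))
    if (!is.null(icc_res))
      write_map_tsv(icc_res$parcel_icc, file.path(out_dir, "icc_parcel_rest.tsv"))
    if (!is.null(networks))
      utils::write.table(
        data.frame(parcel = seq_along(networks$assignment),
                   network = networks$assignment),
        file.path(out_dir, "consensus_assignment.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(mm))
      utils::write.table(mm$betas, file.path(out_dir, "mixed_model_betas.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.fc_pipeline_result <- function(x, ...) {
  states <- names(x$fc_trc)
  cat("<fc_pipeline_result>\n")
  for (st in states)
    cat(sprintf("  FC-TRC %-9s group mean %.3f\n", st,
                mean(x$fc_trc[[st]]$mean)))
  if (!is.null(x$icc))
    cat(sprintf("  rest edge ICC(2,1) mean %.3f\n",
                mean(x$icc$edge_icc, na.rm = TRUE)))
  if (!is.null(x$networks))
    cat(sprintf("  consensus networks: %d\n",
                length(unique(x$networks$assignment))))
  invisible(x)
}
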