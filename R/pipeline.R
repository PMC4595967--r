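#' Analysis configuration with canonical defaults
#'
#' All numeric constants of the pipeline in one validated list. Defaults:
#' 2-cm bins, sigma-2-bin smoothing, 100 circular shuffles with a 2.325 SMI
#' cutoff (99th percentile of chance), 0.5-Hz activity and 5-Hz CA1
#' interneuron thresholds, 6 cm/s / 0.5 s stop filter, 10-cm well margins,
#' 30th-percentile field baseline with 1-Hz / 20%-of-baseline peaks, 10%
#' boundaries and 4-cm merging, 10-ms cross-correlogram bins with threshold
#' 8 in a +/-200-ms window, +/-50-cm bidirectionality window at per-lag
#' alpha 0.00098 (0.05/51), 50% minimum field overlap and 10 usable laps.
#'
#' @param ... overrides for any default listed above.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(bin_cm = 2, smooth_sigma_bins = 2, n_shuffles = 100,
              smi_threshold = 2.325, smi_basis = "sic", active_hz = 0.5,
              interneuron_hz = 5, speed_floor_cms = 6, stop_min_s = 0.5,
              well_margin_cm = 10, baseline_pct = 30, field_peak_min_hz = 1,
              field_peak_baseline_frac = 0.2, field_boundary_frac = 0.1,
              field_merge_gap_cm = 4, xcorr_bin_ms = 10,
              xcorr_max_lag_ms = 500, xcorr_peak_window_ms = 200,
              xcorr_sig_threshold = 8, bidir_window_cm = 50,
              bidir_alpha = 0.00098, overlap_min_frac = 0.5,
              overlap_denom = "shorter", min_laps = 10, master_seed = 1L,
              path = default_c_track())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(unlist(cfg[num & names(cfg) != "master_seed"]) <= 0))
    stop("all numeric thresholds must be positive")
  structure(cfg, class = "run_config")
}

#' Recording-day group
#'
#' Days 1-2 form T1 (novel), days 3-5 T2 (intermediate), days 6 and later T3
#' (familiar).
#'
#' @param day recording-day integer(s).
#' @return character vector of `"T1"`, `"T2"`, `"T3"`.
#' @export
day_group <- function(day) {
  ifelse(day <= 2, "T1", ifelse(day <= 5, "T2", "T3"))
}

# FNV-style string hash, hex; used to stamp outputs with their config.
# Modulus keeps intermediate products exactly representable as doubles.
fnv1a_hex <- function(s) {
  h <- 10570841
  for (ch in utf8ToInt(s))
    h <- ((bitwXor(as.integer(h), ch)) * 16777619) %% 67108859
  sprintf("%08x", as.integer(h))
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), "path")]
  fnv1a_hex(paste(
    paste(names(keep), vapply(keep, function(x) paste(format(x), collapse = ","),
                              character(1)), sep = "=", collapse = ";"),
    paste(format(config$path$vertices), collapse = ","), sep = "|"))
}

#' Run the full analysis pipeline on a session
#'
#' Linearizes and segments the session, masks non-running samples, then per
#' trajectory: rate curves, spatial information, stability, SMI with
#' location-responsiveness, firing-field detection, V1-CA1 spike
#' cross-correlograms, pair classification with lap-by-lap co-fluctuation
#' (raw and behavior-residualized), bidirectional firing classification,
#' and COM-shift curves. Deterministic given the session and
#' `config$master_seed`.
#'
#' @param session a [track_session()].
#' @param config a [run_config()].
#' @return list of data.frames `behavior`, `metrics`, `fields`, `bidir`,
#'   `xcorr_pairs`, `pairs`, `comshift`, plus `summary` (grouped counts and
#'   medians), `laps` and `config`.
#' @export
run_pipeline <- function(session, config = run_config()) {
  stopifnot(inherits(session, "track_session"), inherits(config, "run_config"))
  L <- session$track_length_cm
  lin <- linearize_and_segment(session$positions, config$path,
                               config$well_margin_cm)
  samples <- compute_speed_and_mask(lin$samples, L, config$well_margin_cm,
                                    config$speed_floor_cms, config$stop_min_s)
  laps <- lin$laps
  behav <- behavior_metrics(laps, samples)
  cells <- session$cells
  cells$cell_id <- as.character(cells$cell_id)

  metrics <- list(); fields <- list(); curves <- list(); xrows <- list()
  prow <- list(); lapcoms <- list()
  for (tr in unique(laps$trajectory_id)) {
    ctx <- traj_ctx(samples, laps, tr, L, config$bin_cm,
                    config$smooth_sigma_bins)
    run_spk <- list()
    for (ci in seq_len(nrow(cells))) {
      id <- cells$cell_id[ci]
      times <- session$spikes[[id]]
      if (is.null(times)) times <- numeric(0)
      curve <- rate_curve_from_ctx(ctx, times)
      cls <- classify_active(curve$overall_rate, cells$region[ci],
                             config$active_hz, config$interneuron_hz)
      si <- spatial_information(curve)
      stab <- spatial_stability(curve)
      usable <- cls$active && !cls$putative_interneuron
      smi <- NA_real_; resp <- FALSE
      if (usable && curve$n_spikes > 0) {
        sm <- compute_smi_ctx(ctx, times, config$n_shuffles,
                              cell_seed(config$master_seed, id, tr),
                              config$smi_basis, config$smi_threshold)
        smi <- sm$smi; resp <- sm$location_responsive
      }
      f <- NULL
      wants_fields <- usable &&
        (cells$region[ci] == "CA1" || resp)
      if (wants_fields) {
        f <- detect_fields(curve, config$baseline_pct,
                           config$field_peak_min_hz,
                           config$field_peak_baseline_frac,
                           config$field_boundary_frac,
                           config$field_merge_gap_cm)
        if (nrow(f)) {
          fields[[length(fields) + 1L]] <-
            cbind(cell_id = id, trajectory_id = tr, f)
        }
      }
      curves[[paste(id, tr)]] <- curve
      rs <- running_spikes(times, samples, tr)
      run_spk[[id]] <- rs
      metrics[[length(metrics) + 1L]] <- data.frame(
        cell_id = id, region = cells$region[ci], layer = cells$layer[ci],
        day = cells$day[ci], day_group = day_group(cells$day[ci]),
        trajectory_id = tr, overall_rate_hz = curve$overall_rate,
        sic_bits_per_spike = si$sic, sir_bits_per_s = si$sir,
        stability = stab$stability, active = cls$active,
        putative_interneuron = cls$putative_interneuron, smi = smi,
        location_responsive = resp,
        n_fields = if (is.null(f)) NA_integer_ else nrow(f))
    }
    mt <- do.call(rbind, metrics)
    mtr <- mt[mt$trajectory_id == tr, ]
    fl <- if (length(fields)) do.call(rbind, fields) else NULL
    get_fields <- function(id) {
      if (is.null(fl)) return(empty_fields())
      g <- fl[fl$cell_id == id & fl$trajectory_id == tr, , drop = FALSE]
      if (!nrow(g)) empty_fields() else g
    }
    v1 <- mtr$cell_id[mtr$region == "V1" & mtr$active]
    ca1 <- mtr$cell_id[mtr$region == "CA1" & mtr$active &
                         !mtr$putative_interneuron]
    rtime <- if (length(run_spk)) run_spk[[1]]$total_time_s else 0
    for (a in v1) for (b in ca1) {
      resp_a <- mtr$location_responsive[mtr$cell_id == a]
      resp_b <- mtr$location_responsive[mtr$cell_id == b]
      xc <- NULL
      if (resp_a && resp_b && rtime > 0 &&
          length(run_spk[[a]]$times) && length(run_spk[[b]]$times)) {
        xc <- normalized_xcorr(run_spk[[a]]$times, run_spk[[b]]$times, rtime,
                               config$xcorr_bin_ms, config$xcorr_max_lag_ms,
                               config$xcorr_peak_window_ms,
                               config$xcorr_sig_threshold)
        xrows[[length(xrows) + 1L]] <- data.frame(
          cell_a = a, cell_b = b, trajectory_id = tr,
          peak_value = xc$peak_value, peak_time_s = xc$peak_time_s,
          highly_significant = xc$highly_significant)
      }
      pc <- classify_pair(get_fields(a), get_fields(b), resp_a, resp_b, xc,
                          config$overlap_min_frac,
                          config$xcorr_sig_threshold,
                          config$xcorr_peak_window_ms / 1000, L,
                          seed = cell_seed(config$master_seed,
                                           paste(a, b), tr),
                          denom = config$overlap_denom)
      if (pc$class %in% c("none", "unclassified")) next
      cf <- pair_cofluctuation(session$spikes[[a]], session$spikes[[b]],
                               pc$interval_a, pc$interval_b, laps, samples,
                               tr, config$min_laps, ctx)
      prow[[length(prow) + 1L]] <- cbind(
        data.frame(cell_a = a, cell_b = b, trajectory_id = tr,
                   class = pc$class, overlap_frac = pc$overlap_frac),
        cf$stats)
    }
    # per-lap COM of each responsive cell's dominant field (for COM shift)
    for (id in c(v1, ca1)) {
      if (!mtr$location_responsive[mtr$cell_id == id]) next
      dom <- dominant_field(get_fields(id))
      if (is.null(dom)) next
      lt <- lap_fluctuations(session$spikes[[id]], laps, samples, tr, dom,
                             ctx)
      lapcoms[[paste(id, tr)]] <- list(
        region = cells$region[cells$cell_id == id], lt = lt)
    }
  }
  metrics <- do.call(rbind, metrics)
  fields <- if (length(fields)) do.call(rbind, fields) else
    cbind(data.frame(cell_id = character(), trajectory_id = character()),
          empty_fields())
  xcorr_pairs <- if (length(xrows)) do.call(rbind, xrows) else
    data.frame(cell_a = character(), cell_b = character(),
               trajectory_id = character(), peak_value = numeric(),
               peak_time_s = numeric(), highly_significant = logical())
  pairs <- if (length(prow)) do.call(rbind, prow) else
    data.frame(cell_a = character(), cell_b = character(),
               trajectory_id = character(), class = character(),
               overlap_frac = numeric(), n_laps = integer(),
               r_drate = numeric(), p_drate = numeric(),
               r_dcom = numeric(), p_dcom = numeric(),
               r_drate_mod = numeric(), p_drate_mod = numeric(),
               r_dcom_mod = numeric(), p_dcom_mod = numeric())
  if (!any(cells$region == "V1") || !any(cells$region == "CA1"))
    warning("session lacks V1 or CA1 cells; pair tables are empty")

  bidir <- bidir_calls(metrics, curves, config)
  comshift <- comshift_table(lapcoms)
  summary <- summarize_run(metrics, pairs, behav, config)
  list(behavior = behav, metrics = metrics, fields = fields, bidir = bidir,
       xcorr_pairs = xcorr_pairs, pairs = pairs, comshift = comshift,
       summary = summary, laps = laps, samples = samples, config = config)
}

empty_fields <- function() {
  data.frame(start_cm = numeric(), end_cm = numeric(),
             peak_pos_cm = numeric(), peak_rate_hz = numeric(),
             length_cm = numeric(), dominant = logical())
}

bidir_calls <- function(metrics, curves, config) {
  out <- list()
  both <- intersect(metrics$cell_id[metrics$trajectory_id == "traj1"],
                    metrics$cell_id[metrics$trajectory_id == "traj2"])
  for (id in both) {
    r1 <- metrics$location_responsive[metrics$cell_id == id &
                                        metrics$trajectory_id == "traj1"]
    r2 <- metrics$location_responsive[metrics$cell_id == id &
                                        metrics$trajectory_id == "traj2"]
    if (!length(r1) || !length(r2)) next
    c1 <- curves[[paste(id, "traj1")]]
    c2 <- curves[[paste(id, "traj2")]]
    if (is.null(c1) || is.null(c2)) next
    bc <- classify_bidirectional(c1, c2, isTRUE(r1) && isTRUE(r2),
                                 config$bidir_window_cm, config$bidir_alpha)
    out[[length(out) + 1L]] <- data.frame(
      cell_id = id, peak_lag_cm = bc$peak_lag_cm, p = bc$peak_p,
      class = bc$class)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(cell_id = character(), peak_lag_cm = numeric(),
               p = numeric(), class = character())
}

comshift_table <- function(lapcoms) {
  if (!length(lapcoms))
    return(data.frame(region = character(), lap = integer(),
                      mean_change_cm = numeric(), se = numeric(),
                      n_cells = integer()))
  regions <- unique(vapply(lapcoms, `[[`, character(1), "region"))
  out <- list()
  for (rg in regions) {
    sub <- Filter(function(x) x$region == rg, lapcoms)
    nl <- max(vapply(sub, function(x) nrow(x$lt), integer(1)))
    M <- t(vapply(sub, function(x) {
      v <- rep(NA_real_, nl)
      v[x$lt$lap] <- x$lt$com_cm
      v
    }, numeric(nl)))
    cs <- suppressWarnings(com_shift_curve(M))
    if (nrow(cs$per_lap))
      out[[rg]] <- cbind(region = rg, cs$per_lap)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(region = character(), lap = integer(),
               mean_change_cm = numeric(), se = numeric(),
               n_cells = integer())
}

summarize_run <- function(metrics, pairs, behav, config) {
  by_region <- lapply(split(metrics, metrics$region), function(m) {
    act <- m[m$active & !m$putative_interneuron, ]
    list(n_cell_traj = nrow(m), n_active = nrow(act),
         pct_location_responsive =
           if (nrow(act)) 100 * mean(act$location_responsive) else NA_real_,
         median_rate_hz = stats::median(act$overall_rate_hz),
         median_sic = stats::median(act$sic_bits_per_spike, na.rm = TRUE),
         median_stability = stats::median(act$stability, na.rm = TRUE),
         median_smi = stats::median(act$smi, na.rm = TRUE),
         mean_n_fields = mean(act$n_fields, na.rm = TRUE))
  })
  grp <- function(col) lapply(split(metrics, metrics[[col]]), function(m) {
    act <- m[m$active & !m$putative_interneuron, ]
    list(n_active = nrow(act),
         pct_location_responsive =
           if (nrow(act)) 100 * mean(act$location_responsive) else NA_real_,
         median_smi = stats::median(act$smi, na.rm = TRUE))
  })
  by_class <- lapply(split(pairs, pairs$class), function(p)
    list(n = nrow(p), mean_r_drate = mean(p$r_drate, na.rm = TRUE),
         mean_r_dcom = mean(p$r_dcom, na.rm = TRUE),
         mean_r_drate_mod = mean(p$r_drate_mod, na.rm = TRUE),
         mean_r_dcom_mod = mean(p$r_dcom_mod, na.rm = TRUE)))
  list(by_region = by_region, by_layer = grp("layer"),
       by_day_group = grp("day_group"), pair_classes = by_class,
       behavior = behav, config_hash = config_hash(config),
       master_seed = config$master_seed)
}

#' Write a pipeline result bundle to disk
#'
#' Writes `metrics.csv`, `fields.csv`, `bidir.csv`, `xcorr_pairs.csv`,
#' `pairs.csv`, `comshift.csv`, `laps.csv` and `summary.json` (which also
#' records the config hash and master seed).
#'
#' @param result a [run_pipeline()] bundle.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE)
  wr(result$metrics, "metrics.csv")
  wr(result$fields, "fields.csv")
  wr(result$bidir, "bidir.csv")
  wr(result$xcorr_pairs, "xcorr_pairs.csv")
  wr(result$pairs, "pairs.csv")
  wr(result$comshift, "comshift.csv")
  wr(result$laps, "laps.csv")
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
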