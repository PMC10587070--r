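# End-to-end orchestration: run configuration (validated, serializable),
# staged execution with manifest-based skipping, and report tables.  Runs
# are reproducible bit-for-bit from (config, seed): every stage derives its
# RNG substream from the master seed and no output embeds timestamps.

#' Default run configuration
#'
#' Stage toggles and all stage parameters.  Analysis parameters default to
#' the pipeline's canonical values (baseline `[-3, -1]` s, 200 ms call
#' exclusion, bootstrap 200 x 200 ms x 1000, four spike windows with
#' `[-8, -4]` s baseline, >= 15 / >= 20 call thresholds, 70/30 split);
#' simulation sizes default to a small demo that completes in minutes.
#'
#' @param seed Master seed.
#' @param outdir Output directory.
#' @return A validated `run_config` list.
#' @export
default_run_config <- function(seed = 1, outdir = "callcortex-run") {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    stages = list(synth = TRUE, detect = TRUE, lfp = TRUE, phase = TRUE,
                  spikes = TRUE, decode = TRUE, report = TRUE),
    synth = list(
      scene_duration_s = 120,
      # named lists (not vectors) so the config survives JSON round-trips
      scene_rates_per_min = list(phee = 2, trill = 4, twitter = 3,
                                 trillphee = 2, compound = 1),
      nontarget_rate_per_min = 6,
      neural_n_calls_per_type = list(trill = 24, twitter = 24,
                                     trillphee = 24),
      neural_call_spacing_s = 14,
      n_channels = 2,
      n_units = 6,
      drift_ppm = 50
    ),
    detect = list(threshold_db = 10, band_hz = c(4000, 20000),
                  min_dur_s = 0.1, max_gap_s = 0.15),
    lfp = list(window = c(-0.1, 0.2), boot_reps = 200, min_trials = 10),
    phase = list(band = c(5, 10)),
    spikes = list(min_calls = 15, boot_reps = 200, shuffle_reps = 10),
    decode = list(centers = c(-1, 0, 1), width_s = 1, min_calls = 20,
                  n_redraw = 200, n_rep = 50, n_pc = 10)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' Rejects unknown keys at every level (against the default template) and
#' checks basic types.
#'
#' @param config A `run_config` (or plain list).
#' @return The config, classed, or an error.
#' @export
validate_run_config <- function(config) {
  template <- unclass(default_run_config_template())
  check_keys <- function(x, tmpl, path = "") {
    if (!is.list(tmpl) || !is.list(x)) return(invisible())
    unknown <- setdiff(names(x), names(tmpl))
    if (length(unknown)) {
      stop("unknown config keys at ", if (nzchar(path)) path else "top level",
           ": ", paste(unknown, collapse = ", "))
    }
    for (nm in names(x)) check_keys(x[[nm]], tmpl[[nm]],
                                    paste0(path, "/", nm))
  }
  check_keys(unclass(config), template)
  stopifnot(is.numeric(config$seed), length(config$seed) == 1)
  class(config) <- "run_config"
  config
}

# The key template is the default config itself; memoized shape only.
default_run_config_template <- function() {
  cfg <- list(seed = 1L, outdir = ".",
              stages = list(synth = TRUE, detect = TRUE, lfp = TRUE,
                            phase = TRUE, spikes = TRUE, decode = TRUE,
                            report = TRUE),
              synth = list(scene_duration_s = 1, scene_rates_per_min = 1,
                           nontarget_rate_per_min = 1,
                           neural_n_calls_per_type = 1,
                           neural_call_spacing_s = 1, n_channels = 1,
                           n_units = 1, drift_ppm = 0),
              detect = list(threshold_db = 1, band_hz = 1, min_dur_s = 1,
                            max_gap_s = 1),
              lfp = list(window = 1, boot_reps = 1, min_trials = 1),
              phase = list(band = 1),
              spikes = list(min_calls = 1, boot_reps = 1, shuffle_reps = 1),
              decode = list(centers = 1, width_s = 1, min_calls = 1,
                            n_redraw = 1, n_rep = 1, n_pc = 1))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration (JSON or YAML by extension)
#' @param config A `run_config`.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `path` / the validated config.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(raw)
}

# Stable hash of a config subtree + upstream hashes; outdir never enters
# the hash so runs in different directories are byte-identical.
config_hash <- function(config, stage = NULL, upstream = character(0)) {
  x <- unclass(config)
  x$outdir <- NULL
  part <- if (is.null(stage)) x else list(seed = x$seed, stage = x[[stage]],
                                          synth = x$synth)
  rlang::hash(list(part, upstream))
}

stage_paths <- function(outdir) {
  list(scene_wav = file.path(outdir, "scene.wav"),
       scene_truth = file.path(outdir, "scene_truth.csv"),
       neural_truth = file.path(outdir, "neural_truth.csv"),
       lfp_bin = file.path(outdir, "lfp.f32"),
       spikes_csv = file.path(outdir, "spikes.csv"),
       sync_csv = file.path(outdir, "sync.csv"),
       detected = file.path(outdir, "detected_calls.csv"),
       detect_metrics = file.path(outdir, "detection_metrics.csv"),
       lfp_results = file.path(outdir, "lfp_results.csv"),
       lfp_embedding = file.path(outdir, "beta_embedding.csv"),
       lfp_distance = file.path(outdir, "beta_distances.csv"),
       phase_results = file.path(outdir, "phase_results.csv"),
       phase_hist = file.path(outdir, "phase_histogram.csv"),
       spike_results = file.path(outdir, "spike_results.csv"),
       spike_tally = file.path(outdir, "spike_tally.csv"),
       decode_curve = file.path(outdir, "decoding_curve.csv"),
       report_txt = file.path(outdir, "summary.txt"),
       report_tally = file.path(outdir, "report_tally.csv"),
       manifest = file.path(outdir, "manifest.json"))
}

write_table <- function(df, path, hash) {
  df$config_hash <- hash
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (synth, detect, lfp, phase,
#' spikes, decode, report), writing tidy CSVs under `config$outdir`.  Each
#' stage records a hash of its governing configuration in the manifest; a
#' rerun skips stages whose hash and outputs are unchanged.  Toggling a
#' stage off makes dependent stages fail with a dependency error.
#'
#' @param config A `run_config` from [default_run_config()].
#' @return A `results_bundle`: list of output paths plus the manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- stage_paths(outdir)
  manifest <- if (file.exists(paths$manifest)) {
    jsonlite::read_json(paths$manifest, simplifyVector = TRUE)
  } else list(stages = list())
  seed <- config$seed
  hashes <- list()

  fresh <- function(stage, hash, outputs) {
    old <- manifest$stages[[stage]]
    !is.null(old) && identical(old, hash) && all(file.exists(outputs))
  }
  require_stage <- function(stage, outputs) {
    if (!all(file.exists(outputs))) {
      stop("stage '", stage, "' outputs missing; enable it or run it first")
    }
  }

  # ---- synth ---------------------------------------------------------
  h_synth <- config_hash(config, "synth")
  hashes$synth <- h_synth
  synth_out <- c(paths$scene_wav, paths$scene_truth, paths$neural_truth,
                 paths$lfp_bin, paths$spikes_csv, paths$sync_csv)
  if (isTRUE(config$stages$synth) && !fresh("synth", h_synth, synth_out)) {
    message("[synth] generating scene, LFP, spikes, sync")
    sc <- config$synth
    cfg_scene <- synth_config(call_rates_per_min =
                                unlist(sc$scene_rates_per_min),
                              n_channels = sc$n_channels,
                              n_units = sc$n_units)
    targets <- generate_call_sequence(cfg_scene, sc$scene_duration_s,
                                      seed = substream_seed(seed, "scene_t"))
    cfg_non <- synth_config(
      call_rates_per_min = c(phee = sc$nontarget_rate_per_min / 2,
                             trill = sc$nontarget_rate_per_min / 2,
                             twitter = 0, trillphee = 0, compound = 0),
      n_channels = sc$n_channels, n_units = sc$n_units)
    nontargets <- generate_call_sequence(
      cfg_non, sc$scene_duration_s,
      seed = substream_seed(seed, "scene_n"))
    nontargets$is_target <- rep(FALSE, nrow(nontargets))
    scene <- generate_acoustic_scene(targets, nontargets, cfg_scene,
                                     seed = substream_seed(seed, "scene"),
                                     duration_s = sc$scene_duration_s)
    write_wav(list(scene$parabolic, scene$reference), paths$scene_wav,
              cfg_scene$sample_rate_hz)
    write_annotations(targets, paths$scene_truth)
    # neural-session calls: regularly spaced with jitter so every trial has
    # clean baseline context
    neural <- neural_call_schedule(unlist(sc$neural_n_calls_per_type),
                                   sc$neural_call_spacing_s, cfg_scene,
                                   substream_seed(seed, "neural"))
    write_annotations(neural, paths$neural_truth)
    lfp <- generate_lfp(neural, cfg_scene,
                        seed = substream_seed(seed, "lfp"),
                        n_channels = sc$n_channels)
    write_lfp(lfp, paths$lfp_bin)
    spk <- generate_spike_trains(neural, cfg_scene,
                                 seed = substream_seed(seed, "spk"))
    write_spikes(spk, paths$spikes_csv)
    sync <- generate_sync(sc$scene_duration_s, drift_ppm = sc$drift_ppm,
                          seed = substream_seed(seed, "sync"))
    write_sync(sync, paths$sync_csv)
  } else if (!isTRUE(config$stages$synth)) {
    message("[synth] disabled")
  } else message("[synth] up to date; skipped")

  # ---- detect --------------------------------------------------------
  h_detect <- config_hash(config, "detect", hashes$synth)
  hashes$detect <- h_detect
  if (isTRUE(config$stages$detect) &&
      !fresh("detect", h_detect, c(paths$detected, paths$detect_metrics))) {
    require_stage("synth", c(paths$scene_wav, paths$scene_truth))
    message("[detect] detecting and classifying target calls")
    wav <- read_wav(paths$scene_wav)
    scene <- structure(list(parabolic = wav$channels[[1]],
                            reference = wav$channels[[2]],
                            sample_rate_hz = wav$sample_rate_hz),
                       class = "acoustic_scene")
    dp <- detection_params(threshold_db = config$detect$threshold_db,
                           band_hz = config$detect$band_hz,
                           min_dur_s = config$detect$min_dur_s,
                           max_gap_s = config$detect$max_gap_s)
    det <- detect_calls(scene, dp)
    write_annotations(det, paths$detected)
    truth <- read_annotations(paths$scene_truth)
    sc <- score_detection(det, truth)
    write_table(data.frame(metric = c("recall", "precision",
                                      "type_accuracy", "n_detected",
                                      "n_truth"),
                           value = c(sc$recall, sc$precision,
                                     sc$type_accuracy, nrow(det),
                                     nrow(truth))),
                paths$detect_metrics, h_detect)
  } else if (isTRUE(config$stages$detect)) message("[detect] up to date; skipped")

  # ---- lfp -----------------------------------------------------------
  h_lfp <- config_hash(config, "lfp", hashes$synth)
  hashes$lfp <- h_lfp
  if (isTRUE(config$stages$lfp) &&
      !fresh("lfp", h_lfp, c(paths$lfp_results, paths$lfp_embedding,
                             paths$lfp_distance))) {
    require_stage("synth", c(paths$lfp_bin, paths$neural_truth))
    message("[lfp] band-power modulation per site and call type")
    lfp <- read_lfp(paths$lfp_bin)
    neural <- read_annotations(paths$neural_truth)
    res <- lfp_stage(lfp, neural, config$lfp, seed)
    write_table(res$table, paths$lfp_results, h_lfp)
    write_table(res$embedding, paths$lfp_embedding, h_lfp)
    write_table(res$distance, paths$lfp_distance, h_lfp)
  } else if (isTRUE(config$stages$lfp)) message("[lfp] up to date; skipped")

  # ---- phase ---------------------------------------------------------
  h_phase <- config_hash(config, "phase", hashes$synth)
  hashes$phase <- h_phase
  if (isTRUE(config$stages$phase) &&
      !fresh("phase", h_phase, c(paths$phase_results, paths$phase_hist))) {
    require_stage("synth", c(paths$lfp_bin, paths$neural_truth))
    message("[phase] theta phase locking of syllable onsets")
    lfp <- read_lfp(paths$lfp_bin)
    neural <- read_annotations(paths$neural_truth)
    multi <- neural[neural$call_type %in% c("twitter", "compound"), ]
    rows <- list(); hrows <- list()
    for (ch in seq_len(nrow(lfp$samples))) {
      pl <- phase_lock_site(lfp, multi, channel = ch,
                            band = config$phase$band)
      rows[[ch]] <- data.frame(site = ch, n = pl$n, vs = pl$vs,
                               rayleigh = pl$statistic, p = pl$p,
                               mean_phase = pl$mean_phase)
      hh <- phase_histogram(pl$phases)
      hh$site <- ch
      hrows[[ch]] <- hh
    }
    write_table(do.call(rbind, rows), paths$phase_results, h_phase)
    write_table(do.call(rbind, hrows), paths$phase_hist, h_phase)
  } else if (isTRUE(config$stages$phase)) message("[phase] up to date; skipped")

  # ---- spikes --------------------------------------------------------
  h_spk <- config_hash(config, "spikes", hashes$synth)
  hashes$spikes <- h_spk
  if (isTRUE(config$stages$spikes) &&
      !fresh("spikes", h_spk, c(paths$spike_results, paths$spike_tally))) {
    require_stage("synth", c(paths$spikes_csv, paths$neural_truth))
    message("[spikes] single-neuron modulation tests and tallies")
    spk <- read_spikes(paths$spikes_csv, n_units = config$synth$n_units,
                       duration_s = NA)
    spk$duration_s <- max(unlist(spk$times), 0) + 11
    neural <- read_annotations(paths$neural_truth)
    res <- spike_stage(spk, neural, config$spikes, seed)
    write_table(res$table, paths$spike_results, h_spk)
    write_table(res$tally, paths$spike_tally, h_spk)
  } else if (isTRUE(config$stages$spikes)) message("[spikes] up to date; skipped")

  # ---- decode --------------------------------------------------------
  h_dec <- config_hash(config, "decode", hashes$synth)
  hashes$decode <- h_dec
  if (isTRUE(config$stages$decode) &&
      !fresh("decode", h_dec, paths$decode_curve)) {
    require_stage("synth", c(paths$spikes_csv, paths$neural_truth))
    message("[decode] Monte-Carlo LDA decoding, trill vs twitter")
    spk <- read_spikes(paths$spikes_csv, n_units = config$synth$n_units)
    spk$duration_s <- max(unlist(spk$times), 0) + 11
    neural <- read_annotations(paths$neural_truth)
    dc <- config$decode
    curve <- sliding_decoding_curve(
      spk, neural[neural$call_type == "trill", ],
      neural[neural$call_type == "twitter", ],
      centers = dc$centers, width_s = dc$width_s,
      min_calls = dc$min_calls, n_redraw = dc$n_redraw,
      n_rep = dc$n_rep, n_pc = dc$n_pc,
      seed = substream_seed(seed, "decode"))
    write_table(as.data.frame(curve), paths$decode_curve, h_dec)
  } else if (isTRUE(config$stages$decode)) message("[decode] up to date; skipped")

  # ---- report --------------------------------------------------------
  manifest <- list(stages = hashes,
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("callcortex")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  bundle <- structure(list(paths = paths, manifest = manifest,
                           config = config),
                      class = "results_bundle")
  if (isTRUE(config$stages$report)) {
    write_report(bundle)
  }
  bundle
}

# Regularly spaced neural-session call schedule (spacing +/- 1 s jitter)
# so every trial has clean [-10, 10] s context.
neural_call_schedule <- function(n_per_type, spacing_s, config, seed) {
  set.seed(seed)
  types <- rep(names(n_per_type), n_per_type)
  types <- sample(types)
  onsets <- 12 + (seq_along(types) - 1) * spacing_s +
    stats::runif(length(types), -1, 1)
  durs <- vapply(types, function(ty) {
    rng <- config$duration_range_s[[ty]]
    stats::runif(1, rng[1], rng[2])
  }, 0)
  syl <- mapply(function(on, d, ty) syllable_times(on, on + d, ty, config),
                onsets, durs, types, SIMPLIFY = FALSE)
  off <- onsets + durs
  tw <- types == "twitter"
  off[tw] <- vapply(syl[tw], max, 0) + config$twitter_syllable_duty_s
  call_events(onsets, off, types, syl, is_target = TRUE)
}

# LFP stage: per site x call type, beta and theta modulation in the
# analysis window, start time, peak features; then the beta-profile PCA.
lfp_stage <- function(lfp, events, opts, seed) {
  types <- intersect(CALL_TYPES, unique(events$call_type))
  rows <- list(); profs <- list(); labels <- character(0)
  for (ch in seq_len(nrow(lfp$samples))) {
    traces <- list(beta = band_power_trace(lfp, beta_band(), ch),
                   theta = band_power_trace(lfp, theta_band(), ch))
    for (ty in types) {
      ev <- events[events$call_type == ty, ]
      if (nrow(ev) < opts$min_trials) next
      for (bd in list(beta_band(), theta_band())) {
        tp <- band_power_timecourse(lfp, ev, bd, channel = ch,
                                    trace = traces[[bd$name]])
        sdb <- bootstrap_baseline_sd(tp, reps = opts$boot_reps,
                                     seed = substream_seed(seed,
                                       paste0("sd", ch, ty, bd$name)))
        mt <- test_window_modulation(tp, opts$window, sdb)
        st <- if (mt$significant) {
          find_modulation_start_time(tp, sdb, mt$direction)
        } else list(start_s = NA_real_, found = FALSE)
        pk <- extract_peak_features(tp, if (mt$direction == "none")
          "suppression" else mt$direction)
        rows[[length(rows) + 1]] <- data.frame(
          site = ch, call_type = ty, band = bd$name,
          n_trials = nrow(tp$power), median_power = mt$median_power,
          p = mt$p, sd = sdb, significant = mt$significant,
          direction = mt$direction, start_time_s = st$start_s,
          peak_magnitude = pk$peak_magnitude, peak_time_s = pk$peak_time_s)
        if (bd$name == "beta") {
          profs[[length(profs) + 1]] <- beta_profile(tp)
          labels <- c(labels, ty)
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  if (length(profs) >= 4 && length(unique(labels)) >= 2) {
    emb <- embed_beta_profiles(profs, labels)
    wb <- within_between_distance(emb)
    embedding <- data.frame(call_type = labels,
                            pc1 = emb$scores[, 1], pc2 = emb$scores[, 2],
                            pc3 = emb$scores[, min(3, ncol(emb$scores))])
    distance <- data.frame(
      set = c("within", "between"),
      mean_distance = c(mean(wb$within), mean(wb$between)),
      n_pairs = c(wb$n_within, wb$n_between),
      p = wb$p)
  } else {
    embedding <- data.frame(call_type = character(0), pc1 = numeric(0),
                            pc2 = numeric(0), pc3 = numeric(0))
    distance <- data.frame(set = character(0), mean_distance = numeric(0),
                           n_pairs = integer(0), p = numeric(0))
  }
  list(table = table, embedding = embedding, distance = distance)
}

# Spike stage: per unit x type window tests; tallies for trill/twitter and
# trill/trillphee.
spike_stage <- function(spk, events, opts, seed) {
  types <- intersect(CALL_TYPES, unique(events$call_type))
  n_units <- length(spk$times)
  # circular-shift shuffle control runs on the most frequent call type
  shuffle_type <- types[which.max(table(events$call_type)[types])]
  rows <- list()
  profiles <- list()
  for (u in seq_len(n_units)) {
    for (ty in types) {
      ev <- events[events$call_type == ty, ]
      ra <- build_raster(spk, ev, u, min_calls = opts$min_calls)
      if (!ra$tested) {
        profiles[[ty]][[u]] <- list(tested = FALSE, modulated = FALSE,
                                    windows = data.frame())
        next
      }
      prof <- normalize_rates(ra)
      res <- test_spike_modulation(prof, n_boot = opts$boot_reps,
                                   seed = substream_seed(seed,
                                     paste0("u", u, ty)),
                                   tested = TRUE)
      profiles[[ty]][[u]] <- res
      shuf <- if (ty == shuffle_type && opts$shuffle_reps > 0) {
        shuffle_control(ra, reps = opts$shuffle_reps,
                        seed = substream_seed(seed, paste0("sh", u)),
                        n_boot = min(200, opts$boot_reps))$prop_windows
      } else NA_real_
      w <- res$windows
      rows[[length(rows) + 1]] <- data.frame(
        unit = u, call_type = ty, window = w$window, p = w$p,
        passes_2sd = w$passes_2sd, significant = w$significant,
        direction = w$direction, tested = TRUE, modulated = res$modulated,
        n_trials = res$n_trials, shuffle_prop_windows = shuf)
    }
  }
  pad <- function(lst) {
    lst <- lst %||% list()
    length(lst) <- n_units
    lapply(lst, function(x) x %||% list(tested = FALSE, modulated = FALSE,
                                        windows = data.frame()))
  }
  tally_rows <- list()
  for (pair in list(c("trill", "twitter"), c("trill", "trillphee"))) {
    if (!all(pair %in% types)) next
    tl <- tally_modulation(pad(profiles[[pair[1]]]), pad(profiles[[pair[2]]]))
    tally_rows[[length(tally_rows) + 1]] <- data.frame(
      type_a = pair[1], type_b = pair[2], n_tested = tl$n_tested,
      a_only = tl$a_only, b_only = tl$b_only, both = tl$both,
      both_different = tl$both_different, modulated = tl$modulated,
      diff_proportion = tl$diff_proportion)
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(unit = integer(0)),
       tally = if (length(tally_rows)) do.call(rbind, tally_rows) else
         data.frame(type_a = character(0)))
}

#' Write the summary report
#'
#' Table-1-style per-type neuron tallies, per-site LFP modulation counts,
#' the phase-lock table and the decoding curve, condensed into
#' `report_tally.csv` and a plain-text `summary.txt`.
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @return The bundle, invisibly.
#' @export
write_report <- function(bundle) {
  paths <- bundle$paths
  need <- c(paths$spike_results, paths$lfp_results, paths$phase_results,
            paths$decode_curve)
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("cannot write report; missing stage outputs: ",
         paste(basename(missing), collapse = ", "))
  }
  spikes <- utils::read.csv(paths$spike_results)
  lfp <- utils::read.csv(paths$lfp_results)
  phase <- utils::read.csv(paths$phase_results)
  curve <- utils::read.csv(paths$decode_curve)
  lines <- c("callcortex run summary", "======================", "")
  tally <- list()
  for (ty in unique(spikes$call_type)) {
    s <- spikes[spikes$call_type == ty, ]
    per_unit <- split(s, s$unit)
    tested <- length(per_unit)
    act <- sum(vapply(per_unit, function(x)
      any(x$significant & x$direction == "activated"), TRUE))
    sup <- sum(vapply(per_unit, function(x)
      any(x$significant) && !any(x$significant &
                                 x$direction == "activated"), TRUE))
    mod <- sum(vapply(per_unit, function(x) any(x$significant), TRUE))
    tally[[ty]] <- data.frame(call_type = ty, tested = tested,
                              modulated = mod, activated = act,
                              suppressed = sup,
                              proportion = if (tested) mod / tested else 0)
    lines <- c(lines, sprintf(
      "%-10s neurons tested %3d, modulated %3d (%d activated / %d suppressed)",
      ty, tested, mod, act, sup))
  }
  tally_df <- if (length(tally)) do.call(rbind, tally) else
    data.frame(call_type = character(0), tested = integer(0),
               modulated = integer(0), activated = integer(0),
               suppressed = integer(0), proportion = numeric(0))
  write_table(tally_df, paths$report_tally, bundle$manifest$config_hash)
  nsig <- sum(lfp$significant & lfp$band == "beta")
  lines <- c(lines, "",
             sprintf("LFP beta-band: %d of %d site x type tests significant",
                     nsig, sum(lfp$band == "beta")),
             sprintf("Phase locking: median VS %.2f over %d sites",
                     stats::median(phase$vs), nrow(phase)),
             sprintf("Decoding: peak accuracy %.2f at t = %+.1f s",
                     max(curve$mean_acc),
                     curve$center_s[which.max(curve$mean_acc)]))
  writeLines(lines, paths$report_txt)
  invisible(bundle)
}
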