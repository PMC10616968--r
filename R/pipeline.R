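#' Default pipeline configuration
#'
#' Nested list of every stage parameter. The defaults reproduce the reference
#' protocol: resample to 256 Hz, 1 Hz high-pass, common median reference,
#' channel rejection at >2 SD (SD), >5 SD (kurtosis), >1% uncorrelated time,
#' ASR cutoff 20 on a standing baseline, EEMD IMF1 + CCA suppression,
#' spherical-spline interpolation, separate EEG/EMG average reference, PCA to
#' 80 components before ICA, epochs (-0.5, 2.0) s, baseline (-0.5, 0) s,
#' k = 14 clustering with weights 2/10/1, 3 SD outliers, minimum 5
#' participants, 85% scalp-variance retention.
#'
#' @param ... named overrides, e.g. `tfr = list(n_boot = 500)` (partial lists
#'   are merged; unknown keys are rejected).
#' @return a `pipeline_config` nested list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(resample = TRUE, highpass = TRUE, median_reference = TRUE,
                  notch = TRUE, channel_rejection = TRUE, asr = TRUE,
                  eemd_cca = TRUE, interpolate = TRUE, average_reference = TRUE,
                  ica = TRUE, clustering = TRUE, tfr = TRUE),
    resample = list(target = 256),
    highpass = list(cutoff = 1),
    notch = list(line_freq = NA, bw = 2),
    channel_rejection = list(window = 1, corr_threshold = 0.4,
                             n_neighbours = 4, sd_crit = 2, kurt_crit = 5,
                             uncorr_crit = 0.01),
    asr = list(cutoff_sd = 20, window = 0.5),
    eemd_cca = list(n_ensembles = 10, noise_sd_fraction = 0.1, delay = 1,
                    iqr_mult = 1.5),
    ica = list(n_pca = 80, include_emg = TRUE, max_iter = 200, tol = 1e-4,
               max_samples = 60000),
    epochs = list(tmin = -0.5, tmax = 2.0),
    tfr = list(fmin = 4, fmax = 100, n_freqs = 50, cycles_base = 3,
               cycle_exponent = 0.5, baseline = c(-0.5, 0), alpha = 0.05,
               n_boot = 200),
    clustering = list(k = 14, weights = c(spectral = 2, dipole = 10, scalp = 1),
                      sd_threshold = 3, min_participants = 5,
                      scalp_variance = 0.85, reduce_dims = 10, n_init = 50))
  over <- list(...)
  merge_cfg <- function(base, o, path = "") {
    for (nm in names(o)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", path, nm)
      if (is.null(o[[nm]]))
        base[[nm]] <- NA                 # JSON null round-trips as NA
      else if (is.list(base[[nm]]) && is.list(o[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], o[[nm]], paste0(path, nm, "."))
      else base[[nm]] <- o[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, over), class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration (JSON)
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$clustering$weights <- unlist(raw$clustering$weights)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  # small deterministic polynomial hash; enough to tag outputs with their config
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

prov_add <- function(prov, stage, params = list(), counts = list()) {
  prov[[length(prov) + 1]] <- list(stage = stage, params = params,
                                   counts = counts,
                                   time = format(Sys.time(), "%H:%M:%OS1"))
  prov
}

preprocess_steps <- function(raw, cfg, prov, tag) {
  st <- cfg$stages
  if (st$resample) {
    raw <- resample_recording(raw, cfg$resample$target)
    prov <- prov_add(prov, paste0(tag, ":resample"),
                     list(target = cfg$resample$target),
                     list(n_samples = ncol(raw$data)))
  }
  if (st$highpass) {
    raw <- highpass_filter(raw, cfg$highpass$cutoff)
    prov <- prov_add(prov, paste0(tag, ":highpass"), list(cutoff = cfg$highpass$cutoff))
  }
  if (st$median_reference) {
    raw <- common_median_reference(raw)
    prov <- prov_add(prov, paste0(tag, ":median_reference"))
  }
  if (st$notch && !is.null(cfg$notch$line_freq) && is.finite(cfg$notch$line_freq)) {
    raw <- notch_line_noise(raw, cfg$notch$line_freq, cfg$notch$bw)
    prov <- prov_add(prov, paste0(tag, ":notch"),
                     list(line_freq = cfg$notch$line_freq))
  }
  list(raw = raw, prov = prov)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, per subject: resampling, high-pass, common median reference,
#' optional notch, channel-quality rejection, ASR calibrated on the subject's
#' standing baseline, EEMD/CCA artifact suppression, interpolation of the
#' rejected channels, separate EEG/EMG average referencing, ICA, scalp-
#' variance component retention and epoching; then, across subjects, weighted
#' k-means dipole clustering with outlier/participant rules and
#' representative selection, and per-retained-cluster masked ERSP and ITC
#' maps (median across trials within participant, averaged across
#' participants).
#'
#' @param config a `pipeline_config`.
#' @param study a study list from [simulate_study()] (per subject: `raw`,
#'   `events`, `baseline`, `subject`).
#' @return list with `qc`, `components`, `clusters`, `table`, `maps`,
#'   `provenance`, `config_hash`.
#' @export
run_pipeline <- function(config, study) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)         # one deterministic stream for the whole run
  st <- config$stages
  prov <- list()
  qc <- list(); comps <- list(); epochs_by_subject <- list()
  # epoch padding: half-support of the lowest-frequency wavelet, so the full
  # analysis window (incl. the baseline) survives TFR edge-trimming
  pad <- 3.5 * config$tfr$cycles_base / (2 * pi * config$tfr$fmin)
  for (sb in study) {
    tag <- sb$subject
    pp <- preprocess_steps(sb$raw, config, prov, tag)
    raw <- pp$raw; prov <- pp$prov
    bad <- integer(0)
    if (st$channel_rejection) {
      cs <- compute_channel_stats(raw, config$channel_rejection$window,
                                  config$channel_rejection$corr_threshold,
                                  config$channel_rejection$n_neighbours)
      rep <- flag_bad_channels(cs, sd_crit = config$channel_rejection$sd_crit,
                               kurt_crit = config$channel_rejection$kurt_crit,
                               uncorr_crit = config$channel_rejection$uncorr_crit)
      qc[[tag]] <- rep
      bad <- rep$bad_channels
      prov <- prov_add(prov, paste0(tag, ":channel_rejection"),
                       counts = list(rejected = length(bad),
                                     retained = rep$retained))
    }
    work <- drop_channels(raw, bad)
    if (st$asr || st$eemd_cca) {
      bl <- preprocess_steps(sb$baseline, config, list(), paste0(tag, ":baseline"))$raw
      bl <- drop_channels(bl, bad)
      model <- if (st$asr)
        asr_calibrate(bl, config$asr$cutoff_sd, config$asr$window) else NULL
      if (st$eemd_cca) {
        dn <- apply_denoise(work, asr = model,
                            n_ensembles = config$eemd_cca$n_ensembles,
                            noise_sd_fraction = config$eemd_cca$noise_sd_fraction,
                            delay = config$eemd_cca$delay,
                            iqr_mult = config$eemd_cca$iqr_mult)
        work <- dn$raw
        prov <- prov_add(prov, paste0(tag, ":denoise"), counts = dn$log$eemd_cca)
      } else if (st$asr) {
        res <- asr_clean(work, model)
        work <- res$raw
        prov <- prov_add(prov, paste0(tag, ":asr"), counts = res$log)
      }
    }
    if (st$interpolate && length(bad) > 0) {
      full <- raw
      good_idx <- setdiff(seq_len(nrow(raw$data)), bad)
      full$data[good_idx, ] <- work$data
      full <- interpolate_channels(full, bad)
      work <- full
      prov <- prov_add(prov, paste0(tag, ":interpolate"),
                       counts = list(n_interpolated = length(bad)))
    }
    if (st$average_reference) {
      work <- average_reference(work, "EEG")
      if (length(channel_indices(work, "EMG")) > 0)
        work <- average_reference(work, "EMG")
      prov <- prov_add(prov, paste0(tag, ":average_reference"))
    }
    if (st$ica) {
      cset <- run_ica(work, n_pca = config$ica$n_pca,
                      include_emg = config$ica$include_emg,
                      max_iter = config$ica$max_iter, tol = config$ica$tol,
                      max_samples = config$ica$max_samples, subject = tag)
      cset <- localize_components(cset, work$positions[cset$channels, , drop = FALSE])
      cset <- retain_by_scalp_variance(cset, config$clustering$scalp_variance)
      comps[[tag]] <- cset
      prov <- prov_add(prov, paste0(tag, ":ica"),
                       counts = list(n_components = nrow(cset$activations)))
      epochs_by_subject[[tag]] <- epoch_recording(
        cset$activations, sb$events,
        tmin = config$epochs$tmin - pad, tmax = config$epochs$tmax + pad,
        srate = work$srate)
    }
  }
  result <- list(qc = qc, components = comps, provenance = prov,
                 config_hash = config_hash(config))
  if (st$clustering && length(comps) > 0) {
    srate <- config$resample$target
    feat <- assemble_features(comps, srate,
                              weights = config$clustering$weights,
                              reduce_dims = config$clustering$reduce_dims)
    cl <- kmeans_cluster(feat, k = config$clustering$k, seed = config$seed,
                         n_init = config$clustering$n_init)
    cl <- mark_outliers(cl, config$clustering$sd_threshold)
    cl <- retain_clusters(cl, config$clustering$min_participants)
    profiles <- vapply(seq_len(nrow(feat$features)), function(i) {
      cs <- comps[[feat$subjects[i]]]
      classify_component_profile(welch_psd(cs$activations[feat$component[i], ],
                                           srate))$class
    }, "")
    cl <- select_representative(cl, profiles)
    result$clusters <- cl
    result$table <- cluster_table(cl)
    prov <- prov_add(prov, "clustering",
                     counts = list(retained_clusters = sum(cl$retained),
                                   n_removed = cl$n_removed))
    if (st$tfr) {
      freqs <- default_freq_grid(config$tfr$fmin, config$tfr$fmax,
                                 config$tfr$n_freqs)
      maps <- list()
      sel <- which(cl$selected)
      for (k in which(cl$retained)) {
        members <- sel[cl$assignment[sel] == k & !is.na(cl$assignment[sel])]
        em <- list(); im <- list()
        for (i in members) {
          ep <- epochs_by_subject[[cl$subjects[i]]]
          tf <- morlet_tfr(ep, freqs, config$tfr$cycles_base,
                           config$tfr$cycle_exponent,
                           channel = cl$component[i])
          em[[length(em) + 1]] <- ersp_bootstrap_mask(tf, config$tfr$baseline,
                                                      config$tfr$alpha,
                                                      config$tfr$n_boot)
          im[[length(im) + 1]] <- itc_significance_mask(tf, config$tfr$baseline,
                                                        config$tfr$alpha,
                                                        config$tfr$n_boot)
        }
        if (length(em) == 0) next
        avg <- function(lst) Reduce(`+`, lapply(lst, `[[`, "values")) / length(lst)
        maps[[as.character(k)]] <- list(
          ersp = list(values = avg(em), freqs = em[[1]]$freqs,
                      times = em[[1]]$times, n_participants = length(em)),
          itc = list(values = avg(im), freqs = im[[1]]$freqs,
                     times = im[[1]]$times, n_participants = length(im)))
      }
      result$maps <- maps
      prov <- prov_add(prov, "tfr", list(n_boot = config$tfr$n_boot,
                                         alpha = config$tfr$alpha),
                       list(n_cluster_maps = length(maps)))
    }
  }
  result$provenance <- prov
  result
}
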