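# Component retention, artifact-profile classification, weighted k-means
# clustering across subjects, and representative selection.

#' Welch power spectral density
#'
#' @param x numeric signal.
#' @param srate sampling rate, Hz.
#' @param seg_len segment length, samples (Hann window, 50% overlap).
#' @return data.frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, srate, seg_len = 512) {
  seg_len <- min(seg_len, length(x))
  hop <- floor(seg_len / 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1, length(x) - seg_len + 1, by = hop)
  acc <- numeric(floor(seg_len / 2) + 1)
  for (st in starts) {
    seg <- (x[st:(st + seg_len - 1)] - mean(x[st:(st + seg_len - 1)])) * win
    sp <- Mod(stats::fft(seg))^2 / (sum(win^2) * srate)
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / length(starts)
  psd[2:(length(psd) - 1)] <- 2 * psd[2:(length(psd) - 1)]
  data.frame(freq = (seq_along(psd) - 1) * srate / seg_len, psd = psd)
}

#' Retain components explaining the bulk of the scalp variance
#'
#' Components are sorted by explained scalp variance and retained greedily
#' until the cumulative fraction exceeds `threshold` (default 0.85).
#'
#' @param comp a `component_set` (with `scalp_variance` fractions).
#' @param threshold cumulative explained-variance target in (0, 1].
#' @return the reduced `component_set`; an attribute `retained_idx` records
#'   the original component indices.
#' @export
retain_by_scalp_variance <- function(comp, threshold = 0.85) {
  if (threshold <= 0 || threshold > 1)
    stop("config error: threshold must be in (0, 1]")
  v <- comp$scalp_variance
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  n_keep <- if (threshold == 1) length(v) else which(cum > threshold)[1]
  if (is.na(n_keep)) n_keep <- length(v)
  keep <- sort(ord[seq_len(n_keep)])
  out <- comp
  out$unmixing <- comp$unmixing[keep, , drop = FALSE]
  out$mixing <- comp$mixing[, keep, drop = FALSE]
  out$activations <- comp$activations[keep, , drop = FALSE]
  out$dipoles <- comp$dipoles[keep, , drop = FALSE]
  out$residual_variance <- comp$residual_variance[keep]
  out$scalp_variance <- comp$scalp_variance[keep]
  attr(out, "retained_idx") <- keep
  out
}

#' Classify a component spectral profile as brain-like or suspect
#'
#' A component is suspect when (a) the global spectral peak lies above 30 Hz,
#' or (b) mean log-power below 6 Hz exceeds mean 6-30 Hz log-power by more
#' than `low_margin_db`, or (c) no local maximum exists in the alpha (8-13 Hz)
#' nor beta (13-30 Hz) range after 1/f detrending.
#'
#' @param psd data.frame with `freq` and `psd` covering at least 2-100 Hz.
#' @param low_margin_db margin for rule (b), dB.
#' @param peak_prominence_db minimal detrended prominence for an alpha/beta
#'   peak, dB.
#' @return list with `class` ("brain" or "suspect") and `rules` triggered.
#' @export
classify_component_profile <- function(psd, low_margin_db = 10,
                                       peak_prominence_db = 1) {
  f <- psd$freq; p <- 10 * log10(pmax(psd$psd, .Machine$double.xmin))
  rng <- f >= 2 & f <= 100
  f <- f[rng]; p <- p[rng]
  rules <- character(0)
  if (f[which.max(p)] > 30) rules <- c(rules, "high_freq_peak")
  lowm <- mean(p[f < 6]); midm <- mean(p[f >= 6 & f <= 30])
  if (lowm - midm > low_margin_db) rules <- c(rules, "low_freq_power")
  # 1/f detrend: robust line fit in log-log
  lf <- log10(f)
  fit <- stats::lm(p ~ lf)
  d <- stats::residuals(fit)
  has_peak <- function(lo, hi) {
    idx <- which(f >= lo & f <= hi)
    any(vapply(idx, function(i) {
      i > 1 && i < length(d) && d[i] > d[i - 1] && d[i] > d[i + 1] &&
        d[i] > peak_prominence_db
    }, logical(1)))
  }
  if (!has_peak(8, 13) && !has_peak(13, 30)) rules <- c(rules, "no_alpha_beta_peak")
  list(class = if (length(rules)) "suspect" else "brain", rules = rules)
}

#' Assemble the weighted clustering feature matrix
#'
#' Per component: a spectral block (log Welch PSD 3-45 Hz, PCA-reduced), the
#' dipole xyz block, and a scalp-map block (PCA-reduced). Each block is
#' centred and scaled by a single per-block factor (the SD of its leading
#' dimension), then multiplied by its weight (defaults 2 / 10 / 1) and
#' concatenated. Components without a dipole are excluded and logged.
#'
#' @param comps list of `component_set` (one per subject).
#' @param srate activation sampling rate, Hz.
#' @param weights named vector c(spectral=, dipole=, scalp=).
#' @param reduce_dims PCA dimensions per reducible block.
#' @return list with `features` matrix, `subjects`, `component` indices,
#'   `dipoles` (mm), `residual_variance`, `excluded`.
#' @export
assemble_features <- function(comps, srate,
                              weights = c(spectral = 2, dipole = 10, scalp = 1),
                              reduce_dims = 10) {
  spec <- list(); dip <- list(); scalp <- list()
  subj <- character(0); cidx <- integer(0); rv <- numeric(0)
  excluded <- list()
  for (cs in comps) {
    for (j in seq_len(nrow(cs$activations))) {
      if (anyNA(cs$dipoles[j, ])) {
        excluded[[length(excluded) + 1]] <- list(subject = cs$subject, comp = j)
        next
      }
      ps <- welch_psd(cs$activations[j, ], srate)
      sel <- ps$freq >= 3 & ps$freq <= 45
      spec[[length(spec) + 1]] <- 10 * log10(pmax(ps$psd[sel], 1e-300))
      dip[[length(dip) + 1]] <- cs$dipoles[j, ]
      scalp[[length(scalp) + 1]] <- cs$mixing[, j] / sqrt(sum(cs$mixing[, j]^2))
      subj <- c(subj, cs$subject); cidx <- c(cidx, j)
      rv <- c(rv, cs$residual_variance[j])
    }
  }
  blocks <- list(spectral = do.call(rbind, spec),
                 dipole = do.call(rbind, dip),
                 scalp = do.call(rbind, scalp))
  out <- NULL
  for (nm in names(blocks)) {
    B <- blocks[[nm]]
    if (nm != "dipole" && ncol(B) > reduce_dims) {
      pc <- stats::prcomp(B, center = TRUE, scale. = FALSE)
      B <- pc$x[, seq_len(min(reduce_dims, ncol(pc$x))), drop = FALSE]
    }
    # one scale factor per block (SD of the leading dimension), preserving
    # relative scales within the block: per-dimension standardization would
    # amplify noise directions to the level of informative ones
    B <- scale(B, center = TRUE, scale = FALSE)
    s <- stats::sd(B[, 1])
    if (!is.finite(s) || s == 0) s <- 1
    out <- cbind(out, B / s * weights[[nm]])
  }
  list(features = out, subjects = subj, component = cidx,
       dipoles = blocks$dipole, residual_variance = rv, excluded = excluded)
}

#' k-means clustering of the component features
#'
#' @param feat output of [assemble_features()].
#' @param k number of clusters (default 14).
#' @param seed RNG seed for the restarts.
#' @param n_init random restarts; the best inertia wins.
#' @return a `cluster_result`: per-component `assignment` (NA = outlier),
#'   `centroids`, plus the feature metadata.
#' @export
kmeans_cluster <- function(feat, k = 14, seed = 1, n_init = 50) {
  X <- feat$features
  if (nrow(X) < k)
    stop("fewer components (", nrow(X), ") than clusters; reduce k")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100)
  structure(list(assignment = km$cluster, centroids = km$centers, k = k,
                 features = X, subjects = feat$subjects,
                 component = feat$component, dipoles = feat$dipoles,
                 residual_variance = feat$residual_variance,
                 retained = rep(TRUE, k), selected = NULL,
                 outlier = rep(FALSE, nrow(X))),
            class = "cluster_result")
}

#' Mark within-cluster outlier components
#'
#' A component is an outlier when its feature distance to its cluster
#' centroid exceeds mean + `sd_threshold` SDs of the within-cluster distances
#' (itself excluded). Singleton clusters never produce outliers.
#'
#' @param result a `cluster_result`.
#' @param sd_threshold SD multiplier (default 3; Inf disables).
#' @return updated `cluster_result` with `outlier` flags and NA assignments
#'   for outliers.
#' @export
mark_outliers <- function(result, sd_threshold = 3) {
  if (!is.finite(sd_threshold)) return(result)
  d <- sqrt(rowSums((result$features -
                       result$centroids[result$assignment, , drop = FALSE])^2))
  for (cl in seq_len(result$k)) {
    idx <- which(result$assignment == cl & !result$outlier)
    if (length(idx) < 3) next
    for (i in idx) {
      rest <- setdiff(idx, i)
      thr <- mean(d[rest]) + sd_threshold * stats::sd(d[rest])
      if (is.finite(thr) && d[i] > thr) result$outlier[i] <- TRUE
    }
  }
  result$assignment[result$outlier] <- NA
  result
}

#' Discard clusters with too few participants
#'
#' @param result a `cluster_result`.
#' @param min_participants minimum distinct subjects (default 5).
#' @return updated `cluster_result` with the `retained` flags set.
#' @export
retain_clusters <- function(result, min_participants = 5) {
  for (cl in seq_len(result$k)) {
    subj <- unique(result$subjects[which(result$assignment == cl)])
    result$retained[cl] <- length(subj) >= min_participants
  }
  if (!any(result$retained))
    warning("no cluster reaches ", min_participants, " participants")
  result
}

#' Select one representative component per subject per retained cluster
#'
#' Within each retained cluster, each subject's members are sorted by
#' residual variance (ascending); the first whose spectral profile is
#' classified "brain" is kept. If all are suspect the lowest-RV one is kept
#' and flagged. Ties on residual variance break toward the lower component
#' index.
#'
#' @param result a `cluster_result`.
#' @param profiles optional character vector ("brain"/"suspect") per
#'   component row; defaults to all "brain" (no exclusions).
#' @return updated `cluster_result` with `selected` (logical per row),
#'   `flagged_suspect`, and `n_removed` (members displaced by the
#'   one-per-subject rule or the profile rule).
#' @export
select_representative <- function(result, profiles = NULL) {
  n <- length(result$assignment)
  if (is.null(profiles)) profiles <- rep("brain", n)
  selected <- rep(FALSE, n)
  flagged <- rep(FALSE, n)
  removed <- 0L
  for (cl in which(result$retained)) {
    members <- which(result$assignment == cl)
    for (s in unique(result$subjects[members])) {
      mine <- members[result$subjects[members] == s]
      ord <- mine[order(result$residual_variance[mine], result$component[mine])]
      pick <- ord[match("brain", profiles[ord])]
      if (is.na(pick)) {
        pick <- ord[1]
        flagged[pick] <- TRUE
      }
      selected[pick] <- TRUE
      removed <- removed + length(mine) - 1L
    }
  }
  result$selected <- selected
  result$flagged_suspect <- flagged
  result$n_removed <- removed
  result
}

#' Summary table of retained clusters
#'
#' One row per retained cluster: participant count, component count and the
#' centroid dipole coordinates (mean of member dipoles, mm).
#'
#' @param result a `cluster_result` after selection.
#' @param use_selected count only selected representatives (default uses all
#'   assigned members).
#' @return data.frame with cluster, n_participants, n_components, x, y, z.
#' @export
cluster_table <- function(result, use_selected = FALSE) {
  rows <- lapply(which(result$retained), function(cl) {
    idx <- which(result$assignment == cl)
    if (use_selected && !is.null(result$selected))
      idx <- idx[result$selected[idx]]
    data.frame(cluster = cl,
               n_participants = length(unique(result$subjects[idx])),
               n_components = length(idx),
               x = mean(result$dipoles[idx, 1]),
               y = mean(result$dipoles[idx, 2]),
               z = mean(result$dipoles[idx, 3]))
  })
  do.call(rbind, rows)
}
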