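# Synthetic multi-subject component sets with ground-truth dipole clusters.
# Used to exercise the clustering stage without running ICA: dipole fitting
# is out of scope, so these stand-in components carry generator-assigned
# dipoles, spectra and scalp maps.

canonical_cluster_locations <- function() {
  rbind(occ_r = c(30, -65, 15), occ_l = c(-30, -65, 15),
        parietal = c(0, -70, 45), sm_r = c(50, -10, 50),
        sm_l = c(-50, -10, 50), frontal = c(0, 45, 35))
}

synth_activation <- function(n, srate, band, amp = 4) {
  lim <- band_limits(band)
  f0 <- mean(lim)
  tt <- (seq_len(n) - 1) / srate
  amp * cos(2 * pi * f0 * tt + cumsum(stats::rnorm(n, 0, 0.05))) +
    2 * pink_noise(n, srate)
}

#' Simulate multi-subject component sets with planted dipole clusters
#'
#' Builds `component_set` objects for `n_subjects` synthetic subjects: each of
#' six canonical source locations contributes one component per member
#' subject (dipole jittered by `location_jitter` mm, brain-like spectrum,
#' smooth scalp map, low residual variance); one extra location is planted in
#' exactly `n_small` subjects (to exercise the minimum-participant rule); and
#' each subject receives `n_noise` artifact-like components at random
#' locations with rough maps and high residual variance.
#'
#' @param n_subjects number of subjects.
#' @param n_small membership of the planted under-sized cluster.
#' @param n_noise noise components per subject.
#' @param location_jitter dipole jitter SD, mm.
#' @param srate,duration activation sampling rate (Hz) and length (s).
#' @param n_channels scalp-map channel count.
#' @return list with `components` (list of `component_set`) and `truth`
#'   (locations and per-cluster member subjects).
#' @export
simulate_component_sets <- function(n_subjects = 8, n_small = 4, n_noise = 2,
                                    location_jitter = 5, srate = 256,
                                    duration = 30, n_channels = 32) {
  locs <- canonical_cluster_locations()
  small_loc <- c(0, 0, 70)
  pos <- synthetic_montage(n_channels)
  n <- round(duration * srate)
  bands <- c("alpha", "alpha", "theta", "beta", "beta", "theta")
  membership <- lapply(seq_len(nrow(locs)), function(i) {
    lo <- min(max(5, n_subjects - 2), n_subjects)
    size <- sample(lo:n_subjects, 1)
    sort(sample(seq_len(n_subjects), size))
  })
  small_members <- sort(sample(seq_len(n_subjects), n_small))
  comps <- list()
  for (s in seq_len(n_subjects)) {
    acts <- list(); dip <- list(); maps <- list(); rv <- c()
    for (ci in seq_len(nrow(locs))) {
      if (!s %in% membership[[ci]]) next
      d <- locs[ci, ] + stats::rnorm(3, 0, location_jitter)
      acts[[length(acts) + 1]] <- synth_activation(n, srate, bands[ci])
      dip[[length(dip) + 1]] <- d
      w <- exp(-sqrt(colSums((t(pos) - d)^2)) / 50)
      maps[[length(maps) + 1]] <- w / sqrt(sum(w^2))
      rv <- c(rv, stats::runif(1, 0.02, 0.10))
    }
    if (s %in% small_members) {
      d <- small_loc + stats::rnorm(3, 0, location_jitter)
      acts[[length(acts) + 1]] <- synth_activation(n, srate, "alpha")
      dip[[length(dip) + 1]] <- d
      w <- exp(-sqrt(colSums((t(pos) - d)^2)) / 50)
      maps[[length(maps) + 1]] <- w / sqrt(sum(w^2))
      rv <- c(rv, stats::runif(1, 0.02, 0.10))
    }
    for (k in seq_len(n_noise)) {
      # noise dipoles kept >= 30 mm from every planted location so the
      # fixture's cluster membership is unambiguous
      repeat {
        d <- stats::runif(3, -70, 70)
        if (min(sqrt(rowSums((rbind(locs, small_loc) -
                                matrix(d, nrow(locs) + 1, 3, byrow = TRUE))^2))) > 30)
          break
      }
      acts[[length(acts) + 1]] <- 3 * pink_noise(n, srate) +
        synth_activation(n, srate, "gamma", amp = 2)
      dip[[length(dip) + 1]] <- d
      w <- stats::rnorm(n_channels)
      maps[[length(maps) + 1]] <- w / sqrt(sum(w^2))
      rv <- c(rv, stats::runif(1, 0.2, 0.5))
    }
    A <- do.call(cbind, maps)
    acts_m <- do.call(rbind, acts)
    comps[[s]] <- structure(list(
      unmixing = MASS_pinv(A), mixing = A, activations = acts_m,
      subject = sprintf("S%02d", s), channels = seq_len(n_channels),
      labels = paste0("EEG", seq_len(n_channels)),
      dipoles = do.call(rbind, dip), residual_variance = rv,
      scalp_variance = rep(1 / nrow(acts_m), nrow(acts_m))),
      class = "component_set")
  }
  list(components = comps,
       truth = list(locations = locs, membership = membership,
                    small_location = small_loc, small_members = small_members))
}
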