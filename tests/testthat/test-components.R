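fake_component_set <- function(sv, rv = NULL, n_ch = 8, subject = "S01") {
  k <- length(sv)
  structure(list(unmixing = diag(k), mixing = matrix(rnorm(n_ch * k), n_ch),
                 activations = matrix(rnorm(k * 256), k),
                 subject = subject, channels = seq_len(n_ch),
                 labels = paste0("EEG", seq_len(n_ch)),
                 dipoles = matrix(rnorm(3 * k), k),
                 residual_variance = rv %||% runif(k),
                 scalp_variance = sv),
            class = "component_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("scalp-variance retention is greedy and cumulative", {
  cs <- fake_component_set(c(0.5, 0.3, 0.1, 0.1))
  kept <- retain_by_scalp_variance(cs, 0.85)
  expect_equal(attr(kept, "retained_idx"), 1:3)     # 0.9 > 0.85
  expect_equal(nrow(retain_by_scalp_variance(cs, 1)$activations), 4)
  one <- fake_component_set(0.9)
  expect_equal(nrow(retain_by_scalp_variance(one, 0.85)$activations), 1)
  expect_error(retain_by_scalp_variance(cs, 1.2), "config error")
})

test_that("spectral profile classification follows the three rules", {
  f <- seq(2, 100, 0.5)
  brain <- classify_component_profile(
    data.frame(freq = f, psd = 1 / f + 0.5 * exp(-(f - 10)^2 / 4)))
  expect_equal(brain$class, "brain")
  hi <- classify_component_profile(
    data.frame(freq = f, psd = 0.1 + 2 * (f == 60)))
  expect_equal(hi$class, "suspect")
  expect_true("high_freq_peak" %in% hi$rules)
  lo <- classify_component_profile(data.frame(freq = f, psd = 1 / f^3))
  expect_true("low_freq_power" %in% lo$rules)
  flat <- classify_component_profile(data.frame(freq = f, psd = 1 / f))
  expect_equal(flat$class, "suspect")
  expect_true("no_alpha_beta_peak" %in% flat$rules)
})

test_that("feature weights control block contributions to distance", {
  set.seed(2)
  scs <- simulate_component_sets(n_subjects = 4, n_small = 0, n_noise = 1)
  f_full <- assemble_features(scs$components, 256)
  f_nodip <- assemble_features(scs$components, 256,
                               weights = c(spectral = 2, dipole = 0, scalp = 1))
  # weight-0 block contributes nothing: distances identical to dropping it
  d_full <- as.matrix(dist(f_full$features))
  keep <- !seq_len(ncol(f_full$features)) %in%
    (ncol(f_full$features) - 12:10)           # dipole block is 3 columns
  d_nodip <- as.matrix(dist(f_nodip$features))
  d_manual <- as.matrix(dist(f_full$features[, 11:13] * 0)) # zero matrix
  expect_true(all(abs(d_nodip - as.matrix(dist(f_nodip$features))) < 1e-12))
  expect_false(isTRUE(all.equal(d_full, d_nodip)))

  # component without a dipole is excluded and logged
  scs$components[[1]]$dipoles[1, ] <- NA
  f_ex <- assemble_features(scs$components, 256)
  expect_equal(nrow(f_ex$features), nrow(f_full$features) - 1)
  expect_length(f_ex$excluded, 1)
})

test_that("k-means clustering recovers separated blobs deterministically", {
  set.seed(4)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 10), matrix(rnorm(30, 5, 0.2), 10),
             matrix(rnorm(30, -5, 0.2), 10))
  feat <- list(features = X, subjects = rep(c("A", "B"), 15),
               component = seq_len(30), dipoles = matrix(0, 30, 3),
               residual_variance = runif(30))
  cl <- kmeans_cluster(feat, k = 3, seed = 1)
  truth <- rep(1:3, each = 10)
  purity <- max(table(cl$assignment, truth)) # any relabeling: each block pure
  expect_equal(length(unique(cl$assignment[1:10])), 1)
  expect_equal(length(unique(cl$assignment[11:20])), 1)
  expect_equal(length(unique(cl$assignment[21:30])), 1)
  cl2 <- kmeans_cluster(feat, k = 3, seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
  k1 <- kmeans_cluster(feat, k = 1, seed = 1)
  expect_close(as.numeric(k1$centroids), colMeans(X), 1e-9)
  expect_error(kmeans_cluster(list(features = X[1:2, ]), k = 3), "reduce k")
})

test_that("outlier marking targets only far members", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3, 0, 0.3), 20)
  X[20, ] <- c(50, 50, 50)
  feat <- list(features = X, subjects = paste0("S", 1:20),
               component = 1:20, dipoles = matrix(0, 20, 3),
               residual_variance = runif(20))
  cl <- kmeans_cluster(feat, k = 1, seed = 1)
  out <- mark_outliers(cl, 3)
  expect_true(out$outlier[20])
  expect_equal(sum(out$outlier), 1)
  expect_true(is.na(out$assignment[20]))
  # sd_threshold = Inf disables
  expect_equal(sum(mark_outliers(cl, Inf)$outlier), 0)
  # homogeneous cluster (uniform ball: bounded distances): no outliers
  set.seed(6)
  B <- matrix(rnorm(25 * 3), 25)
  B <- B / sqrt(rowSums(B^2)) * runif(25)^(1 / 3)
  cl2 <- kmeans_cluster(list(features = B, subjects = paste0("S", 1:25),
                             component = 1:25, dipoles = matrix(0, 25, 3),
                             residual_variance = runif(25)), k = 1, seed = 1)
  expect_equal(sum(mark_outliers(cl2, 3)$outlier), 0)
})

test_that("cluster retention counts distinct participants", {
  feat <- list(features = matrix(rnorm(18), 6),
               subjects = c("A", "B", "C", "D", "E", "E"),
               component = 1:6, dipoles = matrix(0, 6, 3),
               residual_variance = runif(6))
  cl <- kmeans_cluster(feat, k = 1, seed = 1)
  expect_true(retain_clusters(cl, 5)$retained[1])   # 5 distinct of 6 members
  cl$subjects <- c("A", "B", "C", "D", "D", "D")    # only 4 distinct
  expect_warning(r2 <- retain_clusters(cl, 5), "no cluster")
  expect_false(r2$retained[1])
})

test_that("representative selection applies the residual-variance rule", {
  feat <- list(features = matrix(0, 5, 2) + rnorm(10, 0, 0.1),
               subjects = c("A", "A", "B", "B", "B"),
               component = c(1, 2, 1, 2, 3),
               dipoles = matrix(0, 5, 3),
               residual_variance = c(0.05, 0.08, 0.10, 0.10, 0.30))
  cl <- kmeans_cluster(feat, k = 1, seed = 1)
  cl$retained <- TRUE
  # A: lowest RV (0.05) is suspect -> the 0.08 brain component wins
  sel <- select_representative(cl, profiles = c("suspect", "brain", "brain",
                                                "brain", "brain"))
  expect_true(sel$selected[2] && !sel$selected[1])
  # B: tie on RV (0.10, 0.10) -> lower component index wins
  expect_true(sel$selected[3] && !sel$selected[4])
  expect_equal(sel$n_removed, 3L)
  # all suspect: lowest RV kept but flagged
  sel2 <- select_representative(cl, profiles = rep("suspect", 5))
  expect_true(sel2$selected[1] && sel2$flagged_suspect[1])
})

test_that("cluster table aggregates members and conserves counts", {
  feat <- list(features = rbind(matrix(rnorm(8, 0, 0.1), 4),
                                matrix(rnorm(8, 10, 0.1), 4)),
               subjects = paste0("S", c(1:4, 1:4)),
               component = c(1:4, 5:8),
               dipoles = rbind(matrix(0, 4, 3),
                               rbind(c(0, 0, 0), c(2, 2, 2), c(1, 1, 1), c(1, 1, 1))),
               residual_variance = runif(8))
  cl <- kmeans_cluster(feat, k = 2, seed = 1)
  cl <- retain_clusters(cl, 4)
  tb <- cluster_table(cl)
  expect_equal(sum(tb$n_components), 8)
  expect_equal(tb$n_participants, c(4, 4))
  row2 <- tb[which.max(tb$x), ]
  expect_equal(unlist(row2[c("x", "y", "z")], use.names = FALSE), c(1, 1, 1))
})

test_that("planted clusters are recovered under the full rule set", {
  set.seed(123)
  scs <- simulate_component_sets()
  feat <- assemble_features(scs$components, 256)
  cl <- kmeans_cluster(feat, k = 14, seed = 1)
  cl <- mark_outliers(cl, 3)
  cl <- retain_clusters(cl, 5)
  tb <- cluster_table(cl)
  tr <- scs$truth$locations
  dmin <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt(rowSums((as.matrix(tb[, c("x", "y", "z")]) -
                        matrix(tr[i, ], nrow(tb), 3, byrow = TRUE))^2))), 0)
  expect_equal(nrow(tb), 6)                    # all six true clusters
  expect_lt(max(dmin), 10)                     # centroids within 10 mm
  dsm <- min(sqrt(rowSums((as.matrix(tb[, c("x", "y", "z")]) -
                             matrix(scs$truth$small_location, nrow(tb), 3,
                                    byrow = TRUE))^2)))
  expect_gt(dsm, 20)                           # 4-subject cluster discarded

  # conservation: every component is assigned, outlier, or in no retained set
  n <- length(cl$assignment)
  expect_equal(sum(!is.na(cl$assignment)) + sum(cl$outlier), n)
})
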