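test_that("area and SNV normalization satisfy their defining identities", {
  ax <- fingerprint_axis(2)
  ones <- spectrum_set(matrix(1, 2, length(ax)), ax, c("a", "b"))
  w <- diff(range(ax))
  area <- normalize_spectra(ones, "area")
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(ax))
  # unit integral over the axis (trapezoidal rule)
  expect_equal(unname(apply(area$spectra, 1, trapz)), rep(1, 2),
               tolerance = 1e-9)
  expect_equal(area$spectra[1, 1], 1 / w, tolerance = 1e-9)
  # SNV is idempotent
  set.seed(2)
  x <- spectrum_set(matrix(rnorm(5 * length(ax), 10), 5), ax, letters[1:5])
  s1 <- normalize_spectra(x, "snv")
  s2 <- normalize_spectra(s1, "snv")
  expect_equal(s1$spectra, s2$spectra, tolerance = 1e-12)
  expect_equal(unname(rowMeans(s1$spectra)), rep(0, 5), tolerance = 1e-12)
  # area normalization is scale-invariant
  x7 <- spectrum_set(7 * abs(x$spectra), ax, x$labels)
  expect_equal(normalize_spectra(x7, "area")$spectra,
               normalize_spectra(spectrum_set(abs(x$spectra), ax, x$labels),
                                 "area")$spectra,
               tolerance = 1e-12)
  # all-zero rows are rejected by name
  bad <- spectrum_set(rbind(x$spectra[1, ], 0), ax, c("a", "b"))
  expect_error(normalize_spectra(bad, "area"), "2")
  expect_error(normalize_spectra(bad, "snv"), "2")
  expect_identical(normalize_spectra(bad, "none"), bad)
})

test_that("PCA models are orthonormal, variance-ordered and reconstructive", {
  set <- make_class_spectra(c("EV", "LDL", "VLDL"), n_per = 20, seed = 3)
  k <- 10
  m <- fit_pca(set, n_components = k)
  g <- m$loadings %*% t(m$loadings)
  expect_equal(g, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(colMeans(m$scores)), rep(0, k), tolerance = 1e-8)
  expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
  # full-rank reconstruction of the centred data
  full <- fit_pca(set, n_components = nrow(set$spectra) - 1)
  rec <- full$scores %*% full$loadings
  centred <- sweep(set$spectra, 2, full$mean)
  expect_lt(max(abs(rec - centred)), 1e-6)
})

test_that("degenerate zero-variance input yields zero scores and ratios", {
  ax <- fingerprint_axis(8)
  same <- spectrum_set(matrix(5, 6, length(ax)), ax, rep(c("a", "b"), 3))
  m <- fit_pca(same, 2)
  expect_true(all(m$scores == 0))
  expect_equal(m$explained_variance_ratio, c(0, 0))
})

test_that("a two-class difference at 1438 cm^-1 is captured by the PC1 loading", {
  ax <- fingerprint_axis(2)
  set.seed(6)
  base <- 2 + 0.5 * sin(ax / 200)
  bump <- exp(-0.5 * ((ax - 1438) / 7)^2)
  x <- rbind(
    t(replicate(25, base + rnorm(length(ax), 0, 0.01))),
    t(replicate(25, base + bump + rnorm(length(ax), 0, 0.01))))
  set <- spectrum_set(x, ax, rep(c("a", "b"), each = 25))
  m <- fit_pca(set, 2)
  peak <- ax[which.max(abs(m$loadings[1, ]))]
  expect_lte(abs(peak - 1438), 6)
  # cross-check the loading against the covariance eigen-decomposition
  ev1 <- eigen(stats::cov(x), symmetric = TRUE)$vectors[, 1]
  ev1 <- ev1 * sign(ev1[which.max(abs(ev1))])
  expect_equal(abs(sum(ev1 * m$loadings[1, ])), 1, tolerance = 1e-6)
})

test_that("loading annotation matches peaks to band assignments within tolerance", {
  ax <- default_axis(600, 3100, 2)
  chol <- make_component_spectrum("cholesterol",
                                  default_band_tables()$cholesterol, ax)
  fake <- structure(list(loadings = matrix(chol$intensity, 1), axis = ax),
                    class = "pca_model")
  ann <- annotate_loading(fake, 1, band_assignment_table(), tolerance = 6)
  hit <- ann$peak_wavenumber[!is.na(ann$component) &
                               ann$component == "cholesterol"]
  for (center in c(698, 1438, 2850, 2866, 2888, 2932)) {
    expect_true(any(abs(hit - center) <= 6),
                label = sprintf("cholesterol line %d annotated", center))
  }
  # empty band table: all peaks unmatched
  empty <- band_assignment_table()[0, ]
  ann0 <- annotate_loading(fake, 1, empty, tolerance = 6)
  expect_true(all(is.na(ann0$component)))
  expect_gt(nrow(ann0), 0)
  # a peak beyond the tolerance stays unmatched
  ax2 <- fingerprint_axis(1)
  lone <- structure(list(
    loadings = matrix(exp(-0.5 * ((ax2 - (1438 + 7)) / 5)^2), 1),
    axis = ax2), class = "pca_model")
  tab1 <- data.frame(wavenumber = 1438, component = "cholesterol",
                     assignment = "test")
  ann2 <- annotate_loading(lone, 1, tab1, tolerance = 6)
  expect_true(all(is.na(ann2$component)))
  expect_error(annotate_loading(fake, 5), "out of range")
})

test_that("cluster separation reports centroid distances, silhouettes and quadrants", {
  scores <- rbind(matrix(rep(c(-1, 0), each = 20), 20),
                  matrix(rep(c(1, 0), each = 20), 20))
  fake <- structure(list(scores = scores,
                         labels = rep(c("a", "b"), each = 20)),
                    class = "pca_model")
  sep <- cluster_separation(fake)
  expect_equal(sep$pairs$centroid_distance, 2)
  expect_equal(sep$pairs$silhouette, 1, tolerance = 1e-9)
  expect_false(sep$pairs$flag)
  expect_equal(sep$quadrants$nn[sep$quadrants$label == "a"], 1)
  # single label errors; singleton label flagged with NA silhouette
  one <- fake; one$labels <- rep("a", 40)
  expect_error(cluster_separation(one), "2 distinct")
  lone <- fake; lone$labels <- c(rep("a", 39), "b")
  sep2 <- cluster_separation(lone)
  expect_true(sep2$pairs$flag)
  expect_true(is.na(sep2$pairs$silhouette))
})

test_that("nearest-centroid classification is accurate on separated classes", {
  set.seed(8)
  cent <- rbind(c(0, 0), c(10, 0), c(0, 10))
  labs <- c("a", "b", "c")
  # reference points placed symmetrically so class centroids are exact
  ref <- do.call(rbind, lapply(1:3, function(k) {
    rbind(cent[k, ] + c(1, 1), cent[k, ] - c(1, 1))
  }))
  fake <- structure(list(scores = ref, labels = rep(labs, each = 2)),
                    class = "pca_model")
  # reference events at a centroid get that label with top confidence
  at_cent <- classify_events(fake, cent)
  expect_equal(at_cent$label, labs)
  expect_true(all(at_cent$confidence > 1 / 3))
  # accuracy on fresh draws from well-separated classes
  new <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(100, 0, 1), 50, 2), 2, cent[k, ], `+`)
  }))
  pred <- classify_events(fake, new)
  expect_gte(mean(pred$label == rep(labs, each = 50)), 0.95)
  # equidistant point breaks ties to the lexicographically first label
  mid2 <- classify_events(fake, matrix(c(5, 0), 1))
  expect_equal(mid2$label, "a")
  expect_lt(mid2$confidence, 0.6)
  expect_error(classify_events(fake, matrix(1, 1, 1)), "2 score")
})

test_that("SNV makes separation statistics invariant to global intensity scaling", {
  set <- make_class_spectra(c("EV", "LDL"), n_per = 25, seed = 10)
  scaled <- spectrum_set(3.7 * set$spectra, set$axis, set$labels)
  m1 <- fit_pca(normalize_spectra(set, "snv"), 2)
  m2 <- fit_pca(normalize_spectra(scaled, "snv"), 2)
  s1 <- cluster_separation(m1)
  s2 <- cluster_separation(m2)
  expect_equal(s1$pairs$centroid_distance, s2$pairs$centroid_distance,
               tolerance = 1e-9)
  expect_equal(s1$pairs$silhouette, s2$pairs$silhouette, tolerance = 1e-9)
})
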