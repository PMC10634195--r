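#' Spectral analysis of trapping-event spectra
#'
#' Normalization, principal component analysis, chemical annotation of
#' loading peaks, and cluster-separation statistics over labelled event
#' spectra.
#'
#' @name spectral-analysis
NULL

#' Construct a labelled spectrum set
#'
#' @param spectra Matrix, events in rows, wavenumbers in columns; no
#'   missing values.
#' @param axis Wavenumber grid (cm^-1) matching the columns.
#' @param labels Sample-type label per event (e.g. `"LDL"`, `"EV"`,
#'   `"EV+LDL"`).
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, axis, labels) {
  spectra <- as.matrix(spectra)
  if (anyNA(spectra)) stop("spectra must not contain missing values")
  if (ncol(spectra) != length(axis)) stop("axis length must match columns")
  if (nrow(spectra) != length(labels)) stop("one label per spectrum required")
  structure(list(spectra = spectra, axis = axis,
                 labels = as.character(labels)),
            class = "spectrum_set")
}

#' Restrict a spectrum set to a wavenumber region
#'
#' The fingerprint region (600-1800 cm^-1) is the default analysis window;
#' the high-frequency CH-stretch region (2800-3050 cm^-1) can be analysed
#' separately.
#'
#' @param set A [spectrum_set()].
#' @param region `c(lo, hi)` in cm^-1.
#' @return A new `spectrum_set` on the restricted axis.
#' @export
restrict_region <- function(set, region = c(600, 1800)) {
  sel <- set$axis >= region[1] & set$axis <= region[2]
  if (!any(sel)) stop("region contains no wavenumber samples")
  spectrum_set(set$spectra[, sel, drop = FALSE], set$axis[sel], set$labels)
}

#' Normalize event spectra
#'
#' * `"area"`: each spectrum is scaled to unit integral over the axis
#'   (trapezoidal rule).
#' * `"snv"`: standard normal variate, each spectrum centred to mean 0 and
#'   scaled to sd 1.
#' * `"none"`: returned unchanged.
#'
#' @param set A [spectrum_set()].
#' @param method `"area"`, `"snv"` or `"none"`.
#' @return A normalized `spectrum_set`.
#' @export
normalize_spectra <- function(set, method = c("area", "snv", "none")) {
  method <- match.arg(method)
  if (method == "none") return(set)
  x <- set$spectra
  if (method == "area") {
    w <- trapz_weights(set$axis)
    areas <- as.vector(x %*% w)
    bad <- which(abs(areas) < .Machine$double.eps)
    if (length(bad) > 0) {
      stop("cannot area-normalize all-zero spectrum row(s): ",
           paste(bad, collapse = ", "))
    }
    x <- x / areas
  } else {
    sds <- apply(x, 1, stats::sd)
    bad <- which(sds == 0)
    if (length(bad) > 0) {
      stop("cannot SNV-normalize constant spectrum row(s): ",
           paste(bad, collapse = ", "))
    }
    x <- (x - rowMeans(x)) / sds
  }
  spectrum_set(x, set$axis, set$labels)
}

# Trapezoidal quadrature weights on a (possibly non-uniform) grid.
trapz_weights <- function(axis) {
  n <- length(axis)
  d <- diff(axis)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Principal component analysis of a spectrum set
#'
#' Column-centred PCA (no scaling). Loading signs are canonicalized so the
#' largest-magnitude element of each loading is positive (PCA signs are
#' otherwise arbitrary). Degenerate zero-variance input yields zero scores
#' and zero explained-variance ratios.
#'
#' @param set A [spectrum_set()].
#' @param n_components Number of components to retain,
#'   `1 <= n_components <= nrow - 1`.
#' @return List of class `pca_model`: `mean` (mean spectrum), `loadings`
#'   (components x wavenumbers), `scores` (events x components),
#'   `explained_variance_ratio`, `axis`, `labels`.
#' @export
fit_pca <- function(set, n_components = 2L) {
  x <- set$spectra
  stopifnot(n_components >= 1, nrow(x) >= n_components)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  total_var <- sum(xc^2) / (nrow(x) - 1)
  k <- min(n_components, nrow(x) - 1, ncol(x))
  if (total_var <= 1e-300) {
    load <- matrix(0, k, ncol(x))
    load[cbind(seq_len(k), seq_len(k))] <- 1
    return(structure(list(
      mean = mu, loadings = load,
      scores = matrix(0, nrow(x), k),
      explained_variance_ratio = rep(0, k),
      axis = set$axis, labels = set$labels), class = "pca_model"))
  }
  sv <- svd(xc, nu = k, nv = k)
  loadings <- t(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  # canonical signs: largest |loading| element positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[j, ]))
    if (loadings[j, i_max] < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- sv$d^2 / sum(sv$d^2)
  structure(list(mean = mu, loadings = loadings, scores = scores,
                 explained_variance_ratio = evr[seq_len(k)],
                 axis = set$axis, labels = set$labels),
            class = "pca_model")
}

#' Project spectra onto a fitted PCA model
#'
#' @param model A `pca_model`.
#' @param spectra Matrix on the model's axis.
#' @return Score matrix (rows x components).
#' @export
project_pca <- function(model, spectra) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(model$mean)) stop("axis dimension mismatch")
  sweep(spectra, 2, model$mean) %*% t(model$loadings)
}

#' Orient principal components by class centroids
#'
#' Flips the sign of chosen components (loadings and scores) so that the
#' named label's centroid score is positive. Useful for presenting scores
#' in a fixed orientation, since PCA signs are arbitrary.
#'
#' @param model A `pca_model` carrying labels.
#' @param positive_label Label whose centroid should be positive.
#' @param components Which components to orient.
#' @return The re-oriented `pca_model`.
#' @export
orient_pca <- function(model, positive_label, components = 1L) {
  sel <- model$labels == positive_label
  if (!any(sel)) stop("label not present: ", positive_label)
  for (j in components) {
    if (mean(model$scores[sel, j]) < 0) {
      model$scores[, j] <- -model$scores[, j]
      model$loadings[j, ] <- -model$loadings[j, ]
    }
  }
  model
}

#' Annotate the peaks of a PCA loading with chemical band assignments
#'
#' Local extrema of the loading with magnitude at least
#' `rel_threshold * max(|loading|)` are located and matched to the nearest
#' band-table entry within `tolerance`; unmatched peaks are reported with
#' an `NA` assignment.
#'
#' @param model A `pca_model`.
#' @param component_index Which loading to annotate.
#' @param table Band table from [band_assignment_table()].
#' @param tolerance Match tolerance in cm^-1, > 0.
#' @param rel_threshold Peak amplitude threshold relative to the loading
#'   maximum magnitude.
#' @return A `data.frame` with `peak_wavenumber`, `loading_value`, `sign`,
#'   `component`, `assignment`, `distance` (cm^-1; `NA` when unmatched).
#' @export
annotate_loading <- function(model, component_index = 1L,
                             table = band_assignment_table(),
                             tolerance = 6, rel_threshold = 0.3) {
  stopifnot(tolerance > 0)
  if (component_index < 1 || component_index > nrow(model$loadings)) {
    stop("component_index out of range")
  }
  v <- model$loadings[component_index, ]
  axis <- model$axis
  n <- length(v)
  amp <- abs(v)
  thr <- rel_threshold * max(amp)
  is_peak <- vapply(seq_len(n), function(i) {
    if (amp[i] < thr) return(FALSE)
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    # local extremum of the signed loading in its own direction
    if (v[i] > 0) v[i] >= max(v[lo:hi]) else v[i] <= min(v[lo:hi])
  }, logical(1))
  peaks <- which(is_peak)
  # collapse flat-top runs
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) == 0) {
    return(data.frame(peak_wavenumber = numeric(0),
                      loading_value = numeric(0), sign = integer(0),
                      component = character(0), assignment = character(0),
                      distance = numeric(0)))
  }
  out <- lapply(peaks, function(i) {
    d <- abs(table$wavenumber - axis[i])
    j <- if (nrow(table) > 0) which.min(d) else integer(0)
    matched <- length(j) == 1 && d[j] <= tolerance
    data.frame(
      peak_wavenumber = axis[i], loading_value = v[i],
      sign = as.integer(sign(v[i])),
      component = if (matched) table$component[j] else NA_character_,
      assignment = if (matched) table$assignment[j] else NA_character_,
      distance = if (matched) d[j] else NA_real_)
  })
  do.call(rbind, out)
}

#' Cluster separation statistics in score space
#'
#' For every pair of labels: Euclidean centroid distance and mean
#' silhouette width on the first two principal components. Additionally,
#' per label, the fraction of events in each PC1/PC2 sign quadrant.
#' Labels with fewer than 2 events are flagged and get `NA` silhouettes.
#'
#' @param model A `pca_model` with at least 2 components.
#' @param labels Optional label vector overriding the model's labels.
#' @return List with `pairs` (label_a, label_b, centroid_distance,
#'   silhouette, flag), `quadrants` (label, fraction per sign quadrant of
#'   PC1/PC2), `centroids`.
#' @export
cluster_separation <- function(model, labels = model$labels) {
  if (ncol(model$scores) < 2) stop("need at least 2 components")
  s <- model$scores[, 1:2, drop = FALSE]
  labs <- unique(labels)
  if (length(labs) < 2) stop("need at least 2 distinct labels")
  cent <- t(vapply(labs, function(l) colMeans(s[labels == l, , drop = FALSE]),
                   numeric(2)))
  rownames(cent) <- labs
  counts <- table(labels)[labs]
  pairs <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (j <= i) next
    sel <- labels %in% c(labs[i], labs[j])
    small <- counts[i] < 2 || counts[j] < 2
    sil <- if (small) NA_real_ else {
      sub <- s[sel, , drop = FALSE]
      cl <- as.integer(factor(labels[sel], levels = c(labs[i], labs[j])))
      mean(cluster::silhouette(cl, stats::dist(sub))[, "sil_width"])
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      label_a = labs[i], label_b = labs[j],
      centroid_distance = sqrt(sum((cent[i, ] - cent[j, ])^2)),
      silhouette = sil, flag = small)
  }
  quad <- do.call(rbind, lapply(labs, function(l) {
    ss <- s[labels == l, , drop = FALSE]
    data.frame(label = l,
               pp = mean(ss[, 1] > 0 & ss[, 2] > 0),
               pn = mean(ss[, 1] > 0 & ss[, 2] <= 0),
               np = mean(ss[, 1] <= 0 & ss[, 2] > 0),
               nn = mean(ss[, 1] <= 0 & ss[, 2] <= 0))
  }))
  list(pairs = do.call(rbind, pairs), quadrants = quad, centroids = cent)
}

#' Nearest-centroid classification in PC space
#'
#' Classifies new scores to the nearest reference-label centroid on the
#' first two principal components. Confidence is a softmin over centroid
#' distances; exact distance ties break to the lexicographically first
#' label (with correspondingly split confidence).
#'
#' @param model A `pca_model` fitted on the reference set.
#' @param reference_labels Labels of the reference events (default the
#'   model's labels).
#' @param new_scores Matrix of scores to classify (>= 2 columns, same
#'   score space); e.g. from [project_pca()].
#' @return A `data.frame` with `label` and `confidence`.
#' @export
classify_events <- function(model, new_scores,
                            reference_labels = model$labels) {
  new_scores <- as.matrix(new_scores)
  if (ncol(new_scores) < 2 || ncol(model$scores) < 2) {
    stop("need at least 2 score dimensions")
  }
  s <- model$scores[, 1:2, drop = FALSE]
  x <- new_scores[, 1:2, drop = FALSE]
  labs <- sort(unique(reference_labels))
  cent <- t(vapply(labs, function(l) {
    colMeans(s[reference_labels == l, , drop = FALSE])
  }, numeric(2)))
  d <- vapply(seq_along(labs), function(k) {
    sqrt(rowSums(sweep(x, 2, cent[k, ])^2))
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  # softmin confidence, scaled by the mean inter-centroid distance
  scale <- mean(stats::dist(cent))
  w <- exp(-d / max(scale, .Machine$double.eps))
  conf <- w / rowSums(w)
  best <- apply(d, 1, function(r) which(r == min(r))[1])  # lexicographic tie
  data.frame(label = labs[best],
             confidence = conf[cbind(seq_len(nrow(x)), best)])
}
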