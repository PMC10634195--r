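#' Spherical-cap morphometry of surface-adsorbed particles
#'
#' A soft particle adsorbed on a substrate assumes a spherical-cap shape
#' described by its height above the substrate `h` and its contact (base)
#' radius `a`. Two derived quantities characterize the particle:
#'
#' * the contact angle `CA = 2 atan(h / a)` (degrees), a proxy for
#'   mechanical stiffness, and
#' * the equivalent solution diameter `D_eq`, the diameter of the free
#'   sphere with the same membrane area as the adsorbed cap. The membrane
#'   covers the curved cap surface `pi (h^2 + a^2)` plus the adhered
#'   contact disc `pi a^2`, so `D_eq = sqrt(h^2 + 2 a^2)`.
#'
#' Area conservation (rather than volume conservation) reflects the
#' near-inextensible lipid envelope of vesicles; it is applied uniformly to
#' lipoprotein-like particles as well so that all particles live in one
#' consistent (D_eq, CA) coordinate system.
#'
#' @name afm-morphometry
NULL

#' Contact angle of a spherical cap
#'
#' @param h Cap height above the substrate (nm), > 0.
#' @param a Contact (base) radius (nm), >= 0. `a = 0` is the unperturbed
#'   full-sphere limit and returns 180 degrees.
#' @return Contact angle in degrees, in (0, 180].
#' @examples
#' contact_angle(50, 50)   # hemisphere: 90 degrees
#' contact_angle(50, 0)    # free sphere: 180 degrees
#' @export
contact_angle <- function(h, a) {
  if (any(h <= 0)) stop("cap height h must be > 0")
  if (any(a < 0)) stop("contact radius a must be >= 0")
  ifelse(a == 0, 180, 2 * atan(h / a) * 180 / pi)
}

#' Equivalent solution diameter of a spherical cap
#'
#' Membrane area `A = pi (h^2 + a^2) + pi a^2`; `D_eq = sqrt(A / pi)`.
#'
#' @inheritParams contact_angle
#' @return Equivalent solution diameter in nm.
#' @examples
#' equivalent_diameter(50, 50)  # hemisphere, sqrt(7500) ~ 86.6 nm
#' equivalent_diameter(80, 0)   # free sphere of diameter 80 nm
#' @export
equivalent_diameter <- function(h, a) {
  if (any(h <= 0)) stop("cap height h must be > 0")
  if (any(a < 0)) stop("contact radius a must be >= 0")
  sqrt(h^2 + 2 * a^2)
}

#' Forward-project (D_eq, CA) to cap measurements
#'
#' Inverse of [contact_angle()] / [equivalent_diameter()]: given the
#' equivalent solution diameter and contact angle, returns the cap height
#' and contact radius that reproduce them. With `t = tan(CA/2)`,
#' `a = D_eq / sqrt(2 + t^2)` and `h = a t`; `CA = 180` is handled as the
#' `a = 0` limit with `h = D_eq`.
#'
#' @param D_eq Equivalent solution diameter (nm), > 0.
#' @param CA Contact angle (degrees), in (0, 180].
#' @return A `data.frame` with columns `h`, `a` (nm).
#' @export
forward_project <- function(D_eq, CA) {
  if (any(D_eq <= 0)) stop("D_eq must be > 0")
  if (any(CA <= 0 | CA > 180)) stop("CA must lie in (0, 180]")
  n <- max(length(D_eq), length(CA))
  D_eq <- rep_len(D_eq, n); CA <- rep_len(CA, n)
  t <- tan(CA / 2 * pi / 180)
  full <- CA == 180
  a <- ifelse(full, 0, D_eq / sqrt(2 + t^2))
  h <- ifelse(full, D_eq, a * t)
  data.frame(h = h, a = a)
}

#' Morphometry of a cap-measurement table
#'
#' @param caps A `data.frame` with columns `h` and `a` (nm) and optionally
#'   `cluster_flag` (logical) and `particle_id`.
#' @return The input with `D_eq` (nm) and `CA` (degrees) columns appended.
#' @export
cap_morphometry <- function(caps) {
  stopifnot(all(c("h", "a") %in% names(caps)))
  caps$D_eq <- equivalent_diameter(caps$h, caps$a)
  caps$CA <- contact_angle(caps$h, caps$a)
  caps
}

#' Default morphometry priors for the LDL and EV populations
#'
#' LDL: D_eq 17 +/- 3 nm, CA 71 +/- 8 degrees. EV: CA 97 +/- 12 degrees
#' with broadly dispersed diameters (~30-130 nm).
#'
#' @return Named list of per-class priors (`ca_mean`, `ca_sd`, `deq_mean`,
#'   `deq_sd`, `weight`).
#' @export
default_morphometry_priors <- function() {
  list(
    LDL = list(ca_mean = 71, ca_sd = 8, deq_mean = 17, deq_sd = 3,
               weight = 0.5),
    EV  = list(ca_mean = 97, ca_sd = 12, deq_mean = 80, deq_sd = 30,
               weight = 0.5)
  )
}

# Lognormal parameters matched to an arithmetic mean and sd.
lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Classify particles from morphometry
#'
#' Two-component Gaussian responsibility model on (CA, log D_eq): each
#' class contributes an independent Gaussian on CA and a lognormal on
#' D_eq, with class weights taken from the priors. Particles get the
#' maximum-responsibility hard label; exact ties are `"unassigned"`, and a
#' `cluster_flag` column overrides the label to `"cluster"`.
#'
#' @param morph A `data.frame` with columns `D_eq` and `CA` (see
#'   [cap_morphometry()]); optional logical `cluster_flag`.
#' @param priors Named list of class priors as in
#'   [default_morphometry_priors()].
#' @return List with `particles` (input plus `class` and per-class
#'   responsibility columns) and `summary` (per-class n, fraction, mean and
#'   sd of D_eq and CA).
#' @export
classify_particles <- function(morph, priors = default_morphometry_priors()) {
  if (nrow(morph) == 0) {
    return(list(particles = morph,
                summary = data.frame(class = character(0), n = integer(0),
                                     fraction = numeric(0))))
  }
  stopifnot(all(c("D_eq", "CA") %in% names(morph)))
  classes <- names(priors)
  w <- vapply(priors, function(p) p$weight %||% 1, numeric(1))
  w <- w / sum(w)
  dens <- sapply(seq_along(classes), function(k) {
    p <- priors[[k]]
    lp <- lnorm_pars(p$deq_mean, p$deq_sd)
    w[k] *
      stats::dnorm(morph$CA, p$ca_mean, p$ca_sd) *
      stats::dlnorm(morph$D_eq, lp$meanlog, lp$sdlog)
  })
  dens <- matrix(dens, nrow = nrow(morph))
  tot <- rowSums(dens)
  resp <- dens / ifelse(tot > 0, tot, 1)
  colnames(resp) <- classes
  best <- max.col(resp, ties.method = "first")
  label <- classes[best]
  # exact responsibility ties (or all-zero density) are left unassigned
  tied <- apply(resp, 1, function(r) sum(r == max(r)) > 1)
  label[tied | tot == 0] <- "unassigned"
  if (!is.null(morph$cluster_flag)) {
    label[as.logical(morph$cluster_flag)] <- "cluster"
  }
  out <- cbind(morph, class = label, as.data.frame(resp))
  agg <- lapply(split(out, out$class), function(d) {
    data.frame(class = d$class[1], n = nrow(d),
               fraction = nrow(d) / nrow(out),
               D_eq_mean = mean(d$D_eq), D_eq_sd = stats::sd(d$D_eq),
               CA_mean = mean(d$CA), CA_sd = stats::sd(d$CA))
  })
  list(particles = out, summary = do.call(rbind, unname(agg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
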