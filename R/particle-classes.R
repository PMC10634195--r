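#' Particle class specifications
#'
#' A particle class bundles everything the synthetic generators need to
#' emulate one population: Raman composition weights, a solution-diameter
#' distribution, a buoyant-density distribution, an adsorbed-cap contact
#' angle distribution, and an optical-trap Rayleigh step height.
#'
#' @param label Class label, e.g. `"LDL"`, `"EV"`, `"EV-LDL"`.
#' @param composition Named weights (component name -> weight >= 0,
#'   sum > 0) over the component spectra.
#' @param size_mean,size_sd Solution diameter distribution, nm (truncated
#'   Gaussian, > 0). For classes with `size_range` set, diameters are drawn
#'   uniformly over that range instead.
#' @param size_range Optional `c(min, max)` nm for uniform diameter draws.
#' @param density_mean,density_sd Buoyant density, g/cm^3, truncated to
#'   \[1.00, 1.30\].
#' @param ca_mean,ca_sd Contact angle of the adsorbed spherical cap,
#'   degrees, truncated to (0, 180).
#' @param deq_mean,deq_sd Equivalent solution diameter of the adsorbed
#'   particle, nm (may differ from the free-solution TEM size).
#' @param trap_step_mean,trap_step_sd Rayleigh step height on trapping,
#'   arbitrary units.
#' @param erf_per_nm2 Mean fluorescence yield per nm^2 of particle surface,
#'   ERF units, used by the flow-cytometry generator.
#' @return An object of class `particle_class_spec`.
#' @export
particle_class_spec <- function(label, composition,
                                size_mean, size_sd, size_range = NULL,
                                density_mean, density_sd,
                                ca_mean = NA_real_, ca_sd = NA_real_,
                                deq_mean = NA_real_, deq_sd = NA_real_,
                                trap_step_mean = 10, trap_step_sd = 1,
                                erf_per_nm2 = 0.04) {
  if (sum(composition) <= 0) stop("composition weights must sum > 0")
  if (is.null(size_range) && size_mean <= 0) stop("size_mean must be > 0")
  if (density_mean < 1.00 || density_mean > 1.30) {
    stop("density_mean must lie within 1.00-1.30 g/cm^3")
  }
  structure(
    list(label = label, composition = composition,
         size_mean = size_mean, size_sd = size_sd, size_range = size_range,
         density_mean = density_mean, density_sd = density_sd,
         ca_mean = ca_mean, ca_sd = ca_sd,
         deq_mean = deq_mean, deq_sd = deq_sd,
         trap_step_mean = trap_step_mean, trap_step_sd = trap_step_sd,
         erf_per_nm2 = erf_per_nm2),
    class = "particle_class_spec"
  )
}

#' Built-in particle classes
#'
#' Population parameters follow the single-particle literature on EV/LPP
#' mixtures: TEM solution diameters CM 148.2 +/- 91 nm, VLDL 63.5 +/- 24 nm,
#' LDL 25.3 +/- 3.4 nm; AFM morphometry LDL D_eq 17 +/- 3 nm with contact
#' angle 71 +/- 8 degrees, EVs 30-130 nm with contact angle 97 +/- 12
#' degrees; LPPs band in the 1.06-1.10 g/cm^3 density window and EVs in
#' 1.12-1.16 g/cm^3. The EV-LDL complex class mixes the EV and LDL Raman
#' compositions 50:50 and floats at LPP-like densities.
#'
#' Compositionally, EVs are cholesterol- and protein-rich while LDL is
#' triglyceride-rich, which is what drives their separation along the first
#' principal component of the event spectra.
#'
#' @return Named list of [particle_class_spec()] objects:
#'   `LDL`, `VLDL`, `CM`, `EV`, `EV-LDL`.
#' @export
default_particle_classes <- function() {
  ev_comp  <- c(cholesterol = 1.0, protein = 0.8, phospholipid = 0.6,
                triglyceride = 0.15)
  ldl_comp <- c(triglyceride = 1.0, cholesterol = 0.35, protein = 0.25,
                phospholipid = 0.25)
  comps <- union(names(ev_comp), names(ldl_comp))
  pad <- function(x) {
    y <- stats::setNames(rep(0, length(comps)), comps)
    y[names(x)] <- x
    y
  }
  list(
    "LDL" = particle_class_spec(
      "LDL", ldl_comp,
      size_mean = 25.3, size_sd = 3.4,
      density_mean = 1.055, density_sd = 0.012,
      ca_mean = 71, ca_sd = 8, deq_mean = 17, deq_sd = 3,
      trap_step_mean = 8, trap_step_sd = 1, erf_per_nm2 = 0.04),
    "VLDL" = particle_class_spec(
      "VLDL", c(triglyceride = 1.0, cholesterol = 0.45, protein = 0.2,
                phospholipid = 0.25),
      size_mean = 63.5, size_sd = 24,
      density_mean = 1.035, density_sd = 0.012,
      trap_step_mean = 10, trap_step_sd = 1, erf_per_nm2 = 0.04),
    "CM" = particle_class_spec(
      "CM", c(triglyceride = 1.0, cholesterol = 0.3, protein = 0.15,
              phospholipid = 0.2),
      size_mean = 148.2, size_sd = 91,
      density_mean = 1.02, density_sd = 0.012,
      trap_step_mean = 14, trap_step_sd = 1.5, erf_per_nm2 = 0.04),
    "EV" = particle_class_spec(
      "EV", ev_comp,
      size_mean = 100, size_sd = 30, size_range = c(50, 200),
      density_mean = 1.14, density_sd = 0.012,
      ca_mean = 97, ca_sd = 12, deq_mean = 80, deq_sd = 25,
      trap_step_mean = 12, trap_step_sd = 1.2, erf_per_nm2 = 0.04),
    "EV-LDL" = particle_class_spec(
      # one EV plus a corona of adsorbed LDLs; the corona's summed Raman
      # weight is taken as twice the EV contribution
      "EV-LDL", (1 * pad(ev_comp) + 2 * pad(ldl_comp)) / 3,
      size_mean = 110, size_sd = 30,
      density_mean = 1.08, density_sd = 0.012,
      ca_mean = 97, ca_sd = 12, deq_mean = 85, deq_sd = 25,
      trap_step_mean = 13, trap_step_sd = 1.2, erf_per_nm2 = 0.04)
  )
}

#' Draw from a truncated Gaussian by rejection
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent Gaussian.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n` inside `(lower, upper)`.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      stop("degenerate distribution outside truncation bounds")
    }
    return(rep(mean, n))
  }
  p_in <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (p_in < 1e-12) {
    stop("truncation bounds exclude essentially all probability mass")
  }
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / p_in * 1.2) + 10
    x <- stats::rnorm(m, mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out[seq_len(n)]
}

#' Maximum-likelihood fit of a zero-truncated Gaussian
#'
#' Estimates the parent mean and sd of a Gaussian observed only above a
#' lower truncation bound. Used to recover generating population
#' parameters from broadly dispersed size populations (e.g. chylomicrons,
#' whose sd is comparable to the mean) where the naive sample mean is
#' biased upward by the truncation.
#'
#' @param x Observations, all > `lower`.
#' @param lower Truncation bound; default 0 (positive diameters).
#' @return List with `mean`, `sd` (parent-scale estimates),
#'   `se_mean` (asymptotic standard error of `mean`) and `convergence`.
#' @export
fit_truncnorm <- function(x, lower = 0) {
  stopifnot(all(x > lower), length(x) >= 10)
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    -sum(stats::dnorm(x, mu, sigma, log = TRUE)) +
      length(x) * stats::pnorm(lower, mu, sigma, lower.tail = FALSE,
                               log.p = TRUE)
  }
  start <- c(mean(x), log(stats::sd(x)))
  fit <- stats::optim(start, nll, method = "BFGS", hessian = TRUE)
  se <- tryCatch(sqrt(diag(solve(fit$hessian)))[1], error = function(e) NA_real_)
  list(mean = fit$par[1], sd = exp(fit$par[2]), se_mean = se,
       convergence = fit$convergence)
}

#' Draw solution diameters for a particle class
#'
#' Truncated-Gaussian draws (diameter > 0), or uniform draws when the class
#' declares a `size_range`.
#'
#' @param spec A [particle_class_spec()].
#' @param n Number of particles.
#' @return Numeric vector of diameters (nm), all > 0.
#' @export
draw_diameters <- function(spec, n) {
  if (!is.null(spec$size_range)) {
    stats::runif(n, spec$size_range[1], spec$size_range[2])
  } else {
    rtruncnorm(n, spec$size_mean, spec$size_sd, lower = 0)
  }
}
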