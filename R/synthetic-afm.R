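#' Synthetic AFM particle fields
#'
#' Draws per-particle morphometry ground truth (equivalent solution
#' diameter and contact angle) from class populations, forward-projects
#' each particle to the cap measurements (height `h`, contact radius `a`)
#' an AFM image analysis would report, and optionally perturbs the
#' measurements with additive Gaussian noise.
#'
#' @param populations Named list of per-class population parameters, each a
#'   list with `deq_mean`, `deq_sd` (nm; or `deq_range = c(min, max)` for a
#'   uniform diameter population), `ca_mean`, `ca_sd` (degrees) and
#'   `fraction` (mixing fraction; fractions must sum to 1).
#' @param n Total number of particles, >= 1.
#' @param noise_sd Gaussian measurement noise sd added to `h` and `a`, nm.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `particle_id`, `h`, `a`,
#'   `cluster_flag` (all `FALSE`; proximity flagging is an upstream image
#'   analysis concern), plus ground truth `true_class`, `true_D_eq`,
#'   `true_CA`.
#' @examples
#' pops <- afm_population_defaults()
#' tab <- generate_afm_particles(pops, n = 100, seed = 7)
#' @export
generate_afm_particles <- function(populations, n, noise_sd = 0, seed = 1L) {
  stopifnot(n >= 1)
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("population fractions must sum to 1")
  set.seed(substream_seed(seed, "afm"))
  cls <- sample(names(populations), n, replace = TRUE, prob = fr)
  D_eq <- numeric(n); CA <- numeric(n)
  for (nm in names(populations)) {
    p <- populations[[nm]]
    sel <- cls == nm
    if (!any(sel)) next
    D_eq[sel] <- if (!is.null(p$deq_range)) {
      stats::runif(sum(sel), p$deq_range[1], p$deq_range[2])
    } else {
      rtruncnorm(sum(sel), p$deq_mean, p$deq_sd, lower = 0)
    }
    CA[sel] <- rtruncnorm(sum(sel), p$ca_mean, p$ca_sd,
                          lower = 0, upper = 180)
  }
  caps <- forward_project(D_eq, CA)
  if (noise_sd > 0) {
    caps$h <- pmax(caps$h + stats::rnorm(n, 0, noise_sd), 1e-6)
    caps$a <- pmax(caps$a + stats::rnorm(n, 0, noise_sd), 0)
  }
  data.frame(particle_id = seq_len(n), h = caps$h, a = caps$a,
             cluster_flag = FALSE, true_class = cls,
             true_D_eq = D_eq, true_CA = CA)
}

#' Default AFM populations for an LDL/EV particle field
#'
#' LDL: D_eq 17 +/- 3 nm, CA 71 +/- 8 degrees; EV: diameters dispersed over
#' 30-130 nm, CA 97 +/- 12 degrees; mixing 86:14 LDL:EV, the highest EV
#' abundance observed on comparable deposition fields.
#'
#' @param ev_fraction Fraction of EVs in the field.
#' @return Named list suitable for [generate_afm_particles()].
#' @export
afm_population_defaults <- function(ev_fraction = 0.14) {
  list(
    LDL = list(deq_mean = 17, deq_sd = 3, ca_mean = 71, ca_sd = 8,
               fraction = 1 - ev_fraction),
    EV = list(deq_range = c(30, 130), ca_mean = 97, ca_sd = 12,
              fraction = ev_fraction)
  )
}
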