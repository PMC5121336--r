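#' Generate synthetic binding data with recorded truth
#'
#' Forward-simulates one of three models and returns the data together with
#' the generating parameters:
#' \describe{
#'   \item{`"saturation"`}{one-site isotherm `B = Bmax L / (Kd + L)` at the
#'     given concentrations, optional multiplicative Gaussian noise.}
#'   \item{`"kinetic_1to1"`}{single-cycle 1:1 sensorgram via
#'     [simulate_sensorgram()].}
#'   \item{`"two_site"`}{sum of two independent 1:1 sites (disjoint epitopes,
#'     e.g. the LDLR and ALK1 sites on an LDL surface); the response is the
#'     sum of the two sites' exact solutions.}
#' }
#'
#' @param model one of `"saturation"`, `"kinetic_1to1"`, `"two_site"`.
#' @param params named list of true parameters. Saturation: `Kd`, `Bmax`,
#'   `conc`. Kinetic: `ka`, `kd`, `Rmax`, `schedule`. Two-site: `ka1`, `kd1`,
#'   `Rmax1`, `ka2`, `kd2`, `Rmax2`, `schedule` (site 1 sees the analyte;
#'   site 2's occupancy is controlled by `site2_occupied`).
#' @param noise relative (saturation) or absolute RU (kinetic) noise s.d.
#'   (default 0).
#' @param drift linear drift in RU/s for sensorgrams (default 0).
#' @param site2_occupied for `"two_site"`: fraction of site 2 pre-saturated
#'   by the competitor before the run (default 0); an occupied independent
#'   site contributes only a constant, reference-subtracted offset.
#' @param seed integer seed.
#' @return list with `data` (a data frame `conc`/`bound`, or a `sensorgram`)
#'   and `truth` (the parameter list).
#' @export
gen_binding <- function(model = c("saturation", "kinetic_1to1", "two_site"),
                        params, noise = 0, drift = 0, site2_occupied = 0,
                        seed = 1L) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  if (model == "saturation") {
    L <- params$conc
    B <- params$Bmax * L / (params$Kd + L)
    if (noise > 0) B <- B * (1 + stats::rnorm(length(B), 0, noise))
    return(list(data = data.frame(conc = L, bound = B), truth = params))
  }
  if (model == "kinetic_1to1") {
    sg <- simulate_sensorgram(params$ka, params$kd, params$Rmax,
                              params$schedule, noise_sd = noise,
                              drift = drift)
    return(list(data = sg, truth = params))
  }
  # two independent sites: analyte binds site 1; site 2, if pre-occupied by
  # the competitor, is invisible after double referencing (constant offset)
  sg1 <- simulate_sensorgram(params$ka1, params$kd1, params$Rmax1,
                             params$schedule)
  resp <- sg1$response
  if (site2_occupied > 0) {
    # occupied-competitor dissociation during the run, at site 2's off-rate
    resp <- resp + site2_occupied * params$Rmax2 *
      exp(-params$kd2 * sg1$time)
  }
  if (noise > 0) resp <- resp + stats::rnorm(length(resp), 0, noise)
  if (drift != 0) resp <- resp + drift * sg1$time
  sg1$response <- resp
  list(data = sg1, truth = c(params, list(site2_occupied = site2_occupied)))
}
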