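#' One-site saturation binding fit
#'
#' Least-squares fit of the one-site isotherm
#' \deqn{B(L) = B_{max} L / (K_d + L)}
#' optionally with a linear nonspecific term \eqn{+ NS\,L}. Points are
#' weighted equally by default; `weights = "poisson"` weights by `1/B`
#' (appropriate when bound values derive from radioactive counts).
#'
#' @param concentrations ligand concentrations, strictly increasing, >= 0.
#' @param bound specifically bound ligand at each concentration.
#' @param nonspecific include a linear nonspecific component (default FALSE).
#' @param weights `"equal"` (default) or `"poisson"`.
#' @return object of class `binding_fit`: list with `Kd`, `Bmax`, (`NS`),
#'   `se` (named asymptotic standard errors), `residual_norm`, `fitted`,
#'   `model = "saturation"`, and the `nls` fit object.
#' @examples
#' L <- c(2, 5, 10, 25, 50, 100)
#' B <- 67 * L / (26 + L)
#' fit_saturation(L, B)$Kd
#' @export
fit_saturation <- function(concentrations, bound, nonspecific = FALSE,
                           weights = c("equal", "poisson")) {
  weights <- match.arg(weights)
  L <- concentrations; B <- bound
  stopifnot(length(L) == length(B), all(is.finite(L)), all(is.finite(B)),
            all(L >= 0), !is.unsorted(L, strictly = TRUE))
  if (length(unique(L)) < 4L) {
    stop("fit_saturation: need >= 4 distinct concentrations")
  }
  bmax0 <- max(B) * 1.2
  kd0 <- tryCatch(stats::approx(B, L, xout = max(B) / 2, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(L)
  w <- if (weights == "poisson") 1 / pmax(B, max(B) * 1e-3) else rep(1, length(B))
  fml <- if (nonspecific) B ~ Bmax * L / (Kd + L) + NS * L else
    B ~ Bmax * L / (Kd + L)
  start <- if (nonspecific) list(Bmax = bmax0, Kd = kd0, NS = 0) else
    list(Bmax = bmax0, Kd = kd0)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = data.frame(L = L, B = B), start = start,
                      weights = w,
                      lower = if (nonspecific) c(0, 1e-12, 0) else c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit_saturation: fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf["Kd"] <= 2e-12 || cf["Kd"] >= max(L) * 100) {
    stop("fit_saturation: Kd estimate at bound (", cf["Kd"],
         "); data do not constrain the isotherm")
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(Kd = unname(cf["Kd"]), Bmax = unname(cf["Bmax"]),
                 NS = if (nonspecific) unname(cf["NS"]) else NULL,
                 se = se, residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit), model = "saturation",
                 fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("Binding fit (", x$model, ")\n", sep = "")
  if (!is.null(x$Kd)) cat("  Kd   =", format(x$Kd, digits = 6), "\n")
  if (!is.null(x$Bmax)) cat("  Bmax =", format(x$Bmax, digits = 6), "\n")
  if (!is.null(x$ka)) cat("  ka   =", format(x$ka, digits = 6),
                          " kd =", format(x$kd_rate, digits = 6),
                          " Rmax =", format(x$Rmax, digits = 6), "\n")
  cat("  residual norm =", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

# Exact 1:1 Langmuir response under a piecewise-constant concentration
# schedule. Within a segment with constant C:
#   dR/dt = ka C (Rmax - R) - kd R
# has solution R(t) = Req + (R0 - Req) exp(-(ka C + kd)(t - t0)),
# Req = ka C Rmax / (ka C + kd). Response carries over between single-cycle
# injections (no regeneration).
.response_1to1 <- function(time, schedule, ka, kd, Rmax, R0 = 0) {
  bounds <- sort(unique(c(0, schedule$start, schedule$stop, max(time))))
  conc_at <- function(t) {
    i <- which(schedule$start <= t & t < schedule$stop)
    if (length(i)) schedule$conc[i[1]] else 0
  }
  R <- numeric(length(time))
  r0 <- R0
  for (s in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1L]
    C <- conc_at(t0)
    kobs <- ka * C + kd
    req <- if (kobs > 0) ka * C * Rmax / kobs else 0
    sel <- time >= t0 & (time < t1 | s == length(bounds) - 1L)
    R[sel] <- req + (r0 - req) * exp(-kobs * (time[sel] - t0))
    r0 <- req + (r0 - req) * exp(-kobs * (t1 - t0))
  }
  R
}

#' Simulate a (single-cycle) SPR sensorgram under the 1:1 model
#'
#' Evaluates the exact solution of
#' \deqn{dR/dt = k_a C(t) (R_{max} - R) - k_d R}
#' with `C(t)` piecewise-constant from the injection schedule (0 during
#' dissociation), response carried over between injections as in single-cycle
#' kinetics. Gaussian noise and linear baseline drift are added on request.
#'
#' @param k_a association rate (per concentration unit per s).
#' @param k_d_rate dissociation rate (per s).
#' @param R_max surface capacity (RU).
#' @param schedule data frame with columns `conc`, `start`, `stop` (seconds);
#'   injections must not overlap and, for single-cycle mode, must be in
#'   increasing concentration order.
#' @param time sample times (s); default 1 Hz from 0 to 120 s past the last
#'   injection.
#' @param noise_sd Gaussian noise s.d. (RU, default 0).
#' @param drift linear baseline drift (RU/s, default 0).
#' @param single_cycle logical flag recorded on the object (default TRUE).
#' @return object of class `sensorgram`: list with `time`, `response`,
#'   `schedule`, `single_cycle`.
#' @export
simulate_sensorgram <- function(k_a, k_d_rate, R_max, schedule,
                                time = NULL, noise_sd = 0, drift = 0,
                                single_cycle = TRUE) {
  stopifnot(k_a > 0, k_d_rate > 0, R_max > 0,
            all(c("conc", "start", "stop") %in% names(schedule)))
  o <- order(schedule$start)
  schedule <- schedule[o, , drop = FALSE]
  if (any(schedule$stop <= schedule$start)) {
    stop("simulate_sensorgram: injection stop must exceed start")
  }
  if (nrow(schedule) > 1L &&
      any(schedule$start[-1] < schedule$stop[-nrow(schedule)])) {
    stop("simulate_sensorgram: overlapping injections")
  }
  if (single_cycle && is.unsorted(schedule$conc, strictly = TRUE)) {
    stop("simulate_sensorgram: single-cycle injections must increase in concentration")
  }
  if (is.null(time)) time <- seq(0, max(schedule$stop) + 120, by = 1)
  R <- .response_1to1(time, schedule, k_a, k_d_rate, R_max)
  if (noise_sd > 0) R <- R + stats::rnorm(length(R), 0, noise_sd)
  if (drift != 0) R <- R + drift * time
  structure(list(time = time, response = R, schedule = schedule,
                 single_cycle = single_cycle), class = "sensorgram")
}

#' Fit the 1:1 kinetic model to a (single-cycle) sensorgram
#'
#' Global least-squares fit of \eqn{k_a}, \eqn{k_d} and \eqn{R_{max}} over
#' all injection and dissociation phases jointly, using the exact
#' piecewise-exponential solution of the 1:1 model. Parameters are fitted on
#' the log scale to enforce positivity; a small multi-start grid guards
#' against local minima. The apparent affinity is \eqn{K_d = k_d / k_a} in
#' the schedule's concentration units.
#'
#' @param sensorgram a `sensorgram` object (double-referenced response with a
#'   known schedule).
#' @return object of class `binding_fit` with `ka`, `kd_rate`, `Rmax`, `Kd`,
#'   `se` (on the log parameters), `residual_norm`, `fitted`,
#'   `model = "kinetic_1to1"`.
#' @export
fit_1to1_kinetics <- function(sensorgram) {
  stopifnot(inherits(sensorgram, "sensorgram") ||
            all(c("time", "response", "schedule") %in% names(sensorgram)))
  tm <- sensorgram$time; y <- sensorgram$response
  sched <- sensorgram$schedule
  if (max(y) - min(y) < 1e-9 * max(abs(y), 1)) {
    stop("fit_1to1_kinetics: flat sensorgram; kinetics not identifiable")
  }
  rmax0 <- max(y) * 1.5
  # kd from the tail of the final dissociation, if it decays
  tail_sel <- tm > max(sched$stop)
  kd0 <- 0.01
  if (sum(tail_sel) > 5) {
    yy <- y[tail_sel]
    if (all(yy > 0) && yy[length(yy)] < yy[1]) {
      tt <- tm[tail_sel]
      kd0 <- max(1e-5, unname(-stats::coef(stats::lm(log(yy) ~ tt))[2]))
    }
  }
  mid_conc <- stats::median(sched$conc)
  obj_data <- data.frame(t = tm, y = y)
  fit_one <- function(ka0) {
    tryCatch(minpack.lm::nlsLM(
      y ~ .response_1to1(t, sched, exp(lka), exp(lkd), exp(lRmax)),
      data = obj_data,
      start = list(lka = log(ka0), lkd = log(kd0), lRmax = log(rmax0)),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
  }
  starts <- kd0 / (mid_conc * c(1, 0.1, 10, 0.01, 100))
  best <- NULL; best_rss <- Inf
  for (ka0 in starts) {
    f <- fit_one(ka0)
    if (is.null(f)) next
    rss <- sum(stats::resid(f)^2)
    if (rss < best_rss) { best <- f; best_rss <- rss }
    if (best_rss < 1e-12 * sum(y^2)) break
  }
  if (is.null(best)) stop("fit_1to1_kinetics: no start converged")
  cf <- stats::coef(best)
  ka <- exp(cf[["lka"]]); kd <- exp(cf[["lkd"]]); rmax <- exp(cf[["lRmax"]])
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(ka = ka, kd_rate = kd, Rmax = rmax, Kd = kd / ka,
                 se = se, residual_norm = sqrt(best_rss),
                 fitted = stats::fitted(best), model = "kinetic_1to1",
                 fit = best),
            class = "binding_fit")
}

#' Double referencing of a raw sensorgram
#'
#' Subtracts, point-for-point, the reference-surface trace (nonspecific
#' binding to the dextran surface alone) and the buffer-blank trace from the
#' raw response. All traces must share the same time base.
#'
#' @param raw a `sensorgram` (or list with `time`, `response`).
#' @param reference_surface,buffer_blank traces with the same `time` vector;
#'   either may be `NULL` (skipped).
#' @return the corrected `sensorgram`. When the correction removes the whole
#'   signal (corrected equals `-raw`), attribute `pathological` is set.
#' @export
double_reference <- function(raw, reference_surface = NULL,
                             buffer_blank = NULL) {
  out <- raw
  for (ref in list(reference_surface, buffer_blank)) {
    if (is.null(ref)) next
    if (length(ref$time) != length(raw$time) ||
        any(ref$time != raw$time)) {
      stop("double_reference: mismatched time bases")
    }
    out$response <- out$response - ref$response
  }
  if (isTRUE(all.equal(out$response, -raw$response)) &&
      any(raw$response != 0)) {
    attr(out, "pathological") <- TRUE
  }
  out
}

#' Competition analysis between two binding fits
#'
#' Compares a fit on the naive surface with a fit after pre-saturating the
#' surface with the putative competitor. When both the affinity ratio and the
#' amplitude (`Rmax`) ratio stay within `[1/tolerance, tolerance]`, the two
#' analytes are judged non-competitive (independent sites); a collapsed
#' amplitude or shifted affinity indicates competition for a shared site.
#'
#' @param naive_fit,presaturated_fit `binding_fit` objects from comparable
#'   surfaces.
#' @param tolerance fold-change tolerance (default 2).
#' @return list: `kd_ratio`, `amplitude_ratio` (presaturated / naive),
#'   `verdict` in `{"non-competitive", "competitive"}`.
#' @export
competition_analysis <- function(naive_fit, presaturated_fit, tolerance = 2) {
  amp <- function(f) if (!is.null(f$Rmax)) f$Rmax else f$Bmax
  kd_ratio <- presaturated_fit$Kd / naive_fit$Kd
  amplitude_ratio <- amp(presaturated_fit) / amp(naive_fit)
  ok <- function(r) is.finite(r) && r >= 1 / tolerance && r <= tolerance
  list(kd_ratio = kd_ratio, amplitude_ratio = amplitude_ratio,
       verdict = if (ok(kd_ratio) && ok(amplitude_ratio))
         "non-competitive" else "competitive")
}

#' Stability-reference-point quantitation
#'
#' Reads each trace's response at a fixed offset into the early dissociation
#' phase (after the last injection stop), where bulk refractive-index
#' contributions have washed out, and normalizes by the same readout of a
#' normalizer trace.
#'
#' @param sensorgrams list of `sensorgram` objects (or a single one).
#' @param normalizer `sensorgram` whose stability-point amplitude defines 1.0.
#' @param offset_s seconds after the final injection stop (default 5).
#' @return numeric vector of normalized amplitudes, one per trace.
#' @export
stability_point_quantitation <- function(sensorgrams, normalizer,
                                         offset_s = 5) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  read_at <- function(sg) {
    t_ref <- max(sg$schedule$stop) + offset_s
    if (t_ref > max(sg$time)) {
      stop("stability_point_quantitation: stability point beyond trace end")
    }
    stats::approx(sg$time, sg$response, xout = t_ref)$y
  }
  norm_amp <- read_at(normalizer)
  if (norm_amp == 0) {
    stop("stability_point_quantitation: normalizer amplitude is zero")
  }
  vapply(sensorgrams, function(sg) read_at(sg) / norm_amp, numeric(1))
}
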