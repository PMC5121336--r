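#' Specification for a synthetic TIRF movie
#'
#' Describes a single-channel time-lapse of diffusing, docking and fusing
#' fluorescent vesicles imaged in a TIRF field: vesicles render as Gaussian
#' PSF spots over a constant camera offset, move by Brownian lateral steps,
#' may dock (motion stops) and, if selected for fusion, collapse to local
#' background over exactly two frames; global photobleaching and Gaussian
#' camera noise are applied. Fusion events occur only on docked vesicles.
#'
#' @param n_frames frames (default 150).
#' @param frame_rate frames per second (default 6.67).
#' @param dim image size in pixels (default `c(180, 180)`).
#' @param n_vesicles vesicles entering the field over the movie (default 80).
#' @param fusion_fraction fraction of vesicles that dock and fuse
#'   (default 0.35; with the defaults this yields of order 20-40 events per
#'   movie, the range typical of control cells).
#' @param psf_sigma Gaussian PSF sigma in pixels (default 1.3).
#' @param amplitude peak amplitude of a vesicle above background, camera
#'   units (default 600).
#' @param diffusion_step Brownian step s.d. in pixels per frame for mobile
#'   vesicles (default 0.6).
#' @param dock_jitter residual jitter of docked vesicles in pixels per frame
#'   (default 0.05).
#' @param dock_frames_min minimum docked frames before fusion (default 8).
#' @param bleach_rate global photobleaching rate per frame (default 0.002).
#' @param camera_offset,camera_noise_sd camera model: constant offset and
#'   Gaussian read-noise s.d. (defaults 100, 10).
#' @param collapse_frames frames over which a fusing vesicle decays to
#'   background (default 2, matching the two-frame fusion criterion;
#'   configurable to stress-test the rule).
#' @param seed integer seed; fixes the movie and its ground truth.
#' @return list of class `tirf_sim_spec`.
#' @export
tirf_sim_spec <- function(n_frames = 150L, frame_rate = 6.67,
                          dim = c(180L, 180L), n_vesicles = 80L,
                          fusion_fraction = 0.35, psf_sigma = 1.3,
                          amplitude = 600, diffusion_step = 0.6,
                          dock_jitter = 0.05, dock_frames_min = 8L,
                          bleach_rate = 0.002, camera_offset = 100,
                          camera_noise_sd = 10, collapse_frames = 2L,
                          seed = 1L) {
  stopifnot(n_frames >= 40L)  # room for a full dock-and-fuse lifecycle
  structure(as.list(environment()), class = "tirf_sim_spec")
}

# add a Gaussian spot of amplitude a at sub-pixel (r0, c0), 0-based
.render_spot <- function(img, r0, c0, sigma, a) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma)
  ri <- max(1L, floor(r0) + 1L - w):min(nr, floor(r0) + 1L + w)
  ci <- max(1L, floor(c0) + 1L - w):min(nc, floor(c0) + 1L + w)
  if (!length(ri) || !length(ci)) return(img)
  g <- a * exp(-(outer((ri - 1 - r0)^2, (ci - 1 - c0)^2, "+")) /
                 (2 * sigma^2))
  img[ri, ci] <- img[ri, ci] + g
  img
}

#' Generate a synthetic TIRF movie with planted fusion ground truth
#'
#' Simulates each vesicle's lifecycle (entry, Brownian motion, optional
#' docking and two-frame fusion collapse, or persistence/exit), renders
#' frames with Gaussian PSFs, photobleaching, camera offset and read noise,
#' and records the planted event list.
#'
#' @param spec a [tirf_sim_spec()].
#' @return list: `movie` (class `tirf_movie`: `frames` list of matrices,
#'   `frame_rate`, `pixel_size`), `truth` (data frame `vesicle`,
#'   `fusion_frame`, `row`, `col` for fusing vesicles).
#' @export
gen_tirf_movie <- function(spec) {
  stopifnot(inherits(spec, "tirf_sim_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames; nr <- spec$dim[1]; nc <- spec$dim[2]
  margin <- 8
  frames <- lapply(seq_len(nf), function(i) matrix(0, nr, nc))
  truth <- list()
  n_fuse <- round(spec$n_vesicles * spec$fusion_fraction)
  fusing <- seq_len(spec$n_vesicles) <= n_fuse
  # vesicle anchor positions with a minimum spacing of ~4 PSF sigma:
  # distinct docking sites, so each planted event is resolvable in principle
  min_sep <- 4.5 * spec$psf_sigma
  anchors <- matrix(NA_real_, spec$n_vesicles, 2)
  for (v in seq_len(spec$n_vesicles)) {
    for (try in 1:100) {
      cand <- c(stats::runif(1, margin, nr - 1 - margin),
                stats::runif(1, margin, nc - 1 - margin))
      if (v == 1L || all(sqrt(rowSums(
            (anchors[seq_len(v - 1L), , drop = FALSE] -
               matrix(cand, v - 1L, 2, byrow = TRUE))^2)) >= min_sep)) break
    }
    anchors[v, ] <- cand
  }
  for (v in seq_len(spec$n_vesicles)) {
    if (fusing[v]) {
      # lifecycle long enough for tracking (>= 10 frames) and a 5-frame
      # docking window before the collapse
      t_enter <- sample(1:(nf - 34L), 1)
      mobile <- sample(5:10, 1)
      docked <- max(spec$dock_frames_min, sample(10:22, 1))
      t_dock <- t_enter + mobile
      t_fuse <- min(t_dock + docked, nf - 4L)
      t_end <- min(t_fuse + spec$collapse_frames, nf)
    } else {
      # non-fusing vesicles either persist to the end of the movie or leave
      # the evanescent field: directed transport away (undocking) starting a
      # few frames before the intensity fades out, as cargo moving axially
      # and laterally out of the TIRF field
      t_enter <- sample(1:(nf - 12L), 1)
      t_exit <- t_enter + sample(15:nf, 1)
      t_dock <- if (stats::runif(1) < 0.3) t_enter + sample(4:10, 1) else Inf
      t_fuse <- Inf
      if (t_exit > nf - 9L) {
        t_exit <- Inf
        t_fade <- Inf
        t_end <- nf
      } else {
        t_fade <- t_exit + 3L
        t_end <- t_fade + 4L
      }
    }
    r <- anchors[v, 1]
    c <- anchors[v, 2]
    amp <- spec$amplitude * stats::runif(1, 0.8, 1.2)
    exit_dir <- stats::runif(1, 0, 2 * pi)
    exit_v <- 1.5 * c(cos(exit_dir), sin(exit_dir))  # px/frame during exit
    for (f in t_enter:t_end) {
      step_sd <- if (f >= t_dock) spec$dock_jitter else spec$diffusion_step
      if (f > t_enter) {
        if (!fusing[v] && is.finite(t_exit) && f >= t_exit) {
          r <- min(max(r + exit_v[1] + stats::rnorm(1, 0, 0.1), 1), nr - 2)
          c <- min(max(c + exit_v[2] + stats::rnorm(1, 0, 0.1), 1), nc - 2)
        } else {
          r <- min(max(r + stats::rnorm(1, 0, step_sd), 1), nr - 2)
          c <- min(max(c + stats::rnorm(1, 0, step_sd), 1), nc - 2)
        }
      }
      a <- amp * exp(-spec$bleach_rate * (f - 1))
      if (is.finite(t_fuse) && f > t_fuse) {
        # collapse to background in comparable per-frame steps over
        # collapse_frames frames (default 2: full -> 1/2 -> 0)
        frac <- 1 - (f - t_fuse) / spec$collapse_frames
        a <- a * max(frac, 0)
      } else if (!fusing[v] && f > t_fade) {
        a <- a * 0.45^(f - t_fade)
      }
      if (a > 0) frames[[f]] <- .render_spot(frames[[f]], r, c,
                                             spec$psf_sigma, a)
    }
    if (is.finite(t_fuse)) {
      truth[[length(truth) + 1L]] <- data.frame(
        vesicle = v, fusion_frame = t_fuse + 1L, row = r, col = c)
    }
  }
  frames <- lapply(seq_len(nf), function(f) {
    frames[[f]] + spec$camera_offset +
      matrix(stats::rnorm(nr * nc, 0, spec$camera_noise_sd), nr, nc)
  })
  movie <- structure(list(frames = frames, frame_rate = spec$frame_rate,
                          pixel_size = 0.16), class = "tirf_movie")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(vesicle = integer(0), fusion_frame = integer(0),
               row = numeric(0), col = numeric(0))
  list(movie = movie, truth = truth)
}

#' Write / read a movie as a multi-frame 16-bit TIFF
#'
#' Intensities are stored as 16-bit integers; values outside `[0, 65535]`
#' are clipped.
#'
#' @param movie a `tirf_movie`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  imgs <- lapply(movie$frames, function(f) {
    pmin(pmax(round(f), 0), 65535) / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate,pixel_size acquisition metadata to attach on read.
#' @export
read_movie_tiff <- function(path, frame_rate = 6.67, pixel_size = 0.16) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(imgs, function(m) m * 65535)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size), class = "tirf_movie")
}
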