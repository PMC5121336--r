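# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results with different primitives than
# the implementation.

# direct median/MAD z-score, no shared code with robust_zscore()
oracle_robust_z <- function(x) {
  m <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) m <- (sort(x)[length(x) / 2] + sort(x)[length(x) / 2 + 1]) / 2
  dev <- abs(x - m)
  md <- sort(dev)[ceiling(length(dev) / 2)]
  if (length(dev) %% 2 == 0) md <- (sort(dev)[length(dev) / 2] + sort(dev)[length(dev) / 2 + 1]) / 2
  (x - m) / (1.4826 * md)
}

# naive per-gene re-evaluation of all four cascade rules, written as flat
# loops over the long table
oracle_cascade_verdict <- function(records, gene) {
  get <- function(assay, sirna, set) {
    v <- records$percent_inhibition[records$gene_id == gene &
                                      records$assay == assay &
                                      records$sirna_id == sirna &
                                      records$set_id == set]
    if (length(v)) v[1] else NA_real_
  }
  sirnas <- unique(records$sirna_id[records$gene_id == gene])
  active <- character(0)
  for (s in sirnas) {
    v1 <- get("dil_ldl_eahy", s, 1); v2 <- get("dil_ldl_eahy", s, 2)
    if (!is.na(v1) && !is.na(v2) && v1 >= 50 && v2 >= 50) active <- c(active, s)
  }
  confirmed <- length(active) >= 2
  clean <- character(0)
  for (s in sirnas) {
    v1 <- get("tf_fitc_eahy", s, 1); v2 <- get("tf_fitc_eahy", s, 2)
    if (!is.na(v1) && !is.na(v2) && v1 < 30 && v2 < 30) clean <- c(clean, s)
  }
  tf_ok <- length(clean) >= 2 && length(intersect(clean, active)) >= 1
  n_dep <- 0
  for (s in sirnas) {
    h <- mean(c(get("dil_ldl_ldlr_high", s, 1), get("dil_ldl_ldlr_high", s, 2)), na.rm = TRUE)
    l <- mean(c(get("dil_ldl_ldlr_low", s, 1), get("dil_ldl_ldlr_low", s, 2)), na.rm = TRUE)
    if (!is.finite(h) || !is.finite(l)) next
    if (l == 0 || sign(h) != sign(l) || h / l >= 2 || h / l <= 0.5) n_dep <- n_dep + 1
  }
  ldlr_ok <- n_dep < 2
  hu_active <- 0
  for (s in sirnas) {
    v1 <- get("dil_ldl_huvec", s, 1); v2 <- get("dil_ldl_huvec", s, 2)
    if (!is.na(v1) && !is.na(v2) && v1 >= 50 && v2 >= 50) hu_active <- hu_active + 1
  }
  huvec_ok <- hu_active >= 2
  c(confirmed = confirmed, tf = confirmed && tf_ok,
    ldlr = confirmed && tf_ok && ldlr_ok,
    final = confirmed && tf_ok && ldlr_ok && huvec_ok)
}

# one-to-one matching of detected events against a planted truth list
match_events <- function(events, truth, max_px = 3, max_frames = 2) {
  used <- rep(FALSE, nrow(events))
  matched <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((events$row - truth$row[i])^2 + (events$col - truth$col[i])^2)
    ok <- which(d < max_px &
                  abs(events$fusion_frame - truth$fusion_frame[i]) <= max_frames &
                  !used)
    if (length(ok)) { matched <- matched + 1L; used[ok[1]] <- TRUE }
  }
  list(tp = matched, fp = nrow(events) - matched, fn = nrow(truth) - matched)
}

# frame with planted Gaussian spots on flat Gaussian noise
make_spot_frame <- function(positions, amplitude = 100, sigma = 1.5,
                            dim = c(96, 96), noise_sd = 10, offset = 100,
                            seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(prod(dim), offset, noise_sd), dim[1], dim[2])
  for (i in seq_len(nrow(positions))) {
    r0 <- positions[i, 1]; c0 <- positions[i, 2]
    rr <- pmax(1, round(r0) - 5):pmin(dim[1], round(r0) + 7)
    cc <- pmax(1, round(c0) - 5):pmin(dim[2], round(c0) + 7)
    f[rr, cc] <- f[rr, cc] + amplitude *
      exp(-outer((rr - 1 - r0)^2, (cc - 1 - c0)^2, "+") / (2 * sigma^2))
  }
  f
}

# synthetic docked-vesicle track with a given intensity series
make_track <- function(intensity, row = 50, col = 50, jitter = 0,
                       start_frame = 1, seed = 1) {
  set.seed(seed)
  n <- length(intensity)
  data.frame(frame = start_frame + seq_len(n) - 1L,
             row = row + cumsum(rnorm(n, 0, jitter)),
             col = col + cumsum(rnorm(n, 0, jitter)),
             intensity = intensity)
}
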