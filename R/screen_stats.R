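#' Per-plate robust z-scores for sample wells
#'
#' Standardizes the mean centre DiI intensity of each sample well against the
#' median and MAD of the sample wells of the same plate:
#' \deqn{z = (x - \mathrm{median}) / (1.4826 \cdot \mathrm{MAD}).}
#' Control and empty wells are excluded from the location/scale estimate (they
#' are reserved for the Z'-factor plate gate) and receive no score.
#'
#' @param plate data frame of wells for one plate and one replicate, with at
#'   least columns `role` and `intensity`. Rows with `role == "sample"` are
#'   scored.
#' @param min_sample_wells minimum number of finite-intensity sample wells
#'   required to estimate location and scale (default 8).
#' @return the sample-well rows of `plate` with an added numeric column `z`.
#' @examples
#' p <- data.frame(role = "sample", intensity = 1:9)
#' robust_zscore(p)$z[9]  # (9 - 5) / (1.4826 * 2)
#' @export
robust_zscore <- function(plate, min_sample_wells = 8L) {
  stopifnot(is.data.frame(plate), all(c("role", "intensity") %in% names(plate)))
  smp <- plate[plate$role == "sample", , drop = FALSE]
  x <- smp$intensity
  if (any(!is.finite(x))) {
    smp <- smp[is.finite(x), , drop = FALSE]
    x <- smp$intensity
  }
  if (nrow(smp) < min_sample_wells) {
    stop("robust_zscore: fewer than ", min_sample_wells,
         " sample wells with finite intensity")
  }
  med <- stats::median(x)
  s <- stats::mad(x, center = med)  # already scaled by 1.4826
  if (s == 0) {
    stop("robust_zscore: degenerate plate (MAD of sample intensities is 0); ",
         "refusing to apply a scale floor silently")
  }
  smp$z <- (x - med) / s
  smp
}

#' Z'-factor assay quality statistic
#'
#' \deqn{Z' = 1 - 3(\sigma_{pos} + \sigma_{neg}) / |\mu_{pos} - \mu_{neg}|}
#' computed from plate control wells with sample standard deviations. Values
#' above 0.2 indicate acceptable separation between the negative (control
#' siRNA) and positive (DNM2 siRNA) controls for this screen.
#'
#' @param neg_intensities,pos_intensities numeric vectors of control-well
#'   intensities; each needs at least 3 finite values.
#' @return unitless scalar, at most 1.
#' @export
zprime_factor <- function(neg_intensities, pos_intensities) {
  neg <- neg_intensities[is.finite(neg_intensities)]
  pos <- pos_intensities[is.finite(pos_intensities)]
  if (length(neg) < 3L || length(pos) < 3L) {
    stop("zprime_factor: need >= 3 finite values per control group")
  }
  mu_n <- mean(neg); mu_p <- mean(pos)
  if (mu_n == mu_p) {
    stop("zprime_factor: control group means are equal; Z' is undefined")
  }
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / abs(mu_p - mu_n)
}

#' Percent effect relative to the positive control
#'
#' Expresses a well intensity on the scale anchored at 0% for the
#' negative-control mean and 100% for the positive-control (DNM2 siRNA) mean.
#' Values outside `[0, 100]` are legitimate (stronger than either control).
#'
#' @param x well intensity (vectorized).
#' @param neg_mean,pos_mean control group means; must differ.
#' @return percent effect, same length as `x`.
#' @export
percent_effect <- function(x, neg_mean, pos_mean) {
  if (neg_mean == pos_mean) {
    stop("percent_effect: control means are equal; percent effect is undefined")
  }
  100 * (x - neg_mean) / (pos_mean - neg_mean)
}

#' Well-level quality control
#'
#' A well passes when it has at least 100 cells and no more than 20% dead
#' cells; both boundaries count as passing.
#'
#' @param cell_count integer vector of cells per well.
#' @param dead_fraction proportion of dead cells per well, in `[0, 1]`.
#' @param min_cells,max_dead the two gates (defaults 100 and 0.20).
#' @return logical vector, `TRUE` = pass.
#' @export
well_qc <- function(cell_count, dead_fraction, min_cells = 100L,
                    max_dead = 0.20) {
  cell_count >= min_cells & dead_fraction <= max_dead
}

#' Plate-level quality control report
#'
#' Computes the Z'-factor from the plate's control wells and accepts the plate
#' only when Z' strictly exceeds `zprime_min`. Also counts sample wells that
#' fail [well_qc()].
#'
#' @param plate data frame of wells for one plate (one replicate), with columns
#'   `plate_id`, `role`, `intensity`, `cell_count`, `dead_fraction`.
#' @param zprime_min acceptance bound on Z' (default 0.2, strict).
#' @inheritParams well_qc
#' @return one-row data frame: `plate_id`, `zprime`, `accepted`,
#'   `n_wells_failed_qc`.
#' @export
plate_qc <- function(plate, zprime_min = 0.2, min_cells = 100L,
                     max_dead = 0.20) {
  stopifnot(all(c("role", "intensity") %in% names(plate)))
  neg <- plate$intensity[plate$role == "neg_control"]
  pos <- plate$intensity[plate$role == "pos_control"]
  if (length(neg) == 0L || length(pos) == 0L) {
    stop("plate_qc: plate must contain both neg_control and pos_control wells")
  }
  zp <- zprime_factor(neg, pos)
  smp <- plate[plate$role == "sample", , drop = FALSE]
  n_fail <- sum(!well_qc(smp$cell_count, smp$dead_fraction, min_cells, max_dead))
  data.frame(
    plate_id = if ("plate_id" %in% names(plate)) plate$plate_id[1] else NA_character_,
    zprime = zp,
    accepted = zp > zprime_min,
    n_wells_failed_qc = n_fail,
    stringsAsFactors = FALSE
  )
}

#' Aggregate replicate z-scores and call hits
#'
#' Combines per-replicate robust z-scores per gene (median by default) and
#' calls two-sided hits at `|z| >= threshold`: `decrease` for the negative
#' tail (reduced DiI-LDL uptake), `increase` for the positive tail. Boundary
#' values count as hits. Genes with no surviving replicate scores are flagged
#' unscorable (`qc_pass = FALSE`) and are never hits.
#'
#' @param scores data frame with columns `gene_id`, `replicate`, `z` (one row
#'   per gene x replicate that survived plate/well QC).
#' @param threshold hit threshold on the aggregated score (default 2.5).
#' @param agg aggregation across replicates: `"median"` (default), `"mean"`.
#' @param mode `"aggregate"` calls hits on the combined score; `"any"` calls a
#'   hit when any single replicate exceeds the threshold (the aggregate column
#'   is still the median/mean).
#' @return data frame with one row per gene: `gene_id`, `z_r1..z_r3` (NA when
#'   missing), `z_aggregate`, `n_replicates`, `qc_pass`, `hit` in
#'   `{"decrease","increase","none"}`.
#' @export
aggregate_and_call <- function(scores, threshold = 2.5,
                               agg = c("median", "mean"),
                               mode = c("aggregate", "any")) {
  agg <- match.arg(agg)
  mode <- match.arg(mode)
  stopifnot(all(c("gene_id", "replicate", "z") %in% names(scores)))
  agg_fun <- if (agg == "median") stats::median else mean
  genes <- unique(scores$gene_id)
  by_gene <- split(scores, factor(scores$gene_id, levels = genes))
  res <- lapply(by_gene, function(g) {
    z <- g$z[is.finite(g$z)]
    reps <- g$replicate[is.finite(g$z)]
    zr <- rep(NA_real_, 3L)
    zr[reps[reps %in% 1:3]] <- z[reps %in% 1:3]
    if (length(z) == 0L) {
      return(data.frame(gene_id = g$gene_id[1], z_r1 = zr[1], z_r2 = zr[2],
                        z_r3 = zr[3], z_aggregate = NA_real_,
                        n_replicates = 0L, qc_pass = FALSE, hit = "none",
                        stringsAsFactors = FALSE))
    }
    za <- agg_fun(z)
    hit <- if (mode == "aggregate") {
      if (za <= -threshold) "decrease" else if (za >= threshold) "increase" else "none"
    } else {
      if (any(z <= -threshold)) "decrease"
      else if (any(z >= threshold)) "increase" else "none"
    }
    data.frame(gene_id = g$gene_id[1], z_r1 = zr[1], z_r2 = zr[2], z_r3 = zr[3],
               z_aggregate = za, n_replicates = length(z), qc_pass = TRUE,
               hit = hit, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full primary-screen hit calling
#'
#' Runs the per-plate pipeline over a well table covering all plates and
#' replicates: plate Z'-gate, well QC, per-plate robust z-scores over the
#' QC-passing sample wells, then replicate aggregation and two-sided hit
#' calling.
#'
#' @param wells well table (see [read_well_table()]): columns `plate_id`,
#'   `replicate`, `row`, `col`, `role`, `gene_id`, `sirna_id`, `intensity`,
#'   `cell_count`, `dead_fraction`.
#' @param z_threshold hit threshold (default 2.5).
#' @param zprime_min plate acceptance bound (default 0.2).
#' @inheritParams well_qc
#' @inheritParams aggregate_and_call
#' @return list with `gene_scores` (from [aggregate_and_call()]), `plate_qc`
#'   (one row per plate x replicate), and `summary` (named counts:
#'   plates seen/accepted, wells failing QC, genes scored, hits by direction).
#' @export
screen_call <- function(wells, z_threshold = 2.5, zprime_min = 0.2,
                        min_cells = 100L, max_dead = 0.20,
                        agg = "median", mode = "aggregate") {
  key <- interaction(wells$plate_id, wells$replicate, drop = TRUE)
  plates <- split(wells, key)
  qc_rows <- vector("list", length(plates))
  score_rows <- vector("list", length(plates))
  for (i in seq_along(plates)) {
    p <- plates[[i]]
    qc <- plate_qc(p, zprime_min = zprime_min, min_cells = min_cells,
                   max_dead = max_dead)
    qc$replicate <- p$replicate[1]
    qc_rows[[i]] <- qc
    if (!qc$accepted) next
    ok <- p$role != "sample" |
      well_qc(p$cell_count, p$dead_fraction, min_cells, max_dead)
    z <- robust_zscore(p[ok, , drop = FALSE])
    score_rows[[i]] <- data.frame(gene_id = z$gene_id,
                                  replicate = z$replicate, z = z$z,
                                  stringsAsFactors = FALSE)
  }
  qc_tab <- do.call(rbind, qc_rows)
  scores <- do.call(rbind, score_rows)
  if (is.null(scores) || nrow(scores) == 0L) {
    stop("screen_call: no plate passed the Z' gate; nothing to score")
  }
  gene_scores <- aggregate_and_call(scores, threshold = z_threshold,
                                    agg = agg, mode = mode)
  list(
    gene_scores = gene_scores,
    plate_qc = qc_tab,
    summary = c(
      n_plate_replicates = nrow(qc_tab),
      n_plate_replicates_accepted = sum(qc_tab$accepted),
      n_wells_failed_qc = sum(qc_tab$n_wells_failed_qc),
      n_genes_scored = sum(gene_scores$qc_pass),
      n_genes_unscorable = sum(!gene_scores$qc_pass),
      n_hits_decrease = sum(gene_scores$hit == "decrease"),
      n_hits_increase = sum(gene_scores$hit == "increase")
    )
  )
}
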