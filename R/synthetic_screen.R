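#' Specification for a synthetic RNAi screen
#'
#' Describes a screen with 384-well geometry: per plate, `n_neg` negative
#' (control siRNA) and `n_pos` positive (DNM2 siRNA) control wells in column
#' 1/24, remaining wells holding one gene each, replicated `n_replicates`
#' times. Null well intensities are log-normal (fluorescence is positive and
#' right-skewed); the positive control and planted hits act multiplicatively.
#' Hit effect sizes are expressed in plate-MAD units: an effect of -6 plants
#' wells whose expected robust z-score is -6.
#'
#' @param n_genes number of library genes (default 2000, a desk-scale
#'   stand-in for the 18,119-gene genome-wide library).
#' @param n_neg,n_pos control wells per plate (default 8 each).
#' @param meanlog,sdlog log-normal null intensity parameters (defaults
#'   `log(1000)`, 0.12).
#' @param pos_effect fractional intensity reduction of the positive control
#'   (default 0.8: DNM2 knockdown removes 80% of uptake signal).
#' @param hits named numeric vector: planted effect sizes in plate-MAD units
#'   per gene id (negative = reduced uptake); names must be gene ids;
#'   effects of 0 are rejected.
#' @param n_replicates independent replicates (default 3).
#' @param rep_noise per-well multiplicative log-normal noise sdlog between
#'   replicates (default 0.03).
#' @param qc_fail_fraction fraction of sample wells planted to fail
#'   cell-count/toxicity QC (default 0.02).
#' @param seed integer; fixes the whole dataset.
#' @return list of class `screen_sim_spec`.
#' @export
screen_sim_spec <- function(n_genes = 2000L, n_neg = 8L, n_pos = 8L,
                            meanlog = log(1000), sdlog = 0.12,
                            pos_effect = 0.8, hits = numeric(0),
                            n_replicates = 3L, rep_noise = 0.03,
                            qc_fail_fraction = 0.02, seed = 1L) {
  if (length(hits) && any(hits == 0)) {
    stop("screen_sim_spec: planted hit effects of 0 are not allowed")
  }
  structure(list(n_genes = as.integer(n_genes), n_neg = as.integer(n_neg),
                 n_pos = as.integer(n_pos), meanlog = meanlog, sdlog = sdlog,
                 pos_effect = pos_effect, hits = hits,
                 n_replicates = as.integer(n_replicates),
                 rep_noise = rep_noise, qc_fail_fraction = qc_fail_fraction,
                 seed = as.integer(seed)),
            class = "screen_sim_spec")
}

# theoretical MAD of a log-normal(meanlog, sdlog): M with
# F(med + M) - F(med - M) = 1/2
.lognormal_mad <- function(meanlog, sdlog) {
  med <- exp(meanlog)
  f <- function(M) {
    stats::plnorm(med + M, meanlog, sdlog) -
      stats::plnorm(pmax(med - M, 0), meanlog, sdlog) - 0.5
  }
  stats::uniroot(f, c(1e-9 * med, 10 * med))$root
}

#' Generate a synthetic screen well table with planted truth
#'
#' Lays genes out on 384-well plates (rows A-P, columns 1-24; column 1 =
#' negative controls, column 24 = positive controls, remaining wells =
#' samples), draws log-normal null intensities, applies the positive-control
#' and planted-hit effects multiplicatively, and plants a configurable
#' fraction of QC-failing wells. Same seed, same table, byte for byte.
#'
#' @param spec a [screen_sim_spec()].
#' @return list: `wells` (the long well table consumed by [screen_call()]),
#'   `truth` (data frame `gene_id`, `effect_mads`).
#' @export
gen_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  set.seed(spec$seed)
  # controls live in columns 1 (neg) and 24 (pos); samples fill columns 2-23
  # (352 wells); unused control-column wells are empty
  n_sample_wells <- 352L
  n_plates <- ceiling(spec$n_genes / n_sample_wells)
  genes <- sprintf("gene%05d", seq_len(spec$n_genes))
  med <- exp(spec$meanlog)
  s_th <- 1.4826 * .lognormal_mad(spec$meanlog, spec$sdlog)
  hit_factor <- function(e) pmax(1 + e * s_th / med, 1e-3)
  rows_all <- LETTERS[1:16]
  tabs <- vector("list", n_plates * spec$n_replicates)
  k <- 0L
  for (p in seq_len(n_plates)) {
    idx <- ((p - 1L) * n_sample_wells + 1L):min(p * n_sample_wells,
                                                spec$n_genes)
    plate_genes <- genes[idx]
    n_smp <- length(plate_genes)
    # geometry: controls in col 1 (neg) and col 24 (pos), samples fill 2..23
    neg_wells <- data.frame(row = rows_all[seq_len(spec$n_neg)], col = 1L,
                            role = "neg_control", gene_id = NA_character_,
                            sirna_id = "siCTRL")
    pos_wells <- data.frame(row = rows_all[seq_len(spec$n_pos)], col = 24L,
                            role = "pos_control", gene_id = NA_character_,
                            sirna_id = "siDNM2")
    grid <- expand.grid(row = rows_all, col = 2:23, stringsAsFactors = FALSE)
    smp_wells <- data.frame(row = grid$row[seq_len(n_smp)],
                            col = grid$col[seq_len(n_smp)],
                            role = "sample", gene_id = plate_genes,
                            sirna_id = paste0("pool_", plate_genes))
    mk_empty <- function(n_used, col) {
      if (n_used >= 16L) return(NULL)
      data.frame(row = rows_all[(n_used + 1L):16L], col = col,
                 role = "empty", gene_id = NA_character_,
                 sirna_id = NA_character_)
    }
    layout <- rbind(neg_wells, pos_wells, mk_empty(spec$n_neg, 1L),
                    mk_empty(spec$n_pos, 24L), smp_wells)
    for (r in seq_len(spec$n_replicates)) {
      k <- k + 1L
      n <- nrow(layout)
      base <- stats::rlnorm(n, spec$meanlog, spec$sdlog) *
        stats::rlnorm(n, 0, spec$rep_noise)
      fac <- rep(1, n)
      fac[layout$role == "pos_control"] <- 1 - spec$pos_effect
      if (length(spec$hits)) {
        m <- match(layout$gene_id, names(spec$hits))
        planted <- !is.na(m)
        fac[planted] <- hit_factor(spec$hits[m[planted]])
      }
      cell_count <- stats::rpois(n, 300)
      dead_fraction <- stats::runif(n, 0, 0.10)
      fail <- stats::runif(n) < spec$qc_fail_fraction & layout$role == "sample"
      half <- stats::runif(n) < 0.5
      cell_count[fail & half] <- stats::rpois(sum(fail & half), 40)
      dead_fraction[fail & !half] <- stats::runif(sum(fail & !half), 0.25, 0.8)
      tabs[[k]] <- data.frame(
        plate_id = sprintf("P%03d", p), replicate = r,
        row = layout$row, col = layout$col,
        well = sprintf("%s%02d", layout$row, layout$col),
        role = layout$role, gene_id = layout$gene_id,
        sirna_id = layout$sirna_id,
        intensity = base * fac, cell_count = cell_count,
        dead_fraction = dead_fraction, stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, tabs)
  rownames(wells) <- NULL
  truth <- data.frame(gene_id = names(spec$hits),
                      effect_mads = unname(spec$hits),
                      stringsAsFactors = FALSE)
  list(wells = wells, truth = truth)
}

#' Generate a synthetic deconvolution (follow-up) table with planted truth
#'
#' Emulates the structure of the follow-up screen table: 4 siRNAs x 2 sets x
#' 5 assays per gene, percent inhibition of the positive-control effect.
#' Genes belong to planted classes: `"true"` hits pass every cascade stage;
#' each decoy class violates exactly one rule (`"fail_dil"`: < 2 active
#' siRNAs; `"tf_dirty"`: transferrin inhibition >= 30%; `"ldlr_dep"`: >= 2
#' siRNAs with a >= 2-fold LDLR-high/low difference; `"fail_huvec"`: no HUVEC
#' re-confirmation).
#'
#' @param n_true,n_fail_dil,n_tf_dirty,n_ldlr_dep,n_fail_huvec genes per
#'   class.
#' @param seed integer seed; fixes the table.
#' @return list: `records` (long deconvolution table), `truth` (data frame
#'   `gene_id`, `class`, `final_hit`).
#' @export
gen_followup <- function(n_true = 10L, n_fail_dil = 100L, n_tf_dirty = 20L,
                         n_ldlr_dep = 5L, n_fail_huvec = 5L, seed = 1L) {
  set.seed(as.integer(seed))
  classes <- rep(c("true", "fail_dil", "tf_dirty", "ldlr_dep", "fail_huvec"),
                 c(n_true, n_fail_dil, n_tf_dirty, n_ldlr_dep, n_fail_huvec))
  n <- length(classes)
  genes <- sprintf("cand%03d", seq_len(n))
  recs <- vector("list", n)
  dup <- function(x, jitter = 3) {  # two sets around a common per-siRNA level
    cbind(x + stats::runif(length(x), -jitter, jitter),
          x + stats::runif(length(x), -jitter, jitter))
  }
  for (i in seq_len(n)) {
    cl <- classes[i]
    n_active <- sample(2:4, 1)
    dil_lvl <- c(stats::runif(n_active, 60, 90),
                 stats::runif(4 - n_active, 5, 38))
    if (cl == "fail_dil") {
      # exactly one siRNA active in both sets; one more active in one set only
      dil <- dup(c(stats::runif(1, 60, 90), stats::runif(3, 5, 40)))
      dil[2, ] <- c(stats::runif(1, 60, 90), stats::runif(1, 10, 42))
    } else {
      dil <- dup(dil_lvl)
    }
    tf <- if (cl == "tf_dirty") dup(stats::runif(4, 40, 80))
          else dup(stats::runif(4, 2, 22))
    huvec <- if (cl == "fail_huvec") dup(stats::runif(4, 5, 40))
             else dup(dil_lvl)
    hi <- stats::runif(4, 40, 70)
    lo <- if (cl == "ldlr_dep") {
      l <- hi * stats::runif(4, 0.8, 1.2)
      l[1:2] <- hi[1:2] / stats::runif(2, 2.6, 4)
      l
    } else hi * stats::runif(4, 0.85, 1.18)
    assay_block <- function(assay, m) {
      data.frame(gene_id = genes[i],
                 sirna_id = rep(sprintf("si%d", 1:4), 2),
                 assay = assay, set_id = rep(1:2, each = 4),
                 percent_inhibition = c(m[, 1], m[, 2]),
                 stringsAsFactors = FALSE)
    }
    recs[[i]] <- rbind(
      assay_block("dil_ldl_eahy", dil),
      assay_block("tf_fitc_eahy", tf),
      assay_block("dil_ldl_huvec", huvec),
      assay_block("dil_ldl_ldlr_high", dup(hi, 2)),
      assay_block("dil_ldl_ldlr_low", dup(lo, 2)))
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  list(records = records,
       truth = data.frame(gene_id = genes, class = classes,
                          final_hit = classes == "true",
                          stringsAsFactors = FALSE))
}
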