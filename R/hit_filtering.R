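#' @section Deconvolution tables:
#' The follow-up (deconvolution) screen re-tests each candidate gene with its
#' four individual siRNAs, in duplicate (set 1 and set 2), across five assays:
#' DiI-LDL uptake in EA.hy926 (`dil_ldl_eahy`), transferrin-FITC uptake
#' (`tf_fitc_eahy`), DiI-LDL uptake in HUVEC (`dil_ldl_huvec`), and DiI-LDL
#' uptake in LDLR-high vs LDLR-low EA.hy926 lines (`dil_ldl_ldlr_high`,
#' `dil_ldl_ldlr_low`). Measurements are percent inhibition relative to the
#' positive-control effect.
#' @name deconvolution
#' @keywords internal
NULL

.assays <- c("dil_ldl_eahy", "tf_fitc_eahy", "dil_ldl_huvec",
             "dil_ldl_ldlr_high", "dil_ldl_ldlr_low")

# per-siRNA (set1, set2) matrix for one gene and assay; NA where missing
.sirna_sets <- function(records, gene, assay) {
  r <- records[records$gene_id == gene & records$assay == assay, , drop = FALSE]
  sirnas <- sort(unique(records$sirna_id[records$gene_id == gene]))
  m <- matrix(NA_real_, nrow = length(sirnas), ncol = 2,
              dimnames = list(sirnas, c("set1", "set2")))
  for (i in seq_len(nrow(r))) {
    m[as.character(r$sirna_id[i]), r$set_id[i]] <- r$percent_inhibition[i]
  }
  m
}

#' Confirm DiI-LDL uptake inhibition by individual siRNAs
#'
#' An siRNA is active when its percent inhibition is at or above `threshold`
#' (50% by default) in both duplicate sets; a gene is confirmed when at least
#' two of its siRNAs are active. An siRNA missing either duplicate is counted
#' inactive and reported in the `missing` attribute.
#'
#' @param records deconvolution table rows (columns `gene_id`, `sirna_id`,
#'   `assay`, `set_id`, `percent_inhibition`); may contain several genes.
#' @param gene gene to evaluate.
#' @param assay assay to evaluate on (default the EA.hy926 DiI-LDL assay;
#'   the HUVEC re-confirmation uses `"dil_ldl_huvec"`).
#' @param threshold percent-inhibition cut, inclusive (default 50).
#' @return list: `confirmed` (logical), `n_active`, `active_sirnas`
#'   (character), plus attribute `missing` naming siRNAs with incomplete
#'   duplicates.
#' @export
confirm_dil_uptake <- function(records, gene, assay = "dil_ldl_eahy",
                               threshold = 50) {
  m <- .sirna_sets(records, gene, assay)
  missing <- rownames(m)[!stats::complete.cases(m)]
  active <- !is.na(m[, 1]) & !is.na(m[, 2]) &
    m[, 1] >= threshold & m[, 2] >= threshold
  out <- list(confirmed = sum(active) >= 2L, n_active = sum(active),
              active_sirnas = rownames(m)[active])
  attr(out, "missing") <- missing
  out
}

#' Transferrin specificity filter
#'
#' A gene is transferrin-clean when at least two of its siRNAs show strictly
#' less than `threshold` (30%) transferrin-FITC inhibition in both duplicate
#' sets. By default at least one of the clean siRNAs must also be DiI-active
#' (`overlap = "one"`): the gene's uptake phenotype and its clean transferrin
#' behaviour should be carried by the same reagent. `overlap = "none"` counts
#' any two clean siRNAs; `overlap = "all"` requires every counted clean siRNA
#' to be DiI-active.
#'
#' @inheritParams confirm_dil_uptake
#' @param active_sirnas character vector of DiI-active siRNAs for this gene
#'   (from [confirm_dil_uptake()]); only consulted when `overlap != "none"`.
#' @param threshold percent-inhibition bound, exclusive (default 30).
#' @param overlap overlap rule between clean and DiI-active siRNAs.
#' @return logical: `TRUE` when the gene passes the specificity filter.
#' @export
transferrin_specificity <- function(records, gene, active_sirnas = character(),
                                    threshold = 30,
                                    overlap = c("one", "none", "all")) {
  overlap <- match.arg(overlap)
  m <- .sirna_sets(records, gene, "tf_fitc_eahy")
  clean <- !is.na(m[, 1]) & !is.na(m[, 2]) &
    m[, 1] < threshold & m[, 2] < threshold
  clean_ids <- rownames(m)[clean]
  if (sum(clean) < 2L) return(FALSE)
  switch(overlap,
         none = TRUE,
         one = length(intersect(clean_ids, active_sirnas)) >= 1L,
         all = length(intersect(clean_ids, active_sirnas)) >= 2L)
}

#' LDLR-independence filter
#'
#' Compares each siRNA's percent effect between LDLR-high and LDLR-low cell
#' lines (duplicate sets averaged). When at least two siRNAs show a 2-fold or
#' larger difference between the two conditions (ratio >= `fold` or
#' <= 1/`fold`, direction-symmetric), the gene is considered LDLR-dependent
#' and fails the filter. A zero or opposite-sign denominator counts as a
#' >= 2-fold difference and is reported in the `degenerate` attribute.
#'
#' @inheritParams confirm_dil_uptake
#' @param fold fold-difference bound, inclusive (default 2).
#' @return logical: `TRUE` when the gene is LDLR-independent (retained).
#' @export
ldlr_independence <- function(records, gene, fold = 2) {
  hi <- rowMeans(.sirna_sets(records, gene, "dil_ldl_ldlr_high"), na.rm = TRUE)
  lo <- rowMeans(.sirna_sets(records, gene, "dil_ldl_ldlr_low"), na.rm = TRUE)
  sirnas <- union(names(hi), names(lo))
  degenerate <- character()
  dep <- vapply(sirnas, function(s) {
    h <- hi[s]; l <- lo[s]
    if (!is.finite(h) || !is.finite(l)) return(FALSE)
    if (l == 0 || sign(h) != sign(l)) {
      degenerate <<- c(degenerate, s)
      return(TRUE)
    }
    ratio <- h / l
    ratio >= fold || ratio <= 1 / fold
  }, logical(1))
  out <- sum(dep) < 2L
  attr(out, "degenerate") <- degenerate
  out
}

#' Run the full deconvolution filter cascade
#'
#' Applies, per gene: (1) DiI-LDL confirmation (>= 2 siRNAs with >= 50%
#' inhibition in both sets), (2) transferrin specificity (>= 2 siRNAs with
#' < 30% Tf-FITC inhibition in both sets), (3) LDLR independence (< 2 siRNAs
#' with a 2-fold difference between LDLR-high and LDLR-low), (4) HUVEC
#' re-confirmation (rule (1) on the HUVEC assay). Later stages are only
#' evaluated for genes surviving earlier ones; a gene missing an entire assay
#' fails at that stage and is reported in the `dropped` attribute.
#'
#' @param records long-format deconvolution table: columns `gene_id`,
#'   `sirna_id`, `assay`, `set_id`, `percent_inhibition`.
#' @param dil_threshold,tf_threshold,ldlr_fold stage thresholds (study
#'   defaults 50, 30, 2).
#' @param tf_overlap overlap rule passed to [transferrin_specificity()].
#' @param huvec_last stage order: `TRUE` (default) runs the LDLR filter before
#'   the HUVEC re-confirmation; `FALSE` swaps the last two stages.
#' @return list with `verdicts` (data frame: `gene_id`, `confirmed_dil`,
#'   `transferrin_clean`, `ldlr_independent`, `huvec_confirmed`, `final_hit`,
#'   `n_active_sirnas`) and `stage_counts` (named integer vector of genes
#'   entering/surviving each stage). Attribute `dropped` lists genes that
#'   failed a stage because an assay was entirely absent.
#' @export
run_cascade <- function(records, dil_threshold = 50, tf_threshold = 30,
                        ldlr_fold = 2, tf_overlap = "one", huvec_last = TRUE) {
  genes <- unique(records$gene_id)
  n <- length(genes)
  v <- data.frame(gene_id = genes,
                  confirmed_dil = logical(n), transferrin_clean = logical(n),
                  ldlr_independent = logical(n), huvec_confirmed = logical(n),
                  final_hit = logical(n), n_active_sirnas = integer(n),
                  stringsAsFactors = FALSE)
  dropped <- character()
  has_assay <- function(g, a) any(records$gene_id == g & records$assay == a)
  for (i in seq_len(n)) {
    g <- genes[i]
    if (!has_assay(g, "dil_ldl_eahy")) { dropped <- c(dropped, g); next }
    cd <- confirm_dil_uptake(records, g, threshold = dil_threshold)
    v$confirmed_dil[i] <- cd$confirmed
    v$n_active_sirnas[i] <- cd$n_active
    if (!cd$confirmed) next
    if (!has_assay(g, "tf_fitc_eahy")) { dropped <- c(dropped, g); next }
    v$transferrin_clean[i] <- transferrin_specificity(
      records, g, cd$active_sirnas, threshold = tf_threshold,
      overlap = tf_overlap)
    if (!v$transferrin_clean[i]) next
    eval_ldlr <- function() {
      if (!has_assay(g, "dil_ldl_ldlr_high") ||
          !has_assay(g, "dil_ldl_ldlr_low")) {
        dropped <<- c(dropped, g); FALSE
      } else as.logical(ldlr_independence(records, g, fold = ldlr_fold))
    }
    eval_huvec <- function() {
      if (!has_assay(g, "dil_ldl_huvec")) { dropped <<- c(dropped, g); FALSE }
      else confirm_dil_uptake(records, g, assay = "dil_ldl_huvec",
                              threshold = dil_threshold)$confirmed
    }
    if (huvec_last) {
      v$ldlr_independent[i] <- eval_ldlr()
      if (!v$ldlr_independent[i]) next
      v$huvec_confirmed[i] <- eval_huvec()
    } else {
      v$huvec_confirmed[i] <- eval_huvec()
      if (!v$huvec_confirmed[i]) next
      v$ldlr_independent[i] <- eval_ldlr()
    }
    v$final_hit[i] <- v$confirmed_dil[i] && v$transferrin_clean[i] &&
      v$ldlr_independent[i] && v$huvec_confirmed[i]
  }
  counts <- c(
    n_input = n,
    n_confirmed_dil = sum(v$confirmed_dil),
    n_transferrin_clean = sum(v$transferrin_clean),
    n_ldlr_independent = sum(v$ldlr_independent),
    n_huvec_confirmed = sum(v$huvec_confirmed),
    n_final = sum(v$final_hit)
  )
  out <- list(verdicts = v, stage_counts = counts)
  attr(out, "dropped") <- unique(dropped)
  out
}
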