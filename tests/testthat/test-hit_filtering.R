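mk_records <- function(gene, dil = NULL, tf = NULL, huvec = NULL,
                       hi = NULL, lo = NULL) {
  # each argument: 4 x 2 matrix (siRNA x set)
  block <- function(assay, m) {
    if (is.null(m)) return(NULL)
    data.frame(gene_id = gene, sirna_id = rep(sprintf("si%d", 1:4), 2),
               assay = assay, set_id = rep(1:2, each = 4),
               percent_inhibition = c(m[, 1], m[, 2]))
  }
  do.call(rbind, Filter(Negate(is.null), list(
    block("dil_ldl_eahy", dil), block("tf_fitc_eahy", tf),
    block("dil_ldl_huvec", huvec), block("dil_ldl_ldlr_high", hi),
    block("dil_ldl_ldlr_low", lo))))
}

m2 <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)

test_that("DiI confirmation needs two siRNAs active in both duplicate sets", {
  r <- mk_records("g", dil = m2(60, 55, 52, 70, 10, 20, 40, 45))
  out <- confirm_dil_uptake(r, "g")
  expect_true(out$confirmed)
  expect_equal(out$n_active, 2)
  # no siRNA reaches 50 in both sets
  r2 <- mk_records("g", dil = m2(60, 40, 52, 45, 80, 10, 90, 20))
  expect_false(confirm_dil_uptake(r2, "g")$confirmed)
  # the 50% boundary is inclusive
  r3 <- mk_records("g", dil = m2(50, 50, 50, 50, 0, 0, 0, 0))
  expect_true(confirm_dil_uptake(r3, "g")$confirmed)
  # missing duplicate counts the siRNA inactive and is flagged
  r4 <- r[-1, ]  # drop si1 set 1
  out4 <- confirm_dil_uptake(r4, "g")
  expect_equal(out4$n_active, 1)
  expect_true("si1" %in% attr(out4, "missing"))
})

test_that("transferrin filter is strict below 30% and respects overlap", {
  base <- m2(10, 15, 5, 20, 50, 50, 60, 60)
  r <- mk_records("g", dil = m2(60, 60, 70, 70, 0, 0, 0, 0), tf = base)
  act <- confirm_dil_uptake(r, "g")$active_sirnas
  expect_true(transferrin_specificity(r, "g", act))
  # dirty transferrin on the clean candidates
  r2 <- mk_records("g", dil = m2(60, 60, 70, 70, 0, 0, 0, 0),
                   tf = m2(35, 40, 50, 10, 50, 50, 60, 60))
  expect_false(transferrin_specificity(r2, "g", act))
  # 29.9 in both sets is clean (strictly less than 30)
  r3 <- mk_records("g", dil = m2(60, 60, 70, 70, 0, 0, 0, 0),
                   tf = m2(29.9, 29.9, 0, 0, 60, 60, 60, 60))
  expect_true(transferrin_specificity(r3, "g", act))
  # overlap rule: clean siRNAs disjoint from the DiI-active ones
  r5 <- mk_records("g", dil = m2(60, 60, 70, 70, 0, 0, 0, 0),
                   tf = m2(60, 60, 70, 70, 5, 5, 5, 5))
  expect_false(transferrin_specificity(r5, "g", act, overlap = "one"))
  expect_true(transferrin_specificity(r5, "g", act, overlap = "none"))
})

test_that("LDLR-dependence counts siRNAs with a symmetric 2-fold difference", {
  ok <- mk_records("g", hi = m2(60, 60, 50, 50, 70, 70, 40, 40),
                   lo = m2(55, 55, 48, 48, 65, 65, 44, 44))
  expect_true(ldlr_independence(ok, "g"))
  dep <- mk_records("g", hi = m2(60, 60, 50, 50, 70, 70, 40, 40),
                    lo = m2(20, 20, 15, 15, 65, 65, 44, 44))
  expect_false(ldlr_independence(dep, "g"))
  # a single 2-fold siRNA is not enough
  one <- mk_records("g", hi = m2(60, 60, 50, 50, 70, 70, 40, 40),
                    lo = m2(30, 30, 48, 48, 65, 65, 44, 44))
  expect_true(ldlr_independence(one, "g"))
  # inverted ratios (low >> high) count too
  inv <- mk_records("g", hi = m2(20, 20, 15, 15, 70, 70, 40, 40),
                    lo = m2(60, 60, 50, 50, 65, 65, 44, 44))
  expect_false(ldlr_independence(inv, "g"))
  # zero denominator treated as dependent and logged
  z <- mk_records("g", hi = m2(60, 60, 50, 50, 70, 70, 40, 40),
                  lo = m2(0, 0, 0, 0, 65, 65, 44, 44))
  out <- ldlr_independence(z, "g")
  expect_false(out)
  expect_setequal(attr(out, "degenerate"), c("si1", "si2"))
})

test_that("cascade recovers planted truth and reports monotone stage counts", {
  sim <- gen_followup(n_true = 10, n_fail_dil = 100, n_tf_dirty = 20,
                      n_ldlr_dep = 5, n_fail_huvec = 5, seed = 5)
  out <- run_cascade(sim$records)
  expect_setequal(out$verdicts$gene_id[out$verdicts$final_hit],
                  sim$truth$gene_id[sim$truth$final_hit])
  cnt <- out$stage_counts
  expect_equal(unname(cnt["n_input"]), 140)
  expect_true(all(diff(cnt[c("n_input", "n_confirmed_dil",
                             "n_transferrin_clean", "n_ldlr_independent",
                             "n_final")]) <= 0))
  # each decoy class is removed at its intended stage
  v <- merge(out$verdicts, sim$truth, by = "gene_id")
  expect_true(all(!v$confirmed_dil[v$class == "fail_dil"]))
  expect_true(all(v$confirmed_dil[v$class == "tf_dirty"] &
                    !v$transferrin_clean[v$class == "tf_dirty"]))
  expect_true(all(v$transferrin_clean[v$class == "ldlr_dep"] &
                    !v$ldlr_independent[v$class == "ldlr_dep"]))
  expect_true(all(v$ldlr_independent[v$class == "fail_huvec"] &
                    !v$huvec_confirmed[v$class == "fail_huvec"]))
})

test_that("cascade verdicts equal a brute-force oracle and ignore row order", {
  sim <- gen_followup(n_true = 4, n_fail_dil = 8, n_tf_dirty = 4,
                      n_ldlr_dep = 2, n_fail_huvec = 2, seed = 9)
  out <- run_cascade(sim$records)
  for (g in out$verdicts$gene_id) {
    o <- oracle_cascade_verdict(sim$records, g)
    i <- which(out$verdicts$gene_id == g)
    expect_equal(unname(out$verdicts$final_hit[i]), unname(o["final"]),
                 label = paste("gene", g))
  }
  # permuting rows changes nothing
  set.seed(1)
  shuffled <- sim$records[sample(nrow(sim$records)), ]
  out2 <- run_cascade(shuffled)
  m <- merge(out$verdicts, out2$verdicts, by = "gene_id")
  expect_equal(m$final_hit.x, m$final_hit.y)
  expect_equal(sort(unname(out$stage_counts)), sort(unname(out2$stage_counts)))
})

test_that("cascade handles empty and all-failing inputs", {
  empty <- data.frame(gene_id = character(0), sirna_id = character(0),
                      assay = character(0), set_id = integer(0),
                      percent_inhibition = numeric(0))
  out <- run_cascade(empty)
  expect_true(all(out$stage_counts == 0))
  # every gene fails stage 1 -> zero everywhere downstream
  sim <- gen_followup(n_true = 0, n_fail_dil = 10, n_tf_dirty = 0,
                      n_ldlr_dep = 0, n_fail_huvec = 0, seed = 2)
  out2 <- run_cascade(sim$records)
  expect_equal(unname(out2$stage_counts["n_confirmed_dil"]), 0L)
  expect_equal(unname(out2$stage_counts["n_final"]), 0L)
  # a gene missing an entire assay is dropped at that stage and logged
  rec <- sim$records
  good <- gen_followup(n_true = 1, n_fail_dil = 0, n_tf_dirty = 0,
                       n_ldlr_dep = 0, n_fail_huvec = 0, seed = 3)$records
  good$gene_id <- "candX01"
  good <- good[good$assay != "tf_fitc_eahy", ]
  out3 <- run_cascade(rbind(rec, good))
  expect_true(good$gene_id[1] %in% attr(out3, "dropped"))
  expect_false(out3$verdicts$final_hit[out3$verdicts$gene_id == good$gene_id[1]])
})
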