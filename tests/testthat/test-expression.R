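test_that("expression calls require at least half the probes detected", {
  probes <- tibble::tibble(
    probe_id = c("a1", "a2", "b1", "b2", "b3", "c1", "c2", "c3"),
    gene_id = c("A", "A", "B", "B", "B", "C", "C", "C"),
    context_id = "t1",
    detection_p = c(0.01, 0.20, 0.06, 0.2, 0.9, 0.01, 0.02, 0.9))
  calls <- call_expression(probes)
  got <- setNames(calls$call, calls$gene_id)
  expect_equal(got[["A"]], "expressed")       # 1 of 2 >= 1
  expect_equal(got[["B"]], "not_expressed")   # 0 of 3
  expect_equal(got[["C"]], "expressed")       # 2 of 3 >= 1.5
})

test_that("the detection rule is strict and no_data pairs are emitted", {
  probes <- tibble::tibble(probe_id = "p", gene_id = "A", context_id = "t1",
                           detection_p = 0.05)
  calls <- call_expression(probes, alpha = 0.05, genes = c("A", "B"))
  expect_equal(calls$call[calls$gene_id == "A"], "not_expressed")  # p < a
  expect_equal(calls$call[calls$gene_id == "B"], "no_data")
  expect_equal(nrow(call_expression(probes[0, ])), 0)
})

test_that("raising alpha never silences an expressed call", {
  set.seed(11)
  probes <- tibble::tibble(
    probe_id = paste0("p", 1:400),
    gene_id = sample(paste0("G", 1:40), 400, replace = TRUE),
    context_id = sample(c("t1", "t2"), 400, replace = TRUE),
    detection_p = stats::runif(400))
  for (pair in list(c(0.01, 0.05), c(0.05, 0.2), c(0.2, 0.8))) {
    lo <- call_expression(probes, alpha = pair[1])
    hi <- call_expression(probes, alpha = pair[2])
    expect_false(any(lo$call == "expressed" & hi$call == "not_expressed"))
  }
})

test_that("breadth classes cut at 107 and 27 of 109 tissues", {
  expect_equal(classify_breadth(108, 109), "housekeeping")
  expect_equal(classify_breadth(107, 109), "housekeeping")
  expect_equal(classify_breadth(106, 109), "intermediate")
  expect_equal(classify_breadth(28, 109), "intermediate")
  expect_equal(classify_breadth(27, 109), "tissue_selective")
  expect_equal(classify_breadth(20, 109), "tissue_selective")
  expect_equal(classify_breadth(50, 109), "intermediate")
  # exact-integer fraction boundaries stay strict / inclusive as documented
  expect_equal(classify_breadth(98, 100), "housekeeping")
  expect_equal(classify_breadth(25, 100), "intermediate")
  expect_equal(classify_breadth(24, 100), "tissue_selective")
  expect_error(classify_breadth(0, 0), "positive")
})

test_that("expressed-fraction comparison matches the closed 2x2 form", {
  mk_calls <- function(pos_g, n_g, pos_r, n_r) {
    tibble::tibble(
      context_id = "t",
      gene_id = paste0(rep(c("g", "r"), c(n_g, n_r)),
                       c(seq_len(n_g), seq_len(n_r))),
      call = c(rep(c("expressed", "not_expressed"), c(pos_g, n_g - pos_g)),
               rep(c("expressed", "not_expressed"), c(pos_r, n_r - pos_r))),
      level = NA_real_)
  }
  calls <- mk_calls(8, 10, 40, 100)
  cmp <- expressed_fraction_comparison(
    calls, paste0("g", 1:10), paste0("r", 1:100), "t")
  expect_equal(cmp$chi2_stat, 5.913978494624, tolerance = 1e-10)
  expect_equal(cmp$p_value, 0.015021210118, tolerance = 1e-8)
  expect_equal(cmp$log2ratio, 1)

  equal <- expressed_fraction_comparison(
    mk_calls(5, 10, 50, 100), paste0("g", 1:10), paste0("r", 1:100), "t")
  expect_equal(equal$log2ratio, 0)
  expect_equal(equal$chi2_stat, 0)
  expect_equal(equal$p_value, 1)

  zero <- expressed_fraction_comparison(
    mk_calls(0, 10, 40, 100), paste0("g", 1:10), paste0("r", 1:100), "t")
  expect_true(zero$undefined)
  expect_true(is.na(zero$log2ratio))
  expect_equal(zero$n_group_neg, 10)

  empty <- expressed_fraction_comparison(
    mk_calls(5, 10, 50, 100), "absent", paste0("r", 1:100), "t")
  expect_true(empty$undefined)
  expect_error(expressed_fraction_comparison(calls, "g1", c("g1", "r1"),
                                             "t"), "disjoint")
})

test_that("chi-squared agrees with stats::chisq.test on random tables", {
  set.seed(99)
  for (i in 1:100) {
    tab <- matrix(sample(1:60, 4, replace = TRUE), 2)
    ours <- driverlens:::chisq2x2(tab[1, 1], tab[1, 2], tab[2, 1],
                                  tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(unname(ours["stat"]), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(ours["p"]), ref$p.value, tolerance = 1e-12)
    yates <- driverlens:::chisq2x2(tab[1, 1], tab[1, 2], tab[2, 1],
                                   tab[2, 2], yates = TRUE)
    refy <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(unname(yates["stat"]), unname(refy$statistic),
                 tolerance = 1e-12)
  }
})

test_that("swapping group and rest negates log2ratio, keeps chi2 and p", {
  set.seed(5)
  calls <- tibble::tibble(
    context_id = "t", gene_id = paste0("x", 1:60),
    call = sample(c("expressed", "not_expressed"), 60, replace = TRUE,
                  prob = c(0.6, 0.4)),
    level = NA_real_)
  g <- paste0("x", 1:20); r <- paste0("x", 21:60)
  ab <- expressed_fraction_comparison(calls, g, r, "t")
  ba <- expressed_fraction_comparison(calls, r, g, "t")
  expect_equal(ab$log2ratio, -ba$log2ratio, tolerance = 1e-12)
  expect_equal(ab$chi2_stat, ba$chi2_stat, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("highly-expressed mode splits at the context median level", {
  calls <- tibble::tibble(
    context_id = "t", gene_id = paste0("x", 1:8),
    call = "expressed", level = c(1, 2, 3, 4, 5, 6, 7, 8))
  cmp <- expressed_fraction_comparison(calls, paste0("x", 5:8),
                                       paste0("x", 1:4), "t",
                                       mode = "highly_expressed")
  # median 4.5: group holds all four high-level genes
  expect_equal(cmp$f_group, 1)
  expect_equal(cmp$f_rest, 0)
  expect_true(cmp$undefined)
})

test_that("Fisher enrichment matches hypergeometric enumeration", {
  expect_equal(class_enrichment_fisher(matrix(c(2, 0, 0, 2), 2))$p_value,
               1 / 3, tolerance = 1e-12)
  expect_equal(class_enrichment_fisher(matrix(c(1, 1, 1, 1), 2))$p_value,
               1, tolerance = 1e-12)
  expect_error(class_enrichment_fisher(matrix(0, 2, 2)), "all-zero")
  or <- class_enrichment_fisher(matrix(c(5, 0, 3, 0), 2))
  expect_true(is.na(or$odds_ratio))  # zero row margin
})

test_that("breadth distribution comparison reports the exact rank-sum tail", {
  same <- compare_breadth_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$wilcoxon_p, 1)
  sep <- compare_breadth_distributions(1:5, 101:105)
  expect_equal(sep$wilcoxon_p, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(sep$median_a, 3)
  expect_error(compare_breadth_distributions(1:2, 1:5), "at least 3")
})

test_that("breadth summary counts only contexts with data", {
  calls <- tibble::tibble(
    context_id = rep(paste0("t", 1:4), 2),
    gene_id = rep(c("A", "B"), each = 4),
    call = c("expressed", "expressed", "not_expressed", "no_data",
             rep("expressed", 4)),
    level = NA_real_)
  bs <- breadth_summary(calls)
  expect_equal(bs$n_total[bs$gene_id == "A"], 3)
  expect_equal(bs$n_expressed[bs$gene_id == "A"], 2)
  expect_equal(bs$breadth_class[bs$gene_id == "B"], "housekeeping")
})
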