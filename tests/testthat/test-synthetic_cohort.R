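test_that("generation is deterministic in the seed", {
  a <- small_cohort(seed = 42, n_samples = 10, n_genes = 100)
  b <- small_cohort(seed = 42, n_samples = 10, n_genes = 100)
  expect_identical(a$bundle$mutations, b$bundle$mutations)
  expect_identical(a$bundle$genes, b$bundle$genes)
  expect_identical(a$bundle$expression, b$bundle$expression)
  expect_identical(a$screen$scores, b$screen$scores)
  expect_identical(a$truth, b$truth)
  expect_true(igraph::identical_graphs(a$bundle$network, b$bundle$network))
  c <- small_cohort(seed = 43, n_samples = 10, n_genes = 100)
  expect_false(identical(a$bundle$mutations, c$bundle$mutations))
})

test_that("a zero passenger rate leaves only planted mutations", {
  co <- small_cohort(seed = 4, n_samples = 10, n_genes = 100,
                     passenger_rate_per_bp = 0)
  planted <- co$truth$drivers
  clean <- unique(planted$sample_id)
  muts_clean <- co$bundle$mutations[
    co$bundle$mutations$sample_id %in% clean, ]
  expect_setequal(paste(muts_clean$sample_id, muts_clean$gene_id),
                  paste(planted$sample_id, planted$gene_id))
  # known-driver samples carry exactly one known-gene mutation
  other <- co$bundle$mutations[!co$bundle$mutations$sample_id %in% clean, ]
  expect_true(all(other$gene_id %in% co$bundle$known_cancer_set))
})

test_that("the constructed known-driver fraction is discarded exactly", {
  co <- small_cohort(seed = 6, n_samples = 20, n_genes = 200,
                     passenger_rate_per_bp = 0,
                     fraction_samples_with_known_driver = 0.9)
  flt <- filter_samples(co$bundle)
  expect_equal(sum(!flt$retained), 18)
  expect_true(all(flt$reason[!flt$retained] == "known_gene"))
})

test_that("planted drivers are recovered perfectly in a noise-free cohort", {
  co <- small_cohort(seed = 10, n_samples = 20, n_genes = 200,
                     passenger_rate_per_bp = 0)
  rep <- quiet_pipeline(co$bundle)
  rec <- evaluate_recovery(rep, co$truth$drivers)
  expect_equal(rec$sensitivity, 1)
  # noise-free: nothing beyond the planted drivers is called
  expect_setequal(paste(rep$drivers$sample_id, rep$drivers$gene_id),
                  paste(co$truth$drivers$sample_id,
                        co$truth$drivers$gene_id))
})

test_that("length-proportional passengers create the length-recurrence bias", {
  co <- small_cohort(seed = 2, n_samples = 60, n_genes = 400,
                     passenger_rate_per_bp = 5e-5)
  rec <- recurrence_counts(co$bundle$mutations,
                           co$bundle$sample_to_cancer_type)
  genes <- dplyr::inner_join(co$bundle$genes, rec, by = "gene_id")
  tr <- length_recurrence_trend(genes, recurrence = "n_samples")
  expect_gt(glance(tr)$slope, 0)
})

test_that("expressed synthetic genes are called expressed almost surely", {
  co <- small_cohort(seed = 14, n_samples = 10, n_genes = 150)
  planted <- co$truth$drivers
  calls <- co$bundle$expression
  idx <- match(paste(planted$sample_id, planted$gene_id),
               paste(calls$context_id, calls$gene_id))
  expect_true(all(calls$call[idx] == "expressed"))
  # probe-level regime: background expressed fraction near expression_rate
  frac <- mean(calls$call[calls$call != "no_data"] == "expressed")
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)
})

test_that("preferential attachment yields connected heavy-tailed networks", {
  tree <- simulate_network(10, attachment = 1, seed = 3)
  expect_equal(igraph::ecount(tree), 9)
  expect_true(igraph::is_connected(tree))
  g <- simulate_network(2000, attachment = 2, seed = 5)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
  deg <- igraph::degree(g)
  expect_gt(max(deg), 5 * stats::median(deg))
  expect_true(igraph::identical_graphs(
    simulate_network(50, 2, seed = 8), simulate_network(50, 2, seed = 8)))
  expect_error(simulate_network(2, attachment = 2), "exceed")
})

test_that("infeasible configurations fail before generating output", {
  expect_error(suppressWarnings(simulate_cohort(synthetic_config(
    n_samples = 5, n_genes = 20,
    n_planted_drivers_per_clean_sample = 50, seed = 1))), "infeasible")
})

test_that("screen suppressors separate from background genes", {
  co <- small_cohort(seed = 16, n_samples = 5, n_genes = 200,
                     n_suppressors = 50)
  eff <- gene_effect(co$screen, cell_lines = "LINE1")
  sup <- eff$effect[eff$gene_id %in% co$truth$suppressors]
  bg <- eff$effect[!eff$gene_id %in% co$truth$suppressors]
  set.seed(1)
  cmp <- compare_silencing_groups(sup, sample(bg, 50))
  expect_lt(cmp$wilcoxon_p, 0.01)
  expect_gt(cmp$median_a, cmp$median_b)
})

test_that("the tissue panel produces the whole breadth spectrum", {
  cfg <- synthetic_config(n_genes = 150, n_tissues = 30, seed = 21)
  probes <- simulate_tissue_panel(cfg)
  calls <- call_expression(probes)
  bs <- breadth_summary(calls)
  expect_setequal(unique(bs$breadth_class),
                  c("housekeeping", "tissue_selective", "intermediate"))
})
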