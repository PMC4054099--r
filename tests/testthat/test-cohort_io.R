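test_that("simple mutation tables are read, validated and deduplicated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    gene_id = c("G1", "G1", "G2"),
    mutation_class = c("missense", "missense", "frameshift"),
    sift_damage_score = c(0.99, 0.99, NA)), path)
  muts <- suppressMessages(read_mutation_table(path, dialect = "simple"))
  expect_equal(nrow(muts), 2)
  expect_equal(sort(muts$gene_id), c("G1", "G2"))
})

test_that("MAF dialect maps variant classes and flags bad scores", {
  path <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(
    Hugo_Symbol = c("A", "B", "C", "D", "E"),
    Tumor_Sample_Barcode = "s1",
    Variant_Classification = c("Frame_Shift_Del", "Missense_Mutation",
                               "Splice_Site", "Silent", "In_Frame_Ins"),
    sift_damage = c(NA, 0.97, NA, NA, NA)), path)
  muts <- read_mutation_table(path, dialect = "maf")
  expect_equal(muts$mutation_class,
               c("frameshift", "missense", "splice_site", "synonymous",
                 "other"))
  # canonical-SIFT conversion flips the orientation
  muts_raw <- read_mutation_table(path, dialect = "maf", sift_raw = TRUE)
  expect_equal(muts_raw$sift_damage_score[2], 1 - 0.97)

  bad <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(
    Hugo_Symbol = "A", Tumor_Sample_Barcode = "s1",
    Variant_Classification = "Missense_Mutation", sift_damage = 1.3), bad)
  expect_error(read_mutation_table(bad, "maf"), "row 1")
  incomplete <- withr::local_tempfile(fileext = ".maf")
  readr::write_tsv(tibble::tibble(Hugo_Symbol = "A"), incomplete)
  expect_error(read_mutation_table(incomplete, "maf"),
               "Tumor_Sample_Barcode")
})

test_that("network reading collapses duplicates and self-loops", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "A\tA", "A\tC"), path)
  g <- suppressMessages(read_network(path))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_false(igraph::any_loop(g))

  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tD"), path2)
  g2 <- read_network(path2)
  expect_equal(igraph::degree(g2)[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 2, D = 1))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A", bad)
  expect_error(read_network(bad), "two columns")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_error(read_network(empty), "empty")
})

test_that("network reading is orientation invariant", {
  set.seed(42)
  a <- sample(LETTERS[1:8], 30, replace = TRUE)
  b <- sample(LETTERS[1:8], 30, replace = TRUE)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  writeLines(paste(a, b, sep = "\t"), p1)
  writeLines(paste(b, a, sep = "\t"), p2)
  g1 <- suppressMessages(read_network(p1))
  g2 <- suppressMessages(read_network(p2))
  expect_true(igraph::identical_graphs(
    igraph::permute(g1, match(igraph::V(g1)$name, igraph::V(g2)$name)), g2))
})

test_that("GCT 1.2 round-trips and rejects malformed files", {
  m <- matrix(c(1.5, 2, 3, 4.25, 5, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("c1", "c2", "c3")))
  scr <- shrna_screen(m, tibble::tibble(probe_id = c("p1", "p2"),
                                        gene_id = c("GA", "GB")))
  path <- withr::local_tempfile(fileext = ".gct")
  write_gct(scr, path)
  back <- read_gct(path)
  expect_equal(back$scores, scr$scores)
  expect_equal(back$probe_map, scr$probe_map)

  lines <- readLines(path)
  badv <- withr::local_tempfile(); writeLines(c("#1.3", lines[-1]), badv)
  expect_error(read_gct(badv), "#1.2")
  baddim <- withr::local_tempfile()
  writeLines(c(lines[1], "5\t3", lines[-(1:2)]), baddim)
  expect_error(read_gct(baddim), "declares 5 rows")
})

test_that("GCT probes without a gene mapping are retained with a warning", {
  m <- matrix(1:4, 2, dimnames = list(c("p1", "p2"), c("c1", "c2")))
  path <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t2", "Name\tDescription\tc1\tc2",
               "p1\tGA\t1\t3", "p2\t\t2\t4"), path)
  expect_warning(scr <- read_gct(path), "no gene mapping")
  expect_equal(scr$probe_map$gene_id, c("GA", NA))
  expect_equal(nrow(scr$scores), 2)
})

test_that("gene tables are validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("G1", "G2"), coding_length_bp = c(1000, 4450),
    gene_class = c("known", "other_mutated"),
    origin_epoch = c("ancient", NA), duplicability = c("singleton", NA)), path)
  genes <- read_gene_table(path)
  expect_equal(genes$coding_length_bp, c(1000L, 4450L))
  expect_true(all(is.na(genes$n_cancer_types_mutated)))

  dup <- dplyr::bind_rows(genes, genes[1, ])
  expect_error(cohort_bundle(
    dup, tibble::tibble(sample_id = character(), gene_id = character()),
    tibble::tibble(context_id = character(), gene_id = character(),
                   call = character(), level = double()),
    igraph::make_empty_graph(directed = FALSE)), "duplicated gene_id")
})

test_that("cohort writers round-trip through the package readers", {
  co <- small_cohort(seed = 3, n_samples = 8, n_genes = 60)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  muts <- suppressMessages(read_mutation_table(
    file.path(dir, "mutations.tsv"), "simple"))
  expect_equal(dplyr::arrange(muts, sample_id, gene_id, mutation_class),
               dplyr::arrange(co$bundle$mutations, sample_id, gene_id,
                              mutation_class))
  genes <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(genes, co$bundle$genes)
  probes <- read_probe_detection(file.path(dir, "probes.tsv"))
  expect_equal(nrow(probes), nrow(co$probes))
  net <- read_network(file.path(dir, "network.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(co$bundle$network))
  scr <- read_gct(file.path(dir, "screen.gct"),
                  groups = readr::read_tsv(file.path(dir,
                                                     "screen_groups.tsv"),
                                           show_col_types = FALSE))
  expect_equal(scr$scores, co$screen$scores, tolerance = 1e-12)
})
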