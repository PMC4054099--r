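#' Read a somatic mutation table
#'
#' Reads non-synonymous somatic mutation calls in either a minimal MAF
#' dialect or a simple long format, and normalises them to one tidy record
#' per mutation. The MAF dialect requires `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification`; any further MAF
#' columns are ignored except the optional predictor-score columns
#' `sift_damage`, `polyphen`, `mutation_taster` and `conservation`. The
#' simple dialect uses the output column names directly.
#'
#' MAF variant classes are mapped to the internal vocabulary:
#' `Missense_Mutation` to `missense`, `Nonsense_Mutation` to `nonsense`,
#' `Frame_Shift_Ins`/`Frame_Shift_Del` to `frameshift`, `Splice_Site` to
#' `splice_site`, `Silent` to `synonymous`, anything else to `other`.
#' Exact duplicate rows are dropped (and counted in a message).
#'
#' @param path Path to a tab-separated mutation table.
#' @param dialect `"maf"` or `"simple"`.
#' @param sift_raw If `TRUE`, the SIFT column holds canonical SIFT scores
#'   (damaging near 0) and is converted to the damage-oriented scale used
#'   throughout the package via `1 - score`.
#' @return A tibble with columns `sample_id`, `gene_id`, `mutation_class`,
#'   `sift_damage_score`, `polyphen_score`, `mutation_taster_call`,
#'   `conservation_score`.
#' @export
read_mutation_table <- function(path, dialect = c("maf", "simple"),
                                sift_raw = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA", "."), comment = "#")
  if (dialect == "maf") {
    need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("mutation table is missing mandatory MAF column(s): ",
                   paste(miss, collapse = ", ")))
    }
    out <- tibble::tibble(
      sample_id = as.character(raw$Tumor_Sample_Barcode),
      gene_id = as.character(raw$Hugo_Symbol),
      mutation_class = map_maf_class(raw$Variant_Classification),
      sift_damage_score = num_col(raw, "sift_damage"),
      polyphen_score = num_col(raw, "polyphen"),
      mutation_taster_call = chr_col(raw, "mutation_taster"),
      conservation_score = num_col(raw, "conservation")
    )
  } else {
    need <- c("sample_id", "gene_id", "mutation_class")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(paste0("mutation table is missing mandatory column(s): ",
                   paste(miss, collapse = ", ")))
    }
    out <- tibble::tibble(
      sample_id = as.character(raw$sample_id),
      gene_id = as.character(raw$gene_id),
      mutation_class = check_mutation_class(raw$mutation_class),
      sift_damage_score = num_col(raw, "sift_damage_score"),
      polyphen_score = num_col(raw, "polyphen_score"),
      mutation_taster_call = chr_col(raw, "mutation_taster_call"),
      conservation_score = num_col(raw, "conservation_score")
    )
  }
  if (sift_raw) out$sift_damage_score <- 1 - out$sift_damage_score
  validate_unit_scores(out)
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n0) {
    inform(sprintf("read_mutation_table: dropped %d exact duplicate row(s); %d retained",
                   n0 - nrow(out), nrow(out)))
  }
  out
}

map_maf_class <- function(x) {
  lookup <- c(Missense_Mutation = "missense",
              Nonsense_Mutation = "nonsense",
              Frame_Shift_Ins = "frameshift",
              Frame_Shift_Del = "frameshift",
              Splice_Site = "splice_site",
              Silent = "synonymous")
  out <- unname(lookup[as.character(x)])
  out[is.na(out)] <- "other"
  out
}

mutation_classes <- c("missense", "nonsense", "frameshift", "splice_site",
                      "synonymous", "other")

check_mutation_class <- function(x) {
  x <- as.character(x)
  bad <- !x %in% mutation_classes
  if (any(bad)) {
    abort(paste0("unknown mutation_class value(s): ",
                 paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

num_col <- function(df, name) {
  if (name %in% names(df)) suppressWarnings(as.numeric(df[[name]])) else
    rep(NA_real_, nrow(df))
}

chr_col <- function(df, name) {
  if (name %in% names(df)) as.character(df[[name]]) else
    rep(NA_character_, nrow(df))
}

validate_unit_scores <- function(muts) {
  for (col in c("sift_damage_score", "polyphen_score", "conservation_score")) {
    x <- muts[[col]]
    bad <- which(!is.na(x) & (x < 0 | x > 1))
    if (length(bad) > 0) {
      abort(sprintf("%s outside [0,1] at row %d (value %g)",
                    col, bad[1], x[bad[1]]))
    }
  }
  mt <- muts$mutation_taster_call
  bad <- which(!is.na(mt) & !mt %in% c("disease_causing", "polymorphism"))
  if (length(bad) > 0) {
    abort(sprintf("mutation_taster_call must be disease_causing/polymorphism; got '%s' at row %d",
                  mt[bad[1]], bad[1]))
  }
  invisible(muts)
}

#' Write a mutation table in the simple dialect
#'
#' @param mutations Tibble as returned by [read_mutation_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(mutations, path) {
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' Read an undirected protein-interaction network from an edge list
#'
#' Reads a tab-separated edge list (first two columns are interacting gene
#' identifiers; further columns are ignored) into an undirected simple
#' graph. Duplicate edges in either orientation are collapsed and
#' self-loops are removed; both are counted in a message.
#'
#' @param path Path to the edge-list TSV (a header line is detected and
#'   skipped when the first line is `gene_a<TAB>gene_b`).
#' @return An undirected simple [igraph::graph] whose vertex names are the
#'   gene identifiers.
#' @export
read_network <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("network file is empty")
  if (identical(tolower(strsplit(lines[1], "\t")[[1]][1:2]),
                c("gene_a", "gene_b"))) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) abort("network file has no edges")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 2)
  if (length(short) > 0) {
    abort(sprintf("network line %d does not have two columns: '%s'",
                  short[1], lines[short[1]]))
  }
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, `[[`, "", 2)
  edges_to_network(a, b, context = "read_network")
}

# shared constructor: dedups either-orientation duplicates, drops self-loops
edges_to_network <- function(a, b, context = "network") {
  n_loops <- sum(a == b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (n_loops > 0 || any(dup)) {
    inform(sprintf("%s: removed %d self-loop(s) and %d duplicate edge(s)",
                   context, n_loops, sum(dup)))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup]), directed = FALSE)
  g
}

#' Write a network as a two-column edge list
#'
#' @param network An undirected [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- tibble::tibble(gene_a = el[, 1], gene_b = el[, 2])
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an shRNA screen from a GCT 1.2 file
#'
#' GCT 1.2 is a tab-delimited matrix format: a `#1.2` version line, a line
#' with row and column counts, then a header `Name`, `Description` and one
#' column per condition. `Name` holds the probe identifier; `Description`
#' holds the target gene (optionally overridden by `probe_map`). Probes
#' with no gene mapping are retained with a missing gene and a warning.
#'
#' @param path Path to the GCT file.
#' @param probe_map Optional tibble `(probe_id, gene_id)` overriding the
#'   Description column.
#' @param groups Optional tibble `(condition_id, group_id)` assigning each
#'   data column to a replicate group (see [shrna_screen()]).
#' @param reference_group Name of the initial DNA-pool group.
#' @return An `shrna_screen` object; see [shrna_screen()].
#' @export
read_gct <- function(path, probe_map = NULL, groups = NULL,
                     reference_group = "DNA") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    abort("not a GCT 1.2 file: first line must be '#1.2'")
  }
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]][1:2]))
  if (anyNA(dims)) abort("GCT dimension line is malformed")
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "Name" || header[2] != "Description") {
    abort("GCT header must start with Name<TAB>Description")
  }
  conditions <- header[-(1:2)]
  if (length(conditions) != dims[2]) {
    abort(sprintf("GCT declares %d data columns but header has %d",
                  dims[2], length(conditions)))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != dims[1]) {
    abort(sprintf("GCT declares %d rows but file has %d", dims[1],
                  length(body)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- vapply(parts, length, 1L)
  if (any(nfield != length(header))) {
    abort(sprintf("GCT row %d has %d fields, expected %d",
                  which(nfield != length(header))[1],
                  nfield[nfield != length(header)][1], length(header)))
  }
  probe_id <- vapply(parts, `[[`, "", 1)
  descr <- vapply(parts, `[[`, "", 2)
  scores <- matrix(
    suppressWarnings(as.numeric(unlist(lapply(parts, `[`, -(1:2))))),
    nrow = dims[1], ncol = dims[2], byrow = TRUE,
    dimnames = list(probe_id, conditions))
  if (is.null(probe_map)) {
    gene <- ifelse(nzchar(descr) & descr != "NA", descr, NA_character_)
  } else {
    gene <- probe_map$gene_id[match(probe_id, probe_map$probe_id)]
  }
  if (anyNA(gene)) {
    warn(sprintf("read_gct: %d probe(s) have no gene mapping and are retained with gene = NA",
                 sum(is.na(gene))))
  }
  shrna_screen(scores, tibble::tibble(probe_id = probe_id, gene_id = gene),
               groups = groups, reference_group = reference_group)
}

#' Write an shRNA screen to a GCT 1.2 file
#'
#' @param screen An `shrna_screen` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(screen, path) {
  m <- screen$scores
  descr <- screen$probe_map$gene_id[match(rownames(m), screen$probe_map$probe_id)]
  descr[is.na(descr)] <- ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(m), ncol(m), sep = "\t"), con)
  writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = "\t"))
  writeLines(paste(rownames(m), descr, body, sep = "\t"), con)
  invisible(path)
}

#' Read a long probe detection table
#'
#' Expects tab-separated columns `probe_id`, `gene_id`, `context_id`
#' (tissue or tumour sample) and `detection_p`, plus an optional `level`
#' column carrying a probe expression level.
#'
#' @param path Path to the TSV file.
#' @return A tibble with those columns (`level` always present, `NA` when
#'   absent from the file).
#' @export
read_probe_detection <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("probe_id", "gene_id", "context_id", "detection_p")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("probe detection table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!is.na(raw$detection_p) &
                 (raw$detection_p < 0 | raw$detection_p > 1))
  if (length(bad) > 0) {
    abort(sprintf("detection_p outside [0,1] at row %d", bad[1]))
  }
  tibble::tibble(
    probe_id = as.character(raw$probe_id),
    gene_id = as.character(raw$gene_id),
    context_id = as.character(raw$context_id),
    detection_p = as.numeric(raw$detection_p),
    level = num_col(raw, "level")
  )
}

#' Read a per-gene annotation table
#'
#' Expects tab-separated columns `gene_id`, `coding_length_bp`,
#' `gene_class`, and optionally `symbol`, `origin_epoch`, `duplicability`
#' and `n_cancer_types_mutated`. `coding_length_bp` is the coding portion
#' of the longest isoform; `origin_epoch` is the most ancient clade where
#' orthologs are found; `duplicability` records whether the gene has a
#' human paralog.
#'
#' @param path Path to the TSV file.
#' @return A gene tibble with all seven columns.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "coding_length_bp", "gene_class")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("gene table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  out <- tibble::tibble(
    gene_id = as.character(raw$gene_id),
    symbol = if ("symbol" %in% names(raw)) as.character(raw$symbol) else
      as.character(raw$gene_id),
    coding_length_bp = as.integer(raw$coding_length_bp),
    gene_class = as.character(raw$gene_class),
    origin_epoch = chr_col(raw, "origin_epoch"),
    duplicability = chr_col(raw, "duplicability"),
    n_cancer_types_mutated = if ("n_cancer_types_mutated" %in% names(raw))
      as.integer(raw$n_cancer_types_mutated) else rep(NA_integer_, nrow(raw))
  )
  validate_gene_table(out)
}

origin_epochs <- c("ancient", "eukaryota", "metazoa", "vertebrata",
                   "mammalia", "recent")
gene_classes <- c("known", "candidate", "other_mutated", "non_mutated")

validate_gene_table <- function(genes) {
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicated gene_id in gene table: %s",
                  genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  if (any(is.na(genes$coding_length_bp) | genes$coding_length_bp < 1)) {
    abort("coding_length_bp must be a positive integer for every gene")
  }
  bad <- !genes$gene_class %in% gene_classes
  if (any(bad)) {
    abort(sprintf("unknown gene_class '%s'", genes$gene_class[bad][1]))
  }
  bad <- !is.na(genes$origin_epoch) & !genes$origin_epoch %in% origin_epochs
  if (any(bad)) {
    abort(sprintf("unknown origin_epoch '%s'", genes$origin_epoch[bad][1]))
  }
  bad <- !is.na(genes$duplicability) &
    !genes$duplicability %in% c("singleton", "duplicated")
  if (any(bad)) {
    abort(sprintf("unknown duplicability '%s'", genes$duplicability[bad][1]))
  }
  genes
}

#' Assemble a cohort bundle
#'
#' Bundles the per-gene annotation, the mutation table, the expression call
#' matrix, the interaction network, the set of known cancer genes and the
#' sample-to-cancer-type map into one validated object consumed by
#' [run_pipeline()]. Mutated genes missing from the annotation are flagged
#' (they later fail the cascade as `unannotated`); expression contexts that
#' match no mutated sample are ignored with a warning.
#'
#' @param genes Gene tibble (see [read_gene_table()]).
#' @param mutations Mutation tibble (see [read_mutation_table()]).
#' @param expression Expression call tibble from [call_expression()], with
#'   columns `context_id`, `gene_id`, `call`, `level`; contexts are tumour
#'   sample identifiers.
#' @param network Undirected [igraph::graph] of protein interactions.
#' @param known_cancer_set Character vector of known cancer gene ids; by
#'   default the genes with `gene_class == "known"`.
#' @param sample_to_cancer_type Named character vector or two-column tibble
#'   `(sample_id, cancer_type)`; optional (a single `"unspecified"` type is
#'   assumed when absent).
#' @return A `cohort_bundle` list.
#' @export
cohort_bundle <- function(genes, mutations, expression, network,
                          known_cancer_set = NULL,
                          sample_to_cancer_type = NULL) {
  genes <- validate_gene_table(genes)
  if (is.null(known_cancer_set)) {
    known_cancer_set <- genes$gene_id[genes$gene_class == "known"]
  }
  if (is.data.frame(sample_to_cancer_type)) {
    sample_to_cancer_type <- setNames(
      as.character(sample_to_cancer_type$cancer_type),
      sample_to_cancer_type$sample_id)
  }
  if (is.null(sample_to_cancer_type)) {
    sample_to_cancer_type <- setNames(
      rep("unspecified", length(unique(mutations$sample_id))),
      unique(mutations$sample_id))
  }
  unannot <- setdiff(unique(mutations$gene_id), genes$gene_id)
  if (length(unannot) > 0) {
    inform(sprintf("cohort_bundle: %d mutated gene(s) lack annotation and will fail the cascade as 'unannotated'",
                   length(unannot)))
  }
  orphan <- setdiff(unique(expression$context_id), unique(mutations$sample_id))
  if (length(orphan) > 0) {
    warn(sprintf("cohort_bundle: %d expression context(s) have no mutated sample and are ignored",
                 length(orphan)))
  }
  structure(list(genes = genes,
                 mutations = mutations,
                 expression = expression,
                 network = network,
                 known_cancer_set = known_cancer_set,
                 sample_to_cancer_type = sample_to_cancer_type),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  genes:      %d (%d known cancer genes)\n",
              nrow(x$genes), length(x$known_cancer_set)))
  cat(sprintf("  mutations:  %d in %d samples\n", nrow(x$mutations),
              length(unique(x$mutations$sample_id))))
  cat(sprintf("  expression: %d contexts x %d genes\n",
              length(unique(x$expression$context_id)),
              length(unique(x$expression$gene_id))))
  cat(sprintf("  network:    %d nodes, %d edges\n",
              igraph::vcount(x$network), igraph::ecount(x$network)))
  invisible(x)
}
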