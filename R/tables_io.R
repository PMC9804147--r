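#' Threshold and procedure configuration
#'
#' Bundles every tunable threshold used across the pipeline.  Defaults follow
#' the study conventions for this kind of analysis: a log2 fold-change
#' threshold of 0.25 and FDR < 0.05 for DEG calling, a raw-p fallback when a
#' model yields fewer than 10 FDR-significant DEGs, Seurat-style single-cell
#' QC bounds (genes in >= 3 cells; cells with 200--7500 expressed genes and
#' <= 10% mitochondrial reads), depth normalization to 10,000 transcripts per
#' cell, and the burden procedure's strict >10-cells-per-sample cluster
#' eligibility with 10 downsampling iterations.
#'
#' @param lfc_min log2 fold-change threshold; DEGs must exceed it strictly.
#' @param fdr_max BH-adjusted p cutoff (strict).
#' @param min_pct minimum fraction of cells expressing a gene for it to be
#'   tested by the single-cell DE engine.
#' @param fallback_min_degs if a table has fewer than this many FDR DEGs,
#'   DEG calling falls back to raw p-values.
#' @param fallback_p raw-p cutoff used in fallback mode.
#' @param qc_min_cells_per_gene,qc_min_genes_per_cell,qc_max_genes_per_cell,qc_max_mito_frac
#'   single-cell QC bounds.
#' @param norm_scale per-cell depth target for log normalization.
#' @param burden_min_cells cluster eligibility: a cluster must have strictly
#'   more than this many cells in every sample.
#' @param burden_k cells to downsample each (cluster, sample) to; `"auto"`
#'   uses the minimum eligible cluster-sample count.
#' @param burden_iters number of downsampling iterations averaged.
#' @return An object of class `threshold_config` (a validated list).
#' @export
threshold_config <- function(lfc_min = 0.25, fdr_max = 0.05, min_pct = 0.05,
                             fallback_min_degs = 10L, fallback_p = 0.05,
                             qc_min_cells_per_gene = 3L,
                             qc_min_genes_per_cell = 200L,
                             qc_max_genes_per_cell = 7500L,
                             qc_max_mito_frac = 0.10,
                             norm_scale = 10000,
                             burden_min_cells = 10L,
                             burden_k = "auto",
                             burden_iters = 10L) {
  cfg <- list(lfc_min = lfc_min, fdr_max = fdr_max, min_pct = min_pct,
              fallback_min_degs = as.integer(fallback_min_degs),
              fallback_p = fallback_p,
              qc_min_cells_per_gene = as.integer(qc_min_cells_per_gene),
              qc_min_genes_per_cell = as.integer(qc_min_genes_per_cell),
              qc_max_genes_per_cell = as.integer(qc_max_genes_per_cell),
              qc_max_mito_frac = qc_max_mito_frac,
              norm_scale = norm_scale,
              burden_min_cells = as.integer(burden_min_cells),
              burden_k = if (identical(burden_k, "auto")) "auto" else as.integer(burden_k),
              burden_iters = as.integer(burden_iters))
  num <- cfg[!names(cfg) %in% "burden_k"]
  if (any(vapply(num, function(x) !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0, logical(1))))
    stop("all configuration values must be positive finite scalars", call. = FALSE)
  for (f in c("fdr_max", "fallback_p", "min_pct", "qc_max_mito_frac"))
    if (cfg[[f]] >= 1) stop(sprintf("'%s' must lie in (0,1)", f), call. = FALSE)
  if (!identical(cfg$burden_k, "auto") && cfg$burden_k <= 0L)
    stop("'burden_k' must be positive or \"auto\"", call. = FALSE)
  structure(cfg, class = "threshold_config")
}

#' Read / write a threshold configuration as a flat key-value file
#'
#' The file holds one `key<TAB>value` pair per line, keys matching the
#' [threshold_config()] arguments.  Missing keys take their defaults.
#'
#' @param path file path.
#' @return For `read_threshold_config`, a `threshold_config`.
#' @export
read_threshold_config <- function(path) {
  kv <- read.delim(path, header = FALSE, col.names = c("key", "value"),
                   colClasses = "character", strip.white = TRUE)
  if (anyDuplicated(kv$key)) stop("duplicate configuration key", call. = FALSE)
  args <- lapply(seq_len(nrow(kv)), function(i) {
    v <- kv$value[i]
    if (kv$key[i] == "burden_k" && v == "auto") "auto" else as.numeric(v)
  })
  names(args) <- kv$key
  unknown <- setdiff(names(args), names(formals(threshold_config)))
  if (length(unknown))
    stop("unknown configuration key: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(threshold_config, args)
}

#' @rdname read_threshold_config
#' @param cfg a `threshold_config`.
#' @export
write_threshold_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "threshold_config"))
  df <- data.frame(key = names(cfg),
                   value = vapply(cfg, function(x) as.character(x), character(1)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a differential-expression result table
#'
#' A `de_table` holds one model's gene-level DE results (log2 fold change in
#' mutant-vs-control orientation, raw p, BH-adjusted p) together with the
#' model's tested-gene universe -- the genes that passed its testing filter
#' (e.g. total reads > 10 for bulk samples).  The universe, not the record
#' set, defines the background population for overlap enrichment.
#'
#' @param records data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @param universe character vector of gene ids; defaults to the table's own
#'   genes when not supplied.
#' @param model_id,species optional labels carried through reports.
#' @return An object of class `de_table` with elements `records`, `universe`,
#'   `model_id`, `species`.
#' @export
de_table <- function(records, universe = NULL, model_id = "model",
                     species = NA_character_) {
  req <- c("gene", "log2fc", "pvalue", "fdr")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("DE table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records <- as.data.frame(records)
  records <- records[c(req, setdiff(names(records), req))]
  records$gene <- as.character(records$gene)
  bad <- !is.finite(records$log2fc) |
    !is.finite(records$pvalue) | records$pvalue < 0 | records$pvalue > 1
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-finite log2fc or p outside [0,1] rejected",
            call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  if (anyDuplicated(records$gene))
    stop("duplicate gene id in DE table: ",
         records$gene[duplicated(records$gene)][1L], call. = FALSE)
  universe <- if (is.null(universe)) records$gene else unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  outside <- setdiff(records$gene, universe)
  if (length(outside))
    stop(length(outside), " record gene(s) absent from the stated universe, e.g. ",
         outside[1L], call. = FALSE)
  structure(list(records = records, universe = universe,
                 model_id = model_id, species = species),
            class = "de_table")
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("de_table '%s'%s: %d records, universe of %d genes\n",
              x$model_id,
              if (is.na(x$species)) "" else paste0(" (", x$species, ")"),
              nrow(x$records), length(x$universe)))
  print(head(x$records, 4L))
  invisible(x)
}

#' Read a DE table (TSV) with an optional universe file
#'
#' The TSV must carry header columns `gene`, `log2fc`, `pvalue`, `fdr`
#' (tab-separated, "." decimal, unquoted ids).  The universe file lists one
#' gene id per line; when absent the universe defaults to the table's genes.
#'
#' @inheritParams de_table
#' @param path TSV path.
#' @param universe_path optional path to the universe file.
#' @return A [de_table()].
#' @export
read_de_table <- function(path, universe_path = NULL, model_id = NULL,
                          species = NA_character_) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  universe <- if (!is.null(universe_path)) readLines(universe_path) else NULL
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  de_table(df, universe = universe, model_id = model_id, species = species)
}

#' @rdname read_de_table
#' @param x a `de_table`.
#' @export
write_de_table <- function(x, path, universe_path = NULL) {
  stopifnot(inherits(x, "de_table"))
  write.table(x$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(universe_path)) writeLines(x$universe, universe_path)
  invisible(path)
}

#' Construct / read an ortholog map
#'
#' Two-column correspondence between gene identifiers of two models (for a
#' cross-species comparison, e.g. human symbols to mouse symbols).  Maps are
#' restricted to 1:1 pairs: any source or target id occurring in more than
#' one pair is dropped entirely, with a message reporting the count, so that
#' no gene is double-counted in the overlap contingency tables.
#'
#' @param pairs data.frame (or 2-column matrix) with columns `source_id`,
#'   `target_id`.
#' @return An object of class `ortholog_map`: a data.frame of 1:1 pairs.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) != 2L) stop("ortholog map needs exactly two columns", call. = FALSE)
  names(pairs) <- c("source_id", "target_id")
  pairs$source_id <- as.character(pairs$source_id)
  pairs$target_id <- as.character(pairs$target_id)
  pairs <- unique(pairs)
  multi <- pairs$source_id %in% pairs$source_id[duplicated(pairs$source_id)] |
    pairs$target_id %in% pairs$target_id[duplicated(pairs$target_id)]
  if (any(multi)) {
    message(sum(multi), " non-1:1 ortholog pair(s) dropped")
    pairs <- pairs[!multi, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(pairs, class = c("ortholog_map", "data.frame"))
}

#' @rdname ortholog_map
#' @param path two-column TSV (header optional: detected by a `source_id`
#'   first field).
#' @export
read_ortholog_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- identical(strsplit(first, "\t")[[1L]][1L], "source_id")
  df <- read.delim(path, header = has_header, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  ortholog_map(df)
}

#' @rdname ortholog_map
#' @param map an `ortholog_map`.
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "ortholog_map"))
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Heuristic human/mouse symbol map
#'
#' Matches identifiers by case-insensitive equality, the usual relationship
#' between human (upper-case, `CDKN1A`) and mouse (title-case, `Cdkn1a`)
#' gene symbols, then restricts to 1:1 matches.  Identifiers that collide
#' case-insensitively on either side are dropped.  This is a stand-in for a
#' curated ortholog table, which should be preferred when available.
#'
#' @param human_ids,mouse_ids character vectors of symbols.
#' @return An [ortholog_map()] with human ids as sources.
#' @export
default_symbol_map <- function(human_ids, mouse_ids) {
  human_ids <- unique(as.character(human_ids))
  mouse_ids <- unique(as.character(mouse_ids))
  if (!length(human_ids) || !length(mouse_ids))
    return(ortholog_map(data.frame(source_id = character(),
                                   target_id = character())))
  hk <- toupper(human_ids); mk <- toupper(mouse_ids)
  keep_h <- !hk %in% hk[duplicated(hk)]
  keep_m <- !mk %in% mk[duplicated(mk)]
  h <- human_ids[keep_h]; hk <- hk[keep_h]
  m <- mouse_ids[keep_m]; mk <- mk[keep_m]
  idx <- match(hk, mk)
  hit <- !is.na(idx)
  ortholog_map(data.frame(source_id = h[hit], target_id = m[idx[hit]],
                          stringsAsFactors = FALSE))
}

#' Construct an annotated cell matrix
#'
#' Genes x cells counts with per-cell sample, line and cluster labels; the
#' container consumed by QC, normalization, the DE engine, and the burden
#' and composition procedures.  Counts are stored sparse.
#'
#' @param counts genes x cells matrix of non-negative integers (dense or
#'   `Matrix` sparse); rownames are gene ids, colnames cell ids.
#' @param cell_meta data.frame with columns `cell_id`, `sample_id`,
#'   `line_id`, `cluster_label`, one row per column of `counts`.
#' @param normalized optional genes x cells real-valued layer.
#' @return An object of class `cell_matrix` with elements `counts`,
#'   `gene_ids`, `cell_meta` and optionally `normalized`.
#' @export
cell_matrix <- function(counts, cell_meta, normalized = NULL) {
  counts <- if (inherits(counts, "Matrix"))
    as(as(counts, "generalMatrix"), "CsparseMatrix") else
      Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  if (is.null(rownames(counts))) stop("counts must carry gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids", call. = FALSE)
  v <- counts@x
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  cell_meta <- as.data.frame(cell_meta)
  req <- c("cell_id", "sample_id", "line_id", "cluster_label")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss))
    stop("cell metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cell_meta <- cell_meta[req]
  for (f in req) cell_meta[[f]] <- as.character(cell_meta[[f]])
  if (nrow(cell_meta) != ncol(counts))
    stop(sprintf("metadata rows (%d) do not match matrix columns (%d)",
                 nrow(cell_meta), ncol(counts)), call. = FALSE)
  if (anyDuplicated(cell_meta$cell_id)) stop("duplicate cell ids", call. = FALSE)
  if (anyNA(cell_meta) || any(cell_meta == ""))
    stop("every cell needs sample, line and cluster labels", call. = FALSE)
  colnames(counts) <- cell_meta$cell_id
  rownames(cell_meta) <- NULL
  if (!is.null(normalized) &&
      !identical(dim(normalized), dim(counts)))
    stop("normalized layer dimensions differ from counts", call. = FALSE)
  structure(list(counts = counts, gene_ids = rownames(counts),
                 cell_meta = cell_meta, normalized = normalized),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf(paste0("cell_matrix: %d genes x %d cells | %d sample(s), ",
                     "%d line(s), %d cluster(s)%s\n"),
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$line_id)),
              length(unique(x$cell_meta$cluster_label)),
              if (is.null(x$normalized)) "" else " | normalized layer present"))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Subset a cell matrix by cells (and optionally genes)
#'
#' @param m a `cell_matrix`.
#' @param cells character cell ids or logical/integer index over columns.
#' @param genes optional gene ids or index over rows.
#' @return A `cell_matrix` restricted to the selection; the normalized layer,
#'   if present, is subset alongside.
#' @export
subset_cells <- function(m, cells, genes = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  j <- if (is.character(cells)) match(cells, m$cell_meta$cell_id) else
    seq_len(ncol(m$counts))[cells]
  if (anyNA(j)) stop("unknown cell id in selection", call. = FALSE)
  i <- if (is.null(genes)) seq_len(nrow(m$counts)) else
    if (is.character(genes)) match(genes, m$gene_ids) else
      seq_len(nrow(m$counts))[genes]
  if (anyNA(i)) stop("unknown gene id in selection", call. = FALSE)
  cell_matrix(m$counts[i, j, drop = FALSE],
              m$cell_meta[j, , drop = FALSE],
              normalized = if (is.null(m$normalized)) NULL else
                m$normalized[i, j, drop = FALSE])
}

#' Read / write an annotated count matrix
#'
#' Counts travel as a Matrix Market coordinate file with two TSV sidecars:
#' `genes_path` (column `gene_id`) and `cells_path` (columns `cell_id`,
#' `sample_id`, `line_id`, `cluster_label`).  `write_counts()` followed by
#' `read_counts()` reproduces the matrix exactly.
#'
#' @param mtx_path,genes_path,cells_path file paths.
#' @return A [cell_matrix()].
#' @export
read_counts <- function(mtx_path, genes_path, cells_path) {
  mm <- Matrix::readMM(mtx_path)
  genes <- read.delim(genes_path, header = TRUE, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes))
    stop("gene sidecar must have a 'gene_id' column", call. = FALSE)
  cells <- read.delim(cells_path, header = TRUE, stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(mm))
    stop(sprintf("gene sidecar has %d rows for a %d-row matrix",
                 nrow(genes), nrow(mm)), call. = FALSE)
  if (nrow(cells) != ncol(mm))
    stop(sprintf("cell sidecar has %d rows for a %d-column matrix",
                 nrow(cells), ncol(mm)), call. = FALSE)
  rownames(mm) <- genes$gene_id
  cell_matrix(mm, cells)
}

#' @rdname read_counts
#' @param m a `cell_matrix`.
#' @export
write_counts <- function(m, mtx_path, genes_path, cells_path) {
  stopifnot(inherits(m, "cell_matrix"))
  Matrix::writeMM(m$counts, mtx_path)
  write.table(data.frame(gene_id = m$gene_ids), genes_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$cell_meta, cells_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(mtx_path)
}
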