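#' Choose the p-value column for DEG calling
#'
#' Low-powered comparisons that yield fewer than `fallback_min_degs` genes at
#' `fdr < fdr_max` (with the fold-change magnitude filter `|log2fc| >
#' lfc_min` applied) fall back to unadjusted p-values at `fallback_p`,
#' trading specificity for sensitivity in downstream cross-model overlap.
#'
#' @param table a [de_table()].
#' @param cfg a [threshold_config()].
#' @return `"fdr"` or `"raw"`.
#' @export
effective_p_mode <- function(table, cfg = threshold_config()) {
  stopifnot(inherits(table, "de_table"))
  r <- table$records
  n_fdr <- sum(r$fdr < cfg$fdr_max & abs(r$log2fc) > cfg$lfc_min)
  if (n_fdr < cfg$fallback_min_degs) "raw" else "fdr"
}

#' Extract a direction-specific DEG set
#'
#' Genes with `log2fc > lfc_min` (up) or `log2fc < -lfc_min` (down) and a
#' significance value below the cutoff of the table's effective p mode
#' ([effective_p_mode()]).  All inequalities are strict, so a gene sitting
#' exactly on a threshold is excluded.
#'
#' @inheritParams effective_p_mode
#' @param direction `"up"` or `"down"`.
#' @return An object of class `deg_set`: list with `direction`, `genes`,
#'   `source_model`, `p_mode` and the `thresholds` used.
#' @export
extract_degs <- function(table, direction = c("up", "down"),
                         cfg = threshold_config()) {
  stopifnot(inherits(table, "de_table"))
  direction <- match.arg(direction)
  p_mode <- effective_p_mode(table, cfg)
  p_cut <- if (p_mode == "fdr") cfg$fdr_max else cfg$fallback_p
  r <- table$records
  pvals <- if (p_mode == "fdr") r$fdr else r$pvalue
  keep <- pvals < p_cut &
    if (direction == "up") r$log2fc > cfg$lfc_min else r$log2fc < -cfg$lfc_min
  structure(list(direction = direction, genes = r$gene[keep],
                 source_model = table$model_id, p_mode = p_mode,
                 thresholds = c(lfc_min = cfg$lfc_min, p_cut = p_cut)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set: %d %sregulated genes from '%s' (p_mode=%s, |log2fc|>%g, p<%g)\n",
              length(x$genes), x$direction, x$source_model, x$p_mode,
              x$thresholds["lfc_min"], x$thresholds["p_cut"]))
  invisible(x)
}

#' DEGs replicated across two tables
#'
#' The two-line intersection rule: a gene counts as up (down) only if it
#' passes the up (down) thresholds in both tables.  A gene up in one table
#' and down in the other therefore appears in neither output set.  The rule
#' is symmetric in its two arguments.
#'
#' @param table_a,table_b [de_table()]s sharing an id space.
#' @inheritParams effective_p_mode
#' @return list with `up` and `down` [extract_degs()]-style `deg_set`s whose
#'   `source_model` names both tables.
#' @export
shared_degs <- function(table_a, table_b, cfg = threshold_config()) {
  stopifnot(inherits(table_a, "de_table"), inherits(table_b, "de_table"))
  if (!length(intersect(table_a$universe, table_b$universe)))
    warning("tables have disjoint universes; shared DEG sets are empty",
            call. = FALSE)
  lab <- paste(table_a$model_id, table_b$model_id, sep = "+")
  out <- lapply(c(up = "up", down = "down"), function(d) {
    a <- extract_degs(table_a, d, cfg)
    b <- extract_degs(table_b, d, cfg)
    structure(list(direction = d, genes = intersect(a$genes, b$genes),
                   source_model = lab,
                   p_mode = paste(a$p_mode, b$p_mode, sep = "+"),
                   thresholds = a$thresholds),
              class = "deg_set")
  })
  out
}
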