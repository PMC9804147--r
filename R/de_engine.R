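#' Group log2 fold change of depth-corrected means
#'
#' Effect size used by the internal DE engine: `log2((mA + 1) / (mB + 1))`
#' where `mA`, `mB` are each group's mean depth-corrected expression
#' (`expm1` of the normalized layer, i.e. counts per `norm_scale`).  The
#' +1 pseudocounts bound the statistic for genes absent from one group;
#' swapping the groups negates the value.
#'
#' @param m a normalized [cell_matrix()].
#' @param cells_a,cells_b character cell ids or column indices.
#' @return Named numeric vector, one value per gene.
#' @export
log2fc_means <- function(m, cells_a, cells_b) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$normalized))
    stop("normalized layer absent; run normalize_cells() first", call. = FALSE)
  ja <- .cell_index(m, cells_a)
  jb <- .cell_index(m, cells_b)
  ma <- .expm1_rowmeans(m$normalized, ja)
  mb <- .expm1_rowmeans(m$normalized, jb)
  setNames(log2((ma + 1) / (mb + 1)), m$gene_ids)
}

.cell_index <- function(m, cells) {
  j <- if (is.character(cells)) match(cells, m$cell_meta$cell_id) else
    seq_len(ncol(m$counts))[cells]
  if (anyNA(j) || !length(j)) stop("unknown or empty cell selection", call. = FALSE)
  j
}

.expm1_rowmeans <- function(norm, j) {
  sub <- norm[, j, drop = FALSE]
  sub@x <- expm1(sub@x)
  Matrix::rowMeans(sub)
}

#' Two-sided rank-sum test
#'
#' The engine's per-gene test.  When both groups have at most 8 values the
#' p-value is exact: all `choose(nA + nB, nA)` group labelings are
#' enumerated and the two-sided p is the fraction of labelings whose
#' rank-sum deviates from its mean at least as much as the observed one
#' (average ranks, so ties are handled exactly).  Larger groups use the
#' normal approximation with tie correction and a 0.5 continuity
#' correction.  Degenerate all-tied input gives `p = 1`.
#'
#' @param a,b numeric vectors, at least one value each.
#' @return Two-sided p-value.
#' @export
rank_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both groups need at least one value", call. = FALSE)
  n <- na + nb
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (na <= 8L && nb <= 8L) {
    cmb <- utils::combn(n, na)
    w_all <- colSums(matrix(r[cmb], nrow = na))
    return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-max(z, 0)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; adjusted values are
#' elementwise at least the raw values and capped at 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) && (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0,1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Rank-based differential expression between two cell groups
#'
#' A self-contained DE engine over the normalized layer, used by the burden
#' procedure and for line-vs-control calls on synthetic data.  Genes are
#' pre-filtered: only genes expressed (count > 0) in at least `min_pct` of
#' the cells of the better-covered group form the tested universe, and of
#' those only genes whose [log2fc_means()] magnitude strictly exceeds
#' `lfc_min` are tested (mirroring the fold-change-threshold semantics of
#' marker-gene engines; genes failing it are reported untested).  Each
#' surviving gene gets a [rank_test()] p over the normalized values.  BH
#' adjustment is applied to the tested p-values with the universe size (the
#' number of `min_pct`-passing genes) as the number of tests: the
#' fold-change pre-filter selects genes whose p-values are conditionally
#' small, and adjusting only across the survivors would not control the
#' false discovery rate on null data (production marker-gene tools correct
#' over all genes for the same reason).
#'
#' This is a deliberately simple within-dataset engine; it does not fit the
#' hurdle models with latent covariates that production single-cell DE tools
#' use, and externally produced DE tables can be substituted anywhere a
#' [de_table()] is accepted.
#'
#' @param m a normalized [cell_matrix()].
#' @param cells_a,cells_b disjoint non-empty cell selections; log2 fold
#'   changes are oriented A vs B (positive = higher in A).
#' @param cfg a [threshold_config()].
#' @return A [de_table()] whose records carry `pct_a` and `pct_b` (fractions
#'   of expressing cells) and whose universe is the `min_pct`-passing genes.
#' @export
run_de <- function(m, cells_a, cells_b, cfg = threshold_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  if (is.null(m$normalized))
    stop("normalized layer absent; run normalize_cells() first", call. = FALSE)
  ja <- .cell_index(m, cells_a)
  jb <- .cell_index(m, cells_b)
  if (length(intersect(ja, jb))) stop("cell groups must be disjoint", call. = FALSE)
  pct_a <- Matrix::rowMeans(m$counts[, ja, drop = FALSE] > 0)
  pct_b <- Matrix::rowMeans(m$counts[, jb, drop = FALSE] > 0)
  in_universe <- pmax(pct_a, pct_b) >= cfg$min_pct
  if (!any(in_universe)) stop("no gene passes the min_pct filter", call. = FALSE)
  lfc <- log2fc_means(m, ja, jb)
  tested <- in_universe & abs(lfc) > cfg$lfc_min
  genes <- m$gene_ids[tested]
  if (length(genes)) {
    vals <- as.matrix(m$normalized[tested, c(ja, jb), drop = FALSE])
    ia <- seq_along(ja)
    p <- apply(vals, 1L, function(v) rank_test(v[ia], v[-ia]))
  } else p <- numeric(0)
  records <- data.frame(gene = genes, log2fc = unname(lfc[tested]),
                        pvalue = unname(p),
                        fdr = p.adjust(unname(p), method = "BH",
                                       n = sum(in_universe)),
                        pct_a = unname(pct_a[tested]),
                        pct_b = unname(pct_b[tested]),
                        stringsAsFactors = FALSE)
  de_table(records, universe = m$gene_ids[in_universe],
           model_id = "rank_de")
}
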