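#' Join two DE tables through an ortholog map
#'
#' Builds the joint background universe for a cross-model comparison: the
#' ortholog pairs whose members were tested (i.e. belong to the universe) in
#' both models.  Pairs where both tables also carry a result record are
#' returned as joined records holding both log2 fold changes and both
#' p-value columns.
#'
#' @param table_a,table_b [de_table()]s; `table_a` ids are the map sources.
#' @param map an [ortholog_map()] (1:1).  For tables sharing one id space,
#'   use an identity map or [identity_map()].
#' @return An object of class `ortholog_join`: list with `universe_pairs`
#'   (data.frame `gene_a`, `gene_b`), `records` (joined data.frame), and the
#'   two model ids.
#' @export
join_on_orthologs <- function(table_a, table_b, map) {
  stopifnot(inherits(table_a, "de_table"), inherits(table_b, "de_table"),
            inherits(map, "ortholog_map"))
  keep <- map$source_id %in% table_a$universe &
    map$target_id %in% table_b$universe
  pairs <- data.frame(gene_a = map$source_id[keep],
                      gene_b = map$target_id[keep],
                      stringsAsFactors = FALSE)
  if (!nrow(pairs))
    stop("empty joint universe: no ortholog pair tested in both models",
         call. = FALSE)
  ia <- match(pairs$gene_a, table_a$records$gene)
  ib <- match(pairs$gene_b, table_b$records$gene)
  hit <- !is.na(ia) & !is.na(ib)
  ra <- table_a$records[ia[hit], , drop = FALSE]
  rb <- table_b$records[ib[hit], , drop = FALSE]
  records <- data.frame(gene_a = pairs$gene_a[hit], gene_b = pairs$gene_b[hit],
                        log2fc_a = ra$log2fc, pvalue_a = ra$pvalue, fdr_a = ra$fdr,
                        log2fc_b = rb$log2fc, pvalue_b = rb$pvalue, fdr_b = rb$fdr,
                        stringsAsFactors = FALSE)
  structure(list(universe_pairs = pairs, records = records,
                 model_a = table_a$model_id, model_b = table_b$model_id),
            class = "ortholog_join")
}

#' @export
print.ortholog_join <- function(x, ...) {
  cat(sprintf("ortholog_join %s ~ %s: joint universe of %d pairs, %d joined records\n",
              x$model_a, x$model_b, nrow(x$universe_pairs), nrow(x$records)))
  invisible(x)
}

#' Identity ortholog map over a set of ids
#'
#' @param ids character vector.
#' @return An [ortholog_map()] mapping each id to itself.
#' @export
identity_map <- function(ids) {
  ids <- unique(as.character(ids))
  ortholog_map(data.frame(source_id = ids, target_id = ids,
                          stringsAsFactors = FALSE))
}

.deg_genes <- function(x) if (inherits(x, "deg_set")) x$genes else as.character(x)
.deg_dir <- function(x, default) if (inherits(x, "deg_set")) x$direction else default

#' Overlap contingency table of two DEG sets over a joint universe
#'
#' Counts `n11` (genes in both sets), `n10` (model A only), `n01` (model B
#' only) and `n00` (neither) over the joint universe; both sets are
#' intersected with the universe before counting.  `n00` is the standard
#' complement `U - (union)`.  With `literal = TRUE` the fourth cell is
#' instead everything not in set B (`U - |B|`), a non-standard construction
#' kept only for comparison; its rows then double-count and `U` no longer
#' equals the cell sum.
#'
#' @param degs_a,degs_b [extract_degs()] `deg_set`s (or plain character
#'   vectors) for models A and B.
#' @param universe character vector of ids (sets share one id space) or an
#'   [join_on_orthologs()] `ortholog_join`, in which case `degs_b` is
#'   translated into A's id space through the universe pairs.
#' @param literal use the literal non-standard fourth cell (see above).
#' @return An object of class `quadrant_table`: list with `n11`, `n10`,
#'   `n01`, `n00`, `U` and the direction-pair `label`.
#' @export
quadrant_counts <- function(degs_a, degs_b, universe, literal = FALSE) {
  a <- .deg_genes(degs_a)
  b <- .deg_genes(degs_b)
  if (inherits(universe, "ortholog_join")) {
    pairs <- universe$universe_pairs
    b <- pairs$gene_a[pairs$gene_b %in% b]
    uni <- pairs$gene_a
  } else uni <- unique(as.character(universe))
  a <- intersect(a, uni)
  b <- intersect(b, uni)
  U <- length(uni)
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- if (literal) U - length(b) else U - n11 - n10 - n01
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00, U = U,
                 label = paste(.deg_dir(degs_a, "A"), .deg_dir(degs_b, "B"),
                               sep = "-"),
                 literal = literal),
            class = "quadrant_table")
}

#' @rdname quadrant_counts
#' @param n11,n10,n01,n00 cell counts for a hand-built table.
#' @param label direction-pair label.
#' @export
quadrant_table <- function(n11, n10, n01, n00, label = "A-B") {
  cells <- c(n11, n10, n01, n00)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("quadrant cells must be non-negative integers", call. = FALSE)
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 U = n11 + n10 + n01 + n00, label = label, literal = FALSE),
            class = "quadrant_table")
}

#' Geometric mean enrichment of a quadrant table
#'
#' The enrichment fold is observed over expected overlap given the universe,
#' `n11 * U / ((n11 + n10) * (n11 + n01))` -- algebraically the geometric
#' mean of the two conditional enrichments of each set within the other.
#' Significance is the one-sided ("greater") Fisher exact test on
#' `[[n11, n10], [n01, n00]]`, i.e. the hypergeometric upper tail
#' `P(X >= n11)`.  When either set is empty the fold is undefined (`NaN`)
#' and `p = 1`.  The Fisher conditional odds ratio is reported alongside for
#' transparency; the fold, not the odds ratio, is the enrichment statistic.
#'
#' @param q a [quadrant_counts()] table.
#' @return An object of class `gme_result`: list with `fold`, `pvalue`,
#'   `odds_ratio` and the `quadrant` table.
#' @export
gme <- function(q) {
  stopifnot(inherits(q, "quadrant_table"))
  nA <- q$n11 + q$n10
  nB <- q$n11 + q$n01
  if (nA == 0L || nB == 0L) {
    fold <- NaN; p <- 1; or <- NA_real_
  } else {
    fold <- q$n11 * q$U / (nA * nB)
    p <- phyper(q$n11 - 1L, nA, q$U - nA, nB, lower.tail = FALSE)
    or <- unname(fisher.test(matrix(c(q$n11, q$n01, q$n10, q$n00), 2L),
                             alternative = "greater")$estimate)
  }
  structure(list(fold = fold, pvalue = min(max(p, 0), 1), odds_ratio = or,
                 quadrant = q),
            class = "gme_result")
}

#' @export
print.gme_result <- function(x, ...) {
  q <- x$quadrant
  cat(sprintf("GME [%s]: fold = %.3g, p = %.3g (n11=%d n10=%d n01=%d n00=%d U=%d)\n",
              q$label, x$fold, x$pvalue, q$n11, q$n10, q$n01, q$n00, q$U))
  invisible(x)
}

#' GME for all four direction combinations
#'
#' Applies [quadrant_counts()] + [gme()] to up-up, down-down, up-down and
#' down-up DEG-set pairs over a common joint universe, the full comparison
#' behind a cross-model concordance panel: concordant dysregulation shows as
#' enrichment of the same-direction quadrants, reversal as enrichment of the
#' opposing ones.
#'
#' @param degs_up_a,degs_down_a,degs_up_b,degs_down_b `deg_set`s (or
#'   character vectors) for the two models.
#' @inheritParams quadrant_counts
#' @return Named list of four [gme()] `gme_result`s: `up_up`, `down_down`,
#'   `up_down`, `down_up`.
#' @export
gme_all_quadrants <- function(degs_up_a, degs_down_a, degs_up_b, degs_down_b,
                              universe) {
  list(
    up_up     = gme(quadrant_counts(degs_up_a,   degs_up_b,   universe)),
    down_down = gme(quadrant_counts(degs_down_a, degs_down_b, universe)),
    up_down   = gme(quadrant_counts(degs_up_a,   degs_down_b, universe)),
    down_up   = gme(quadrant_counts(degs_down_a, degs_up_b,   universe))
  )
}

.parse_threshold <- function(x) {
  if (is.null(x) || identical(x, "none")) return(NULL)
  if (is.list(x)) return(x)
  m <- regmatches(x, regexec("^(raw|fdr)[<:]([0-9.eE+-]+)$", x))[[1L]]
  if (length(m) != 3L)
    stop("threshold must be \"none\", \"raw<a\" or \"fdr<a\": got ", x,
         call. = FALSE)
  list(col = m[2L], alpha = as.numeric(m[3L]))
}

.threshold_label <- function(th)
  if (is.null(th)) "none" else sprintf("%s<%g", th$col, th$alpha)

#' Least-squares regression of model-B on model-A log2 fold changes
#'
#' For the genes in `x_genes` (typically model A's pooled up+down DEGs),
#' regresses model B's log2 fold change on model A's by unweighted ordinary
#' least squares, optionally restricting model B to genes passing a raw-p or
#' FDR threshold.  `r2` is the squared Pearson correlation of the points.
#' Fits over fewer than 3 genes (or degenerate zero-variance input) are
#' flagged invalid with `NA` coefficients.
#'
#' @param join an [join_on_orthologs()] `ortholog_join` (or its `records`
#'   data.frame).
#' @param x_genes a `deg_set`, a list of `deg_set`s (pooled), or character
#'   gene ids in model A's id space.
#' @param y_threshold `"none"`, `"raw<alpha"` or `"fdr<alpha"` applied to
#'   model B's p columns.
#' @return An object of class `fit_result`: `slope`, `intercept`, `r2`,
#'   `n_genes`, `threshold_label`, `valid`.
#' @export
lfc_regression <- function(join, x_genes, y_threshold = "none") {
  rec <- if (inherits(join, "ortholog_join")) join$records else as.data.frame(join)
  genes <- if (is.list(x_genes) && !inherits(x_genes, "deg_set"))
    unique(unlist(lapply(x_genes, .deg_genes))) else .deg_genes(x_genes)
  th <- .parse_threshold(y_threshold)
  rec <- rec[rec$gene_a %in% genes, , drop = FALSE]
  if (!is.null(th)) {
    pcol <- if (th$col == "fdr") rec$fdr_b else rec$pvalue_b
    rec <- rec[pcol < th$alpha, , drop = FALSE]
  }
  n <- nrow(rec)
  lab <- .threshold_label(th)
  if (n < 3L || sd(rec$log2fc_a) == 0 || sd(rec$log2fc_b) == 0)
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, n_genes = n, threshold_label = lab,
                          valid = FALSE),
                     class = "fit_result"))
  fit <- lm(log2fc_b ~ log2fc_a, data = rec)
  structure(list(slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r2 = stats::cor(rec$log2fc_a, rec$log2fc_b)^2,
                 n_genes = n, threshold_label = lab, valid = TRUE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$valid)
    cat(sprintf("fit [%s]: slope = %.3g, intercept = %.3g, R^2 = %.3g (n = %d)\n",
                x$threshold_label, x$slope, x$intercept, x$r2, x$n_genes))
  else
    cat(sprintf("fit [%s]: undefined (n = %d)\n", x$threshold_label, x$n_genes))
  invisible(x)
}

#' Regression under a sweep of significance thresholds
#'
#' Repeats [lfc_regression()] under an ordered (loose to strict) list of
#' model-B significance thresholds; with shared dysregulation, tightening
#' the threshold concentrates the points on truly co-regulated genes and the
#' correlation typically rises.  The default sweep `none`, `fdr<0.5`,
#' `fdr<0.05` mirrors a three-panel concordance figure.
#'
#' @inheritParams lfc_regression
#' @param thresholds character vector of threshold labels, loose to strict.
#' @return list of [lfc_regression()] `fit_result`s, one per threshold;
#'   `n_genes` is non-increasing along the list.
#' @export
threshold_sweep <- function(join, x_genes,
                            thresholds = c("none", "fdr<0.5", "fdr<0.05")) {
  fits <- lapply(thresholds, function(t) lfc_regression(join, x_genes, t))
  names(fits) <- vapply(fits, `[[`, character(1), "threshold_label")
  fits
}

#' Sign consistency of a gene set in a target table
#'
#' For genes with a queried direction (e.g. genes discordant between two
#' models, asked whether their raw fold changes in a third table agree with
#' a hypothesised direction), counts agreements of the raw target log2
#' fold-change sign (a zero fold change counts as disagreement) and attaches
#' an exact two-sided binomial p-value at success probability 1/2.  Genes
#' absent from the target table are dropped with a message.
#'
#' @param genes character gene ids (in the target table's id space).
#' @param direction `"up"`/`"down"`, length 1 or per gene.
#' @param target a [de_table()].
#' @return An object of class `sign_consistency`: `n_agree`, `n_total`,
#'   `p_binomial`.
#' @export
sign_consistency <- function(genes, direction, target) {
  stopifnot(inherits(target, "de_table"))
  genes <- as.character(genes)
  direction <- rep_len(match.arg(direction, c("up", "down"), several.ok = TRUE),
                       length(genes))
  idx <- match(genes, target$records$gene)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " gene(s) absent from target table dropped")
    direction <- direction[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  lfc <- target$records$log2fc[idx]
  agree <- ifelse(direction == "up", lfc > 0, lfc < 0)
  n <- length(agree)
  p <- if (n == 0L) 1 else binom.test(sum(agree), n, p = 0.5)$p.value
  structure(list(n_agree = sum(agree), n_total = n, p_binomial = p),
            class = "sign_consistency")
}

#' @export
print.sign_consistency <- function(x, ...) {
  cat(sprintf("sign consistency: %d of %d agree (two-sided binomial p = %.3g)\n",
              x$n_agree, x$n_total, x$p_binomial))
  invisible(x)
}
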