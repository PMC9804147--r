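#' Clusters eligible for the downsampled burden analysis
#'
#' A cluster is eligible when it has strictly more than `burden_min_cells`
#' cells in every sample of the matrix, so that downsampling to a common
#' cell number is possible everywhere.  The downsampling depth `k` is the
#' minimum cell count over all (eligible cluster, sample) combinations,
#' unless `cfg$burden_k` fixes it explicitly.
#'
#' @param m a [cell_matrix()] with every cell labelled.
#' @param cfg a [threshold_config()].
#' @return list with `clusters` (character), `k` (integer), and the
#'   cluster-by-sample count matrix `counts`.
#' @export
eligible_clusters <- function(m, cfg = threshold_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  tab <- table(m$cell_meta$cluster_label, m$cell_meta$sample_id)
  ok <- apply(tab, 1L, min) > cfg$burden_min_cells
  if (!any(ok))
    stop("no cluster exceeds ", cfg$burden_min_cells, " cells in every sample",
         call. = FALSE)
  clusters <- rownames(tab)[ok]
  k <- if (identical(cfg$burden_k, "auto"))
    as.integer(min(tab[ok, , drop = FALSE])) else cfg$burden_k
  list(clusters = clusters, k = k,
       counts = as.matrix(tab)[ok, , drop = FALSE])
}

#' Downsample one cluster in one sample to k cells
#'
#' Uniform sampling without replacement; uses the current RNG state, so a
#' caller fixing the seed gets a reproducible subset.  When the cluster has
#' exactly `k` cells all of them are returned without consuming randomness.
#'
#' @param m a [cell_matrix()].
#' @param cluster,sample_id labels selecting the cells.
#' @param k number of cells to keep.
#' @return Sorted character vector of `k` cell ids.
#' @export
downsample_cells <- function(m, cluster, sample_id, k) {
  stopifnot(inherits(m, "cell_matrix"))
  ids <- m$cell_meta$cell_id[m$cell_meta$cluster_label == cluster &
                               m$cell_meta$sample_id == sample_id]
  if (length(ids) < k)
    stop(sprintf("cluster '%s' has %d cells in sample '%s' (< k = %d)",
                 cluster, length(ids), sample_id, k), call. = FALSE)
  if (length(ids) == k) return(sort(ids))
  sort(sample(ids, k))
}

#' Cluster-downsampled, iterated DEG burden
#'
#' Ranks clusters by transcriptomic disruption in a mutant line while
#' controlling for cell-number bias: in each of `burden_iters` iterations,
#' every eligible cluster is downsampled to `k` cells in every sample, the
#' mutant line's pooled cells are tested against the control line's pooled
#' cells per cluster with [run_de()] (strict `|log2fc| > lfc_min`,
#' `fdr < fdr_max`), and the DEG count (both directions) is recorded; counts
#' are averaged over iterations.  One master seed spawns independent
#' per-iteration streams, so iteration `j` is reproducible on its own.
#'
#' @param m a QC-filtered, normalized [cell_matrix()]; cluster eligibility
#'   is assessed over all samples present (all lines).
#' @param control_line,mutant_line line labels.
#' @param cfg a [threshold_config()].
#' @param seed master seed for the downsampling randomness.
#' @return An object of class `burden_result`: `iteration_counts`
#'   (iterations x clusters matrix), `mean_count` (named per cluster),
#'   `k_used`, `eligible_clusters`, `seed`, `mutant_line`, `control_line`.
#' @export
burden <- function(m, control_line, mutant_line, cfg = threshold_config(),
                   seed = 1L) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  for (ln in c(control_line, mutant_line))
    if (!any(meta$line_id == ln)) stop("line not present: ", ln, call. = FALSE)
  el <- eligible_clusters(m, cfg)
  samples_mut <- unique(meta$sample_id[meta$line_id == mutant_line])
  samples_ctl <- unique(meta$sample_id[meta$line_id == control_line])
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, cfg$burden_iters)
  counts <- matrix(NA_integer_, nrow = cfg$burden_iters,
                   ncol = length(el$clusters),
                   dimnames = list(NULL, el$clusters))
  for (j in seq_len(cfg$burden_iters)) {
    set.seed(iter_seeds[j])
    for (cl in el$clusters) {
      cells_mut <- unlist(lapply(samples_mut, function(s)
        downsample_cells(m, cl, s, el$k)))
      cells_ctl <- unlist(lapply(samples_ctl, function(s)
        downsample_cells(m, cl, s, el$k)))
      de <- run_de(m, cells_mut, cells_ctl, cfg)
      counts[j, cl] <- sum(de$records$fdr < cfg$fdr_max)
    }
  }
  structure(list(iteration_counts = counts,
                 mean_count = colMeans(counts),
                 k_used = el$k, eligible_clusters = el$clusters,
                 seed = seed, mutant_line = mutant_line,
                 control_line = control_line),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf("burden %s vs %s: k = %d, %d iterations\n", x$mutant_line,
              x$control_line, x$k_used, nrow(x$iteration_counts)))
  print(round(sort(x$mean_count, decreasing = TRUE), 1))
  invisible(x)
}

#' Cell-type composition comparison between two lines
#'
#' Per cluster, compares the fraction of a line's cells falling in the
#' cluster against the control line.  Replicate-level per-sample proportions
#' give the reported mean and SEM; significance comes from a two-sided
#' Fisher exact test on the pooled in-cluster/out-of-cluster counts of the
#' two lines, and the direction of change is the sign of the pooled
#' proportion difference.  Both views are returned because pooling and
#' replicate-level variability answer subtly different questions.
#'
#' @param m a [cell_matrix()].
#' @param control_line,line line labels.
#' @return An object of class `composition_result`: `summary` data.frame
#'   (per cluster: pooled counts, proportions, mean/SEM over samples,
#'   Fisher p, direction) and `proportions` (sample x cluster matrix,
#'   rows summing to 1).
#' @export
composition <- function(m, control_line, line) {
  stopifnot(inherits(m, "cell_matrix"))
  meta <- m$cell_meta
  for (ln in c(control_line, line))
    if (!any(meta$line_id == ln)) stop("line not present: ", ln, call. = FALSE)
  clusters <- sort(unique(meta$cluster_label))
  tab <- table(meta$sample_id, meta$cluster_label)
  props <- sweep(as.matrix(tab), 1L, rowSums(tab), "/")
  sample_line <- meta$line_id[match(rownames(props), meta$sample_id)]
  pool <- function(ln) {
    in_cl <- colSums(as.matrix(tab)[sample_line == ln, , drop = FALSE])
    c(list(total = sum(in_cl)), list(in_cl = in_cl))
  }
  pl <- pool(line); pc <- pool(control_line)
  rows <- lapply(clusters, function(cl) {
    a <- pl$in_cl[[cl]]; b <- pl$total - a
    c0 <- pc$in_cl[[cl]]; d0 <- pc$total - c0
    p <- fisher.test(matrix(c(a, b, c0, d0), 2L))$p.value
    prop_l <- a / pl$total; prop_c <- c0 / pc$total
    sl <- props[sample_line == line, cl]
    sc <- props[sample_line == control_line, cl]
    data.frame(cluster = cl, line_cells = a, control_cells = c0,
               prop_line = prop_l, prop_control = prop_c,
               mean_line = mean(sl), sem_line = sd(sl) / sqrt(length(sl)),
               mean_control = mean(sc), sem_control = sd(sc) / sqrt(length(sc)),
               fisher_p = p,
               direction = if (prop_l > prop_c) "increased" else
                 if (prop_l < prop_c) "decreased" else "none",
               stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, rows), proportions = props,
                 line = line, control_line = control_line),
            class = "composition_result")
}

#' @export
print.composition_result <- function(x, ...) {
  cat(sprintf("composition %s vs %s:\n", x$line, x$control_line))
  print(x$summary[c("cluster", "prop_line", "prop_control", "fisher_p",
                    "direction")], digits = 3)
  invisible(x)
}
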