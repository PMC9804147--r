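# Fixtures are built in code; nothing is read from disk except via tempfiles.

# Six-gene table with hand-checkable thresholds (lfc 0.25, fdr 0.05).
toy_de_table <- function(model_id = "toy") {
  de_table(data.frame(
    gene   = c("g1", "g2", "g3", "g4", "g5", "g6"),
    log2fc = c(0.80, 0.25, -0.90, 0.30, -0.26, 1.50),
    pvalue = c(1e-4, 1e-4, 2e-4, 0.20, 1e-3, 1e-5),
    fdr    = c(6e-4, 6e-4, 6e-4, 0.30, 3e-3, 1e-4)),
    model_id = model_id)
}

# DE table with a chosen number of qualifying FDR DEGs (fdr<0.05 & |lfc|>0.25)
# plus `n_null` clearly non-qualifying genes.
table_with_n_fdr_degs <- function(n_deg, n_null = 5L) {
  n <- n_deg + n_null
  de_table(data.frame(
    gene = sprintf("g%03d", seq_len(n)),
    log2fc = c(rep(1, n_deg), rep(0.1, n_null)),
    pvalue = c(rep(1e-6, n_deg), rep(0.9, n_null)),
    fdr = c(rep(1e-4, n_deg), rep(0.95, n_null))))
}

# Dense cell matrix from explicit counts; labels default to one sample/line.
toy_cell_matrix <- function(counts, sample_id = "s1", line_id = "l1",
                            cluster_label = "c1") {
  n <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  cell_matrix(counts, data.frame(
    cell_id = sprintf("cell%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    line_id = rep_len(line_id, n),
    cluster_label = rep_len(cluster_label, n)))
}

# Metadata-only matrix (1 housekeeping gene) for eligibility/downsampling.
meta_cell_matrix <- function(meta) {
  counts <- matrix(1L, nrow = 1L, ncol = nrow(meta),
                   dimnames = list("g001", meta$cell_id))
  cell_matrix(counts, meta)
}

# Small two-group null single-cell fixture at the downsampled-cluster scale.
null_sc_matrix <- function(seed, n_genes = 200L, cells_per_group = 60L) {
  cfg <- sc_sim_config(n_genes = n_genes, n_mito = 5L, clusters = "c1",
                       lines = list(control = "ctl", mutants = "mut"),
                       samples_per_line = 1L,
                       cells_per_cluster = c(cells_per_group, cells_per_group),
                       n_deg_per_cluster = 0L, seed = seed)
  normalize_cells(simulate_sc(cfg)$matrix)
}

# Compact planted-burden configuration shared by burden tests.
burden_sim_config <- function(seed, n_deg = c(a = 12L, b = 12L, c = 12L),
                              clusters = c("a", "b", "c")) {
  sc_sim_config(n_genes = 300L, n_mito = 5L, clusters = clusters,
                lines = list(control = "wt", mutants = "mut"),
                samples_per_line = 5L, cells_per_cluster = c(30L, 45L),
                n_deg_per_cluster = n_deg, deg_lfc = 1, seed = seed)
}

# Exhaustive two-sided binomial p at p = 0.5 by outcome enumeration
# (groups the 2^n equally likely sign vectors by their success count).
enum_binom_two_sided <- function(k, n) {
  prob <- choose(n, 0:n) / 2^n
  sum(prob[prob <= prob[k + 1L] * (1 + 1e-9)])
}

# Hypergeometric upper tail P(X >= x), X ~ Hypergeom(N, K, n), from choose().
enum_hyper_upper <- function(x, N, K, n) {
  lo <- max(x, 0L); hi <- min(K, n)
  if (lo > hi) return(0)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

make_meta <- function(cluster_sizes) {
  # cluster_sizes: named list cluster -> named vector sample -> count,
  # with a line label derived from the sample prefix before "_s"
  rows <- list()
  i <- 0L
  for (cl in names(cluster_sizes)) for (s in names(cluster_sizes[[cl]])) {
    n <- cluster_sizes[[cl]][[s]]
    if (n == 0) next
    rows[[paste(cl, s)]] <- data.frame(
      cell_id = sprintf("c%06d", i + seq_len(n)),
      sample_id = s, line_id = sub("_s.*", "", s), cluster_label = cl)
    i <- i + n
  }
  do.call(rbind, rows)
}


# 50 genes x 30 cells with hand-enumerated QC fates (thresholds scaled to the
# 50-gene panel): 6 genes fail the 3-cell floor, 6 cells fail (2 low gene
# count, 1 high gene count, 3 mitochondrial), leaving 44 x 24.
qc_toy <- function() {
  cnt <- matrix(0L, nrow = 50, ncol = 30,
                dimnames = list(c("MT-1", sprintf("g%02d", 2:50)), NULL))
  cnt[1, c(1:24)] <- 1L            # MT-1 in all surviving cells
  cnt[1, 28:30] <- 10L             # heavy mito load in cells 28-30
  cnt[2:25, 1:24] <- 1L            # 24 core genes in surviving cells
  cnt[2:10, 25:26] <- 1L           # cells 25,26: only 9 genes
  cnt[2:44, 27] <- 1L              # cell 27: 43 genes
  cnt[2:25, 28] <- 1L              # cell 28: core + mito
  cnt[26:44, c(27, 29, 30)] <- 1L  # 19 extra genes supported by 3 cells
  # rows 45:50 stay all-zero: the 6 failing genes
  toy_cell_matrix(cnt)
}

qc_toy_cfg <- threshold_config(qc_min_cells_per_gene = 3L,
                               qc_min_genes_per_cell = 10L,
                               qc_max_genes_per_cell = 40L)

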