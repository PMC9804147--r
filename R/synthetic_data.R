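#' Configuration for the paired bulk DE-table simulator
#'
#' The generator emulates the statistical structure behind a two-model
#' comparison: each gene carries a latent log2 effect that is shared
#' (concordant genes), sign-flipped (discordant genes) or absent (null
#' genes) across the two models, and each model observes it with
#' independent Gaussian noise of known standard error.  P-values come from
#' the known-SE normal model, giving closed-form truth for calibration
#' tests.  Human-style (upper-case) and mouse-style (title-case) gene ids
#' are used for the two tables so the case-heuristic ortholog path is
#' exercised.
#'
#' @param n_genes number of simulated genes.
#' @param f_conc,f_disc fractions of planted concordant / discordant genes
#'   (`f_conc + f_disc <= 1`); effect signs are random per gene.
#' @param effect_mu,effect_sd mean and sd of the absolute latent log2
#'   effect.
#' @param se_a,se_b per-model standard errors of the observed log2fc.
#' @param ortholog_dropout fraction of gene pairs omitted from the emitted
#'   ortholog map.
#' @param universe_dropout per-table fraction of genes dropped from the
#'   tested universe (emulating model-specific testing filters).
#' @param seed RNG seed.
#' @return An object of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_genes = 5000L, f_conc = 0.10, f_disc = 0.05,
                            effect_mu = 1.5, effect_sd = 0.4,
                            se_a = 0.3, se_b = 0.3,
                            ortholog_dropout = 0.05,
                            universe_dropout = 0.02, seed = 1L) {
  if (f_conc < 0 || f_disc < 0 || f_conc + f_disc > 1)
    stop("need f_conc, f_disc >= 0 and f_conc + f_disc <= 1", call. = FALSE)
  if (effect_sd <= 0 || se_a <= 0 || se_b <= 0)
    stop("effect_sd, se_a and se_b must be positive", call. = FALSE)
  if (ortholog_dropout < 0 || ortholog_dropout >= 1 ||
      universe_dropout < 0 || universe_dropout >= 1)
    stop("dropout fractions must lie in [0,1)", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), f_conc = f_conc,
                 f_disc = f_disc, effect_mu = effect_mu,
                 effect_sd = effect_sd, se_a = se_a, se_b = se_b,
                 ortholog_dropout = ortholog_dropout,
                 universe_dropout = universe_dropout,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Population squared correlation implied by a bulk simulation config
#'
#' Closed form for the population squared Pearson correlation of the two
#' observed log2 fold changes across the gene population: with `M =
#' effect_mu^2 + effect_sd^2`, the latent effect variance in each model is
#' `V = (f_conc + f_disc) * M` and the cross-model covariance is
#' `(f_conc - f_disc) * M`, so
#' `r^2 = ((f_conc - f_disc) * M)^2 / ((V + se_a^2) * (V + se_b^2))`.
#'
#' @param cfg a [bulk_sim_config()].
#' @return The population r-squared.
#' @export
bulk_population_r2 <- function(cfg) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  M <- cfg$effect_mu^2 + cfg$effect_sd^2
  V <- (cfg$f_conc + cfg$f_disc) * M
  ((cfg$f_conc - cfg$f_disc) * M)^2 / ((V + cfg$se_a^2) * (V + cfg$se_b^2))
}

#' Simulate a pair of DE tables with planted cross-model structure
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `table_a`, `table_b` ([de_table()]s), `map`
#'   ([ortholog_map()]), `truth` (data.frame: per-gene class, latent
#'   effects and ids in both tables) and `config`.
#' @export
simulate_bulk_pair <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  gene_a <- sprintf("GENE%05d", seq_len(G))
  gene_b <- sprintf("Gene%05d", seq_len(G))
  n_conc <- round(cfg$f_conc * G)
  n_disc <- round(cfg$f_disc * G)
  class <- rep("null", G)
  planted <- sample.int(G, n_conc + n_disc)
  class[planted[seq_len(n_conc)]] <- "concordant"
  if (n_disc) class[planted[n_conc + seq_len(n_disc)]] <- "discordant"
  sgn <- sample(c(-1, 1), G, replace = TRUE)
  mag <- abs(rnorm(G, cfg$effect_mu, cfg$effect_sd))
  theta_a <- ifelse(class == "null", 0, sgn * mag)
  theta_b <- ifelse(class == "concordant", theta_a,
                    ifelse(class == "discordant", -theta_a, 0))
  class[class == "concordant"] <- ifelse(sgn[class == "concordant"] > 0,
                                         "concordant-up", "concordant-down")
  make_table <- function(ids, theta, se, model_id, species) {
    lfc <- theta + rnorm(G, 0, se)
    p <- 2 * pnorm(-abs(lfc) / se)
    drop_n <- round(cfg$universe_dropout * G)
    uni_idx <- if (drop_n) sort(sample.int(G, G - drop_n)) else seq_len(G)
    de_table(data.frame(gene = ids[uni_idx], log2fc = lfc[uni_idx],
                        pvalue = p[uni_idx],
                        fdr = bh_adjust(p[uni_idx]),
                        stringsAsFactors = FALSE),
             universe = ids[uni_idx], model_id = model_id, species = species)
  }
  table_a <- make_table(gene_a, theta_a, cfg$se_a, "sim_model_a", "human")
  table_b <- make_table(gene_b, theta_b, cfg$se_b, "sim_model_b", "mouse")
  keep_n <- G - round(cfg$ortholog_dropout * G)
  keep <- sort(sample.int(G, keep_n))
  map <- ortholog_map(data.frame(source_id = gene_a[keep],
                                 target_id = gene_b[keep],
                                 stringsAsFactors = FALSE))
  truth <- data.frame(gene_a = gene_a, gene_b = gene_b, class = class,
                      theta_a = theta_a, theta_b = theta_b,
                      stringsAsFactors = FALSE)
  list(table_a = table_a, table_b = table_b, map = map, truth = truth,
       config = cfg)
}

#' Configuration for the multi-sample single-cell count simulator
#'
#' Emulates a replicated single-cell design: a control line plus mutant
#' lines, each with `samples_per_line` biological replicates, cells
#' allocated to annotated clusters.  Counts are negative binomial with a
#' shared dispersion around `size factor x cluster profile`, cluster
#' identity comes from upweighted marker genes, mutant lines shift cluster
#' composition through per-cluster multipliers, and planted DEGs multiply a
#' gene's mean by `2^deg_lfc` in a mutant line's cells of that cluster.
#' Mitochondrial (`MT-`-prefixed) genes with a target read fraction are
#' included so the QC path is exercised.
#'
#' @param n_genes total genes, including `n_mito` mitochondrial ones.
#' @param n_mito number of `MT-` genes.
#' @param clusters character vector of cluster labels.
#' @param lines named list: `control` (label) and `mutants` (labels).
#' @param samples_per_line biological replicates per line.
#' @param cells_per_cluster length-2 range: baseline cells per cluster per
#'   sample, drawn uniformly before the composition multiplier.
#' @param nb_dispersion shared NB dispersion (variance = mu + dispersion *
#'   mu^2).
#' @param composition named list per mutant line of named per-cluster
#'   abundance multipliers (default 1); the control is the reference.
#' @param n_deg_per_cluster planted DEGs per (cluster, mutant line): a
#'   single number or a named per-cluster vector.
#' @param deg_lfc absolute log2 effect of planted DEGs (sign random).
#' @param mito_target target mitochondrial read fraction.
#' @param gene_mean_meanlog,gene_mean_sdlog log-normal parameters of
#'   per-gene base means.
#' @param size_factor_sdlog log-normal sd of per-cell size factors.
#' @param n_markers marker genes upweighted (x4) per cluster.
#' @param seed RNG seed.
#' @return An object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_genes = 1000L, n_mito = 10L,
                          clusters = c("npc", "nsc", "ipc", "neuron", "gaba"),
                          lines = list(control = "wt",
                                       mutants = c("mut1", "mut2")),
                          samples_per_line = 5L,
                          cells_per_cluster = c(50L, 90L),
                          nb_dispersion = 0.5,
                          composition = list(),
                          n_deg_per_cluster = 15L,
                          deg_lfc = 1.0,
                          mito_target = 0.05,
                          gene_mean_meanlog = 0.3,
                          gene_mean_sdlog = 1.0,
                          size_factor_sdlog = 0.3,
                          n_markers = 40L,
                          seed = 1L) {
  if (n_mito >= n_genes) stop("n_mito must be < n_genes", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive", call. = FALSE)
  if (mito_target <= 0 || mito_target >= 1)
    stop("mito_target must lie in (0,1)", call. = FALSE)
  if (length(cells_per_cluster) != 2L || any(cells_per_cluster < 1))
    stop("cells_per_cluster must be a positive range", call. = FALSE)
  if (is.null(lines$control) || !length(lines$mutants))
    stop("lines must name a control and at least one mutant", call. = FALSE)
  for (ln in names(composition)) {
    cm <- composition[[ln]]
    if (any(cm <= 0) || !all(names(cm) %in% clusters))
      stop("composition multipliers must be positive and keyed by cluster",
           call. = FALSE)
  }
  if (is.null(names(n_deg_per_cluster)) && length(n_deg_per_cluster) != 1L)
    stop("n_deg_per_cluster must be scalar or named per cluster", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes), n_mito = as.integer(n_mito),
                 clusters = clusters, lines = lines,
                 samples_per_line = as.integer(samples_per_line),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 nb_dispersion = nb_dispersion, composition = composition,
                 n_deg_per_cluster = n_deg_per_cluster, deg_lfc = deg_lfc,
                 mito_target = mito_target,
                 gene_mean_meanlog = gene_mean_meanlog,
                 gene_mean_sdlog = gene_mean_sdlog,
                 size_factor_sdlog = size_factor_sdlog,
                 n_markers = as.integer(n_markers),
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

.comp_mult <- function(cfg, line, cluster) {
  cm <- cfg$composition[[line]]
  if (is.null(cm) || is.na(cm[cluster])) 1 else unname(cm[cluster])
}

.deg_n <- function(cfg, cluster) {
  n <- cfg$n_deg_per_cluster
  if (is.null(names(n))) n[[1L]] else if (is.na(n[cluster])) 0L else n[[cluster]]
}

#' Simulate an annotated multi-sample single-cell count matrix
#'
#' @param cfg an [sc_sim_config()].
#' @return list with `matrix` (a [cell_matrix()]), `truth` (list:
#'   `deg_table` -- data.frame of planted per-(line, cluster) DEGs with
#'   signed log2 effects; `composition` -- per-line expected cluster
#'   proportions, each row a simplex point) and `config`.
#' @export
simulate_sc <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  genes <- c(sprintf("MT-%d", seq_len(cfg$n_mito)),
             sprintf("G%05d", seq_len(G - cfg$n_mito)))
  mito <- seq_len(cfg$n_mito)
  base <- exp(rnorm(G, cfg$gene_mean_meanlog, cfg$gene_mean_sdlog))
  base[mito] <- cfg$mito_target / (1 - cfg$mito_target) *
    sum(base[-mito]) / cfg$n_mito
  n_mark <- min(cfg$n_markers, G - cfg$n_mito)
  profiles <- vapply(cfg$clusters, function(cl) {
    pr <- base
    markers <- sample((cfg$n_mito + 1L):G, n_mark)
    pr[markers] <- pr[markers] * 4
    pr
  }, numeric(G))
  dimnames(profiles) <- list(genes, cfg$clusters)
  all_lines <- c(cfg$lines$control, cfg$lines$mutants)
  deg_rows <- list()
  deg_mult <- list()   # per (line, cluster): named multiplier vector
  for (ln in cfg$lines$mutants) for (cl in cfg$clusters) {
    nd <- .deg_n(cfg, cl)
    if (nd == 0L) next
    gs <- sample((cfg$n_mito + 1L):G, nd)
    lfc <- sample(c(-1, 1), nd, replace = TRUE) * cfg$deg_lfc
    deg_rows[[paste(ln, cl)]] <- data.frame(line = ln, cluster = cl,
                                            gene = genes[gs], lfc = lfc,
                                            stringsAsFactors = FALSE)
    deg_mult[[paste(ln, cl)]] <- setNames(2^lfc, gs)
  }
  blocks <- list(); metas <- list()
  cell_no <- 0L
  for (ln in all_lines) for (s in seq_len(cfg$samples_per_line)) {
    samp <- sprintf("%s_s%d", ln, s)
    for (cl in cfg$clusters) {
      n_base <- round(runif(1, cfg$cells_per_cluster[1L],
                            cfg$cells_per_cluster[2L]))
      n <- max(1L, round(n_base * .comp_mult(cfg, ln, cl)))
      sf <- exp(rnorm(n, 0, cfg$size_factor_sdlog))
      mu_gene <- profiles[, cl]
      dm <- deg_mult[[paste(ln, cl)]]
      if (!is.null(dm)) mu_gene[as.integer(names(dm))] <-
          mu_gene[as.integer(names(dm))] * dm
      mu <- outer(mu_gene, sf)
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                    nrow = G)
      ids <- sprintf("cell%06d", cell_no + seq_len(n))
      cell_no <- cell_no + n
      dimnames(cnt) <- list(genes, ids)
      blocks[[length(blocks) + 1L]] <- Matrix::Matrix(cnt, sparse = TRUE)
      metas[[length(metas) + 1L]] <- data.frame(cell_id = ids, sample_id = samp,
                                                line_id = ln, cluster_label = cl,
                                                stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  exp_comp <- matrix(0, length(all_lines), length(cfg$clusters),
                     dimnames = list(all_lines, cfg$clusters))
  for (ln in all_lines) for (cl in cfg$clusters)
    exp_comp[ln, cl] <- .comp_mult(cfg, ln, cl)
  exp_comp <- exp_comp / rowSums(exp_comp)
  truth <- list(deg_table = if (length(deg_rows))
    do.call(rbind, c(deg_rows, make.row.names = FALSE)) else
      data.frame(line = character(), cluster = character(),
                 gene = character(), lfc = numeric()),
    composition = exp_comp)
  list(matrix = cell_matrix(counts, meta), truth = truth, config = cfg)
}
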