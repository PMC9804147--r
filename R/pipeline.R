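#' Run the full cross-model concordance and single-cell burden pipeline
#'
#' End-to-end orchestration on simulated inputs: generates a paired bulk
#' DE-table comparison and a multi-sample single-cell matrix, calls DEGs
#' (with the low-power fallback rule), joins the two models through the
#' case-heuristic ortholog map, computes the four-quadrant geometric mean
#' enrichment, the threshold-swept log2FC regression and the
#' sign-consistency of discordant genes, then QC-filters and normalizes the
#' single-cell matrix and runs the downsampled DEG-burden and composition
#' procedures for every mutant line.  All randomness flows from `seed`
#' (which re-seeds both simulation configs), so a rerun with the same
#' arguments is byte-identical.
#'
#' @param bulk_cfg a [bulk_sim_config()].
#' @param sc_cfg an [sc_sim_config()].
#' @param cfg a [threshold_config()].
#' @param seed master seed; the bulk and single-cell simulators and the
#'   burden iterations derive their streams from it.
#' @param out_dir optional directory; when given, a `report.json` plus DEG,
#'   joined-record and burden TSVs are written there.
#' @param verbose log stage progress to standard error.
#' @return The report as a nested list (invisibly when `out_dir` is given).
#' @export
run_full <- function(bulk_cfg = bulk_sim_config(), sc_cfg = sc_sim_config(),
                     cfg = threshold_config(), seed = 1L, out_dir = NULL,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message("[run_full] ", sprintf(...))
  seed <- as.integer(seed)
  bulk_cfg$seed <- seed
  sc_cfg$seed <- seed + 1L

  say("simulating bulk pair (G = %d)", bulk_cfg$n_genes)
  sim <- simulate_bulk_pair(bulk_cfg)
  ta <- sim$table_a; tb <- sim$table_b

  say("calling DEGs")
  degs <- list(a_up = extract_degs(ta, "up", cfg),
               a_down = extract_degs(ta, "down", cfg),
               b_up = extract_degs(tb, "up", cfg),
               b_down = extract_degs(tb, "down", cfg))

  say("joining on orthologs and computing GME")
  map <- default_symbol_map(ta$universe, tb$universe)
  join <- join_on_orthologs(ta, tb, map)
  gmes <- gme_all_quadrants(degs$a_up, degs$a_down, degs$b_up, degs$b_down,
                            join)

  say("threshold sweep")
  sweep_fits <- threshold_sweep(join, list(degs$a_up, degs$a_down))

  # discordant genes: model-A DEGs whose partner is a DEG of opposite sign
  # in model B; ask whether their raw model-B fold changes oppose model A.
  pairs <- join$universe_pairs
  disc_b <- c(pairs$gene_b[pairs$gene_a %in% degs$a_up$genes &
                             pairs$gene_b %in% degs$b_down$genes],
              pairs$gene_b[pairs$gene_a %in% degs$a_down$genes &
                             pairs$gene_b %in% degs$b_up$genes])
  disc_dir <- rep(c("down", "up"),
                  c(sum(pairs$gene_a %in% degs$a_up$genes &
                          pairs$gene_b %in% degs$b_down$genes),
                    sum(pairs$gene_a %in% degs$a_down$genes &
                          pairs$gene_b %in% degs$b_up$genes)))
  sc_res <- if (length(disc_b)) sign_consistency(disc_b, disc_dir, tb) else
    structure(list(n_agree = 0L, n_total = 0L, p_binomial = 1),
              class = "sign_consistency")

  say("simulating single-cell matrix")
  scsim <- simulate_sc(sc_cfg)
  say("QC and normalization")
  mat <- normalize_cells(qc_filter(scsim$matrix, cfg), cfg)

  burdens <- list(); compositions <- list()
  for (ln in sc_cfg$lines$mutants) {
    say("burden for line %s", ln)
    burdens[[ln]] <- burden(mat, sc_cfg$lines$control, ln, cfg,
                            seed = seed + 2L)
    compositions[[ln]] <- composition(mat, sc_cfg$lines$control, ln)
  }

  report <- list(
    schema = "txconcord-report/1",
    seed = seed,
    thresholds = unclass(cfg),
    bulk = list(
      config = unclass(bulk_cfg),
      n_degs = lapply(degs, function(d) length(d$genes)),
      p_mode = list(a = degs$a_up$p_mode, b = degs$b_up$p_mode),
      joint_universe = nrow(join$universe_pairs),
      gme = lapply(gmes, function(g)
        list(fold = g$fold, pvalue = g$pvalue, odds_ratio = g$odds_ratio,
             n11 = g$quadrant$n11, n10 = g$quadrant$n10,
             n01 = g$quadrant$n01, n00 = g$quadrant$n00, U = g$quadrant$U)),
      sweep = lapply(sweep_fits, unclass),
      sign_consistency = unclass(sc_res)),
    single_cell = list(
      config = unclass(sc_cfg)[c("n_genes", "clusters", "samples_per_line",
                                 "nb_dispersion", "deg_lfc")],
      n_cells_pre_qc = ncol(scsim$matrix$counts),
      n_cells_post_qc = ncol(mat$counts),
      n_genes_post_qc = nrow(mat$counts),
      burden = lapply(burdens, function(b)
        list(k = b$k_used, eligible = b$eligible_clusters,
             mean_count = as.list(b$mean_count))),
      composition = lapply(compositions, function(cp)
        lapply(seq_len(nrow(cp$summary)), function(i) as.list(cp$summary[i, ])))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(join$records, file.path(out_dir, "joined_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(degs))
      writeLines(degs[[nm]]$genes, file.path(out_dir, paste0("degs_", nm, ".txt")))
    for (ln in names(burdens))
      write.table(data.frame(cluster = names(burdens[[ln]]$mean_count),
                             mean_degs = unname(burdens[[ln]]$mean_count)),
                  file.path(out_dir, paste0("burden_", ln, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}
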