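test_that("bulk simulation is seed-deterministic with exact planted counts", {
  cfg <- bulk_sim_config(n_genes = 800L, f_conc = 0.1, f_disc = 0.05, seed = 41L)
  s1 <- simulate_bulk_pair(cfg)
  s2 <- simulate_bulk_pair(cfg)
  expect_identical(s1, s2)

  counts <- table(s1$truth$class)
  expect_equal(sum(counts[c("concordant-up", "concordant-down")]),
               round(0.1 * 800))
  expect_equal(unname(counts["discordant"]), round(0.05 * 800))

  # universes and map honour the dropout fractions exactly
  expect_equal(length(s1$table_a$universe), 800L - round(0.02 * 800))
  expect_equal(nrow(s1$map), 800L - round(0.05 * 800))

  # all-null config plants nothing
  s0 <- simulate_bulk_pair(bulk_sim_config(n_genes = 300L, f_conc = 0,
                                           f_disc = 0, seed = 42L))
  expect_true(all(s0$truth$class == "null"))
  expect_true(all(s0$truth$theta_a == 0))
})

test_that("planted effects follow the class-determined sign structure", {
  cfg <- bulk_sim_config(n_genes = 500L, f_conc = 0.2, f_disc = 0.2, seed = 43L)
  tr <- simulate_bulk_pair(cfg)$truth
  conc <- grepl("^concordant", tr$class)
  expect_true(all(tr$theta_a[conc] == tr$theta_b[conc]))
  disc <- tr$class == "discordant"
  expect_true(all(tr$theta_a[disc] == -tr$theta_b[disc]))
  expect_true(all(tr$theta_a[tr$class == "concordant-up"] > 0))
  expect_true(all(tr$theta_a[tr$class == "concordant-down"] < 0))
})

test_that("observed cross-model correlation matches the analytic value", {
  cfg <- bulk_sim_config(n_genes = 5000L, f_conc = 1, f_disc = 0, seed = 44L)
  sim <- simulate_bulk_pair(cfg)
  j <- join_on_orthologs(sim$table_a, sim$table_b, sim$map)
  r2 <- cor(j$records$log2fc_a, j$records$log2fc_b)^2
  expect_lt(abs(r2 - bulk_population_r2(cfg)), 0.05)
})

test_that("discordant genes show opposite raw signs at the analytic rate", {
  cfg <- bulk_sim_config(n_genes = 4000L, f_conc = 0, f_disc = 0.25,
                         se_a = 0.4, se_b = 0.4, seed = 45L)
  sim <- simulate_bulk_pair(cfg)
  tr <- sim$truth[sim$truth$class == "discordant", ]
  lfc_a <- sim$table_a$records$log2fc[match(tr$gene_a, sim$table_a$records$gene)]
  lfc_b <- sim$table_b$records$log2fc[match(tr$gene_b, sim$table_b$records$gene)]
  ok <- !is.na(lfc_a) & !is.na(lfc_b)
  observed <- mean(sign(lfc_a[ok]) == -sign(lfc_b[ok]))
  expected <- mean(pnorm(abs(tr$theta_a[ok]) / 0.4) *
                     pnorm(abs(tr$theta_b[ok]) / 0.4))
  se <- sqrt(expected * (1 - expected) / sum(ok))
  expect_gte(observed, expected - 3 * se)
})

test_that("single-cell counts match the configured NB mean and variance", {
  cfg <- sc_sim_config(n_genes = 60L, n_mito = 2L, clusters = "c1",
                       lines = list(control = "a", mutants = "b"),
                       samples_per_line = 1L,
                       cells_per_cluster = c(5000L, 5000L),
                       n_deg_per_cluster = 0L, size_factor_sdlog = 1e-9,
                       nb_dispersion = 0.5, n_markers = 0L, seed = 46L)
  sim <- simulate_sc(cfg)
  cnt <- as.matrix(sim$matrix$counts)   # 60 x 10000, no planted effects
  # recover the generator's base means from the config seed
  set.seed(46L)
  base <- exp(rnorm(60, 0.3, 1))
  base[1:2] <- 0.05 / 0.95 * sum(base[-(1:2)]) / 2
  keep <- base > 0.5
  emp_mean <- rowMeans(cnt)
  emp_var <- apply(cnt, 1, var)
  expect_true(all(abs(emp_mean[keep] - base[keep]) / base[keep] < 0.1))
  th_var <- base + 0.5 * base^2
  expect_true(all(abs(emp_var[keep] - th_var[keep]) / th_var[keep] < 0.25))
})

test_that("single-cell simulation is deterministic and respects its blueprint", {
  cfg <- sc_sim_config(n_genes = 120L, n_mito = 4L, clusters = c("x", "y"),
                       lines = list(control = "a", mutants = "b"),
                       samples_per_line = 2L, cells_per_cluster = c(10L, 20L),
                       composition = list(b = c(x = 0.5)),
                       n_deg_per_cluster = 5L, seed = 47L)
  s1 <- simulate_sc(cfg)
  s2 <- simulate_sc(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_equal(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))

  meta <- s1$matrix$cell_meta
  expect_setequal(unique(meta$line_id), c("a", "b"))
  expect_equal(length(unique(meta$sample_id)), 4L)
  tr <- s1$truth
  expect_equal(nrow(tr$deg_table), 2L * 5L)   # one mutant line, two clusters
  expect_true(all(abs(tr$deg_table$lfc) == 1))
  # expected composition rows are simplex points
  expect_equal(unname(rowSums(tr$composition)), c(1, 1))
  # mutant line depleted in cluster x by construction
  expect_lt(tr$composition["b", "x"], tr$composition["a", "x"])
})

test_that("planted single-cell DEGs are recovered by the DE engine", {
  cfg <- sc_sim_config(n_genes = 250L, n_mito = 5L, clusters = "c1",
                       lines = list(control = "a", mutants = "b"),
                       samples_per_line = 2L, cells_per_cluster = c(80L, 120L),
                       n_deg_per_cluster = 10L, deg_lfc = 1.5, seed = 48L)
  sim <- simulate_sc(cfg)
  m <- normalize_cells(sim$matrix)
  meta <- m$cell_meta
  de <- run_de(m, meta$cell_id[meta$line_id == "b"],
               meta$cell_id[meta$line_id == "a"])
  hits <- de$records$gene[de$records$fdr < 0.05]
  planted <- sim$truth$deg_table$gene
  expect_gte(length(intersect(hits, planted)), 8L)
  # planted signs are reproduced in the estimated fold changes
  est <- de$records$log2fc[match(planted, de$records$gene)]
  truth_sign <- sign(sim$truth$deg_table$lfc)
  ok <- !is.na(est)
  expect_true(all(sign(est[ok]) == truth_sign[ok]))
})
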