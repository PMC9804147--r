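cfg <- threshold_config()

make_pair <- function(n = 20L, drop = 3L, seed = 1L) {
  set.seed(seed)
  ga <- sprintf("GENE%02d", 1:n)
  gb <- sprintf("Gene%02d", 1:n)
  mk <- function(ids, model) {
    p <- runif(n)
    de_table(data.frame(gene = ids, log2fc = rnorm(n), pvalue = p,
                        fdr = bh_adjust(p)), model_id = model)
  }
  map <- ortholog_map(data.frame(source_id = ga[seq_len(n - drop)],
                                 target_id = gb[seq_len(n - drop)]))
  list(a = mk(ga, "a"), b = mk(gb, "b"), map = map)
}

test_that("ortholog join builds the joint universe by brute force", {
  pr <- make_pair(20L, drop = 3L)
  j <- join_on_orthologs(pr$a, pr$b, pr$map)
  # oracle: enumerate pairs whose members sit in both universes
  oracle <- mapply(function(s, t) s %in% pr$a$universe & t %in% pr$b$universe,
                   pr$map$source_id, pr$map$target_id)
  expect_equal(nrow(j$universe_pairs), sum(oracle))
  expect_equal(nrow(j$universe_pairs), 17L)

  # identity map over a shared id space: joint universe = universe intersection
  ji <- join_on_orthologs(pr$a, pr$a, identity_map(pr$a$universe))
  expect_setequal(ji$universe_pairs$gene_a, pr$a$universe)

  # a pair whose target is missing from B's universe is excluded
  b_small <- de_table(pr$b$records[-1, ], model_id = "b")
  j2 <- join_on_orthologs(pr$a, b_small, pr$map)
  expect_false("Gene01" %in% j2$universe_pairs$gene_b)

  # empty joint universe is an error
  m0 <- ortholog_map(data.frame(s = "NOPE", t = "Nope"))
  expect_error(join_on_orthologs(pr$a, pr$b, m0), "empty joint universe")
})

test_that("quadrant counts enumerate set membership", {
  U <- sprintf("u%02d", 1:20)
  expect_q <- function(q, v) expect_equal(unlist(q[c("n11", "n10", "n01", "n00")]),
                                          setNames(v, c("n11", "n10", "n01", "n00")))
  expect_q(quadrant_counts(U[1:5], U[6:13], U), c(0L, 5L, 8L, 7L))
  expect_q(quadrant_counts(U, U, U), c(20L, 0L, 0L, 0L))
  A <- U[1:5]; B <- U[c(2:5, 10:13)]   # |A|=5, |B|=8, overlap 4
  expect_q(quadrant_counts(A, B, U), c(4L, 1L, 4L, 11L))
  # members outside the universe are ignored
  expect_q(quadrant_counts(c(A, "zz"), B, U), c(4L, 1L, 4L, 11L))
  # literal variant: fourth cell is everything not in B
  expect_equal(quadrant_counts(A, B, U, literal = TRUE)$n00, 12L)
})

test_that("GME fold and p match exact enumeration and fisher.test", {
  q <- quadrant_table(4L, 1L, 4L, 11L)
  g <- gme(q)
  expect_equal(g$fold, 4 * 20 / (5 * 8))
  expect_equal(g$fold, 2)
  expect_equal(g$pvalue, enum_hyper_upper(4L, 20L, 5L, 8L), tolerance = 1e-12)
  expect_equal(g$pvalue,
               fisher.test(matrix(c(4, 4, 1, 11), 2), alternative = "greater")$p.value,
               tolerance = 1e-12)

  # zero overlap with non-empty margins: fold 0, p 1
  g0 <- gme(quadrant_table(0L, 5L, 8L, 7L))
  expect_equal(g0$fold, 0)
  expect_equal(g0$pvalue, 1)

  # empty marginal: fold undefined, p 1
  gu <- gme(quadrant_table(0L, 0L, 8L, 12L))
  expect_true(is.nan(gu$fold))
  expect_equal(gu$pvalue, 1)
})

test_that("GME is transpose-symmetric and fold = 1 at expected overlap", {
  set.seed(3)
  for (rep in 1:20) {
    cells <- as.integer(rmultinom(1, 60L, runif(4, 0.05, 1)))
    g1 <- gme(quadrant_table(cells[1], cells[2], cells[3], cells[4]))
    g2 <- gme(quadrant_table(cells[1], cells[3], cells[2], cells[4]))
    expect_equal(g1$fold, g2$fold)
    expect_equal(g1$pvalue, g2$pvalue, tolerance = 1e-12)
  }
  # (n11+n10)(n11+n01)/U = 6*10/30 = 2 = n11
  expect_equal(gme(quadrant_table(2L, 4L, 8L, 16L))$fold, 1)
})

test_that("fold equals the geometric mean of the two conditional enrichments", {
  set.seed(4)
  for (rep in 1:20) {
    cells <- as.integer(rmultinom(1, 80L, runif(4, 0.05, 1))) + 1L
    q <- quadrant_table(cells[1], cells[2], cells[3], cells[4])
    g <- gme(q)
    nA <- q$n11 + q$n10; nB <- q$n11 + q$n01
    e1 <- (q$n11 / nA) / (nB / q$U)
    e2 <- (q$n11 / nB) / (nA / q$U)
    expect_equal(g$fold, sqrt(e1 * e2), tolerance = 1e-12)
  }
})

test_that("all-quadrant GME recovers planted concordance and handles empties", {
  sim <- simulate_bulk_pair(bulk_sim_config(n_genes = 3000L, f_conc = 0.12,
                                            f_disc = 0, seed = 21L))
  j <- join_on_orthologs(sim$table_a, sim$table_b, sim$map)
  degs <- lapply(list(c("a", "up"), c("a", "down"), c("b", "up"), c("b", "down")),
                 function(x) extract_degs(sim[[paste0("table_", x[1])]], x[2], cfg))
  g <- gme_all_quadrants(degs[[1]], degs[[2]], degs[[3]], degs[[4]], j)
  expect_gt(g$up_up$fold, 1)
  expect_gt(g$down_down$fold, 1)
  expect_lt(g$up_up$pvalue, 1e-6)
  expect_lt(g$down_down$pvalue, 1e-6)

  g0 <- gme_all_quadrants(character(), character(), character(), character(), j)
  for (x in g0) {
    expect_true(is.nan(x$fold))
    expect_equal(x$pvalue, 1)
  }
})

test_that("least-squares fit matches hand-computed coefficients", {
  rec <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("a", "b", "c"),
                    log2fc_a = 0:2, pvalue_a = 0.01, fdr_a = 0.01,
                    log2fc_b = 0:2, pvalue_b = 0.01, fdr_b = 0.01)
  f <- lfc_regression(rec, c("a", "b", "c"))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)

  rec4 <- data.frame(gene_a = letters[1:4], gene_b = letters[1:4],
                     log2fc_a = 0:3, pvalue_a = 0.01, fdr_a = 0.01,
                     log2fc_b = c(0, 1, 0, 1), pvalue_b = 0.01, fdr_b = 0.01)
  f4 <- lfc_regression(rec4, letters[1:4])
  expect_equal(f4$slope, 0.2)
  expect_equal(f4$intercept, 0.2)
  expect_equal(f4$r2, 0.2)

  # r2 equals squared Pearson correlation
  set.seed(5)
  recr <- data.frame(gene_a = sprintf("g%02d", 1:40), gene_b = sprintf("g%02d", 1:40),
                     log2fc_a = rnorm(40), pvalue_a = 0.01, fdr_a = 0.01,
                     log2fc_b = rnorm(40), pvalue_b = 0.01, fdr_b = 0.01)
  fr <- lfc_regression(recr, recr$gene_a)
  expect_equal(fr$r2, cor(recr$log2fc_a, recr$log2fc_b)^2, tolerance = 1e-10)

  # undefined fit below 3 genes
  expect_false(lfc_regression(rec[1:2, ], c("a", "b"))$valid)
})

test_that("threshold sweep reduces to single fits and never gains genes", {
  sim <- simulate_bulk_pair(bulk_sim_config(n_genes = 2000L, seed = 9L))
  j <- join_on_orthologs(sim$table_a, sim$table_b, sim$map)
  xd <- list(extract_degs(sim$table_a, "up", cfg),
             extract_degs(sim$table_a, "down", cfg))
  sw <- threshold_sweep(j, xd)
  expect_equal(sw[["none"]], lfc_regression(j, xd, "none"))
  ns <- vapply(sw, `[[`, integer(1), "n_genes")
  expect_true(all(diff(ns) <= 0))
})

test_that("sign consistency counts raw agreement with an exact binomial p", {
  tab <- de_table(data.frame(gene = sprintf("g%d", 1:6),
                             log2fc = c(0.4, 0.2, 0.9, 1.1, 0.05, -0.3),
                             pvalue = 0.5, fdr = 0.9))
  all_up <- sign_consistency(sprintf("g%d", 1:5), "up", tab)
  expect_equal(all_up$n_agree, 5L)
  expect_equal(all_up$n_total, 5L)

  four <- sign_consistency(sprintf("g%d", 2:6), "up", tab)
  expect_equal(four$n_agree, 4L)
  expect_equal(four$p_binomial, 0.375)
  expect_equal(four$p_binomial, enum_binom_two_sided(4L, 5L))

  expect_message(miss <- sign_consistency(c("g1", "nope"), "up", tab), "dropped")
  expect_equal(miss$n_total, 1L)

  # zero log2fc counts as disagreement
  zero_tab <- de_table(data.frame(gene = "z", log2fc = 0, pvalue = 1, fdr = 1))
  expect_equal(sign_consistency("z", "up", zero_tab)$n_agree, 0L)
})
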