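test_that("generator is deterministic and honors the latent-factor model", {
  cfg <- synthetic_config(n_genes = 100, n_samples_case = 8,
                          n_samples_control = 6, n_modules = 2,
                          module_sizes = c(20L, 20L), seed = 5,
                          missing_rate = 0.02)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$discriminative_genes, b$truth$discriminative_genes)

  # near-noise-free single module: within-module correlations ~ 1
  cfg1 <- synthetic_config(n_genes = 30, n_samples_case = 6,
                           n_samples_control = 6, n_modules = 1,
                           module_sizes = 30L, factor_loading = 1,
                           noise_sd = 1e-8, n_discriminative = 0,
                           factor_shift = 0, seed = 2)
  m <- generate_expression(cfg1)$expression
  cm <- cor(t(m))
  expect_true(all(abs(cm) > 1 - 1e-6))
  expect_true(all(abs(cm)^6 > 1 - 1e-4))   # adjacency ~ 1 at any power

  expect_error(synthetic_config(n_genes = 10, module_sizes = c(8L, 8L),
                                n_modules = 2), "exceeds")
})

test_that("planted modules are detectably co-expressed against background", {
  cfg <- synthetic_config(n_genes = 2000, n_samples_case = 40,
                          n_samples_control = 32, n_modules = 4,
                          module_sizes = rep(100L, 4), factor_loading = 0.8,
                          noise_sd = 1, n_discriminative = 0,
                          factor_shift = 0, seed = 7)
  sim <- generate_expression(cfg)
  cm <- abs(cor(t(sim$expression)))
  lab <- sim$truth$module_label_per_gene
  same <- outer(lab, lab, "==") & lab != "background"
  diag(same) <- NA
  bg <- outer(lab == "background", lab == "background", "&")
  diag(bg) <- NA
  within <- mean(cm[which(same)], na.rm = TRUE)
  background <- mean(cm[which(bg)], na.rm = TRUE)
  expect_gt(within, background)
  expect_gt(within, 0.3)   # planted structure detectable at stated settings
})

test_that("missingness mask hits its rate within binomial bounds", {
  cfg <- synthetic_config(n_genes = 500, n_samples_case = 20,
                          n_samples_control = 20, missing_rate = 0.05,
                          seed = 3)
  m <- generate_expression(cfg)$expression
  n <- length(m)
  k <- sum(is.na(m))
  bounds <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("planted-hub graph has the constructed degree structure", {
  # star: no background edges, one hub boosted by 5 in a 10-node graph
  g1 <- generate_ppi_graph(10, 1, 5, edge_prob = 0, seed = 1)
  deg <- igraph::degree(g1$graph)
  expect_equal(igraph::ecount(g1$graph), 5)
  expect_equal(unname(deg[g1$truth$planted_hubs]), 5)
  expect_equal(sort(unname(deg), decreasing = TRUE)[2], 1)

  # complete graph at edge_prob 1 (no room to boost, so zero boost)
  g2 <- generate_ppi_graph(6, 1, 0, edge_prob = 1, seed = 1)
  expect_true(all(igraph::degree(g2$graph) == 5))

  # planted hubs occupy the top degree ranks
  g3 <- generate_ppi_graph(60, 5, 12, edge_prob = 0.05, seed = 3)
  deg3 <- sort(igraph::degree(g3$graph), decreasing = TRUE)
  expect_setequal(names(deg3)[1:5], g3$truth$planted_hubs)

  expect_error(generate_ppi_graph(10, 1, 9, edge_prob = 1, seed = 1),
               "non-neighbors")
  expect_error(generate_ppi_graph(5, 5, 1, edge_prob = 0, seed = 1), "n_hubs")
})

test_that("enriched gene sets carry more group signal than null sets", {
  cfg <- synthetic_config(n_genes = 400, n_samples_case = 20,
                          n_samples_control = 20, n_modules = 2,
                          module_sizes = c(60L, 60L), trait_effect = 1.5,
                          n_discriminative = 40, seed = 11)
  sim <- generate_expression(cfg)
  sets <- generate_gene_sets(sim$truth, n_enriched = 5, n_null = 5,
                             set_size = 30, seed = 4)
  grp <- sim$phenotypes$group
  mdiff <- function(genes) {
    sub <- sim$expression[genes, , drop = FALSE]
    mean(abs(rowMeans(sub[, grp == "AS"]) - rowMeans(sub[, grp == "HC"])))
  }
  enr <- mean(vapply(sets[grep("^ENRICHED", names(sets))], mdiff, numeric(1)))
  nul <- mean(vapply(sets[grep("^NULL", names(sets))], mdiff, numeric(1)))
  expect_gt(enr, nul)

  # degenerate sizes
  all_g <- generate_gene_sets(sim$truth, 0, 1, set_size = 400, seed = 1)
  expect_setequal(all_g$NULL_1, rownames(sim$expression))
  expect_error(generate_gene_sets(sim$truth, 1, 1, set_size = 401, seed = 1),
               "exceeds")
})

test_that("severity is case-only, clipped to [0,10], and tracks its drivers", {
  cfg <- synthetic_config(n_genes = 50, n_samples_case = 20,
                          n_samples_control = 10, n_modules = 1,
                          module_sizes = 20L, n_discriminative = 5, seed = 8)
  sim <- generate_expression(cfg)
  drv <- rownames(sim$expression)[1]

  # noise-free single driver: Pearson r with that gene is 1 among cases
  sev <- generate_severity(sim$phenotypes, sim$expression, drv,
                           coupling = 1, seed = 1, noise_sd = 0)
  cases <- sim$phenotypes$group == "AS"
  expect_true(all(is.na(sev[!cases])))
  expect_true(all(sev[cases] >= 0 & sev[cases] <= 10))
  expect_equal(cor(sev[cases], sim$expression[drv, cases]), 1)

  # coupling 0: r below the alpha = 0.05 critical value in >= 90% of seeds
  n <- sum(cases)
  r_crit <- sqrt(qt(0.975, n - 2)^2 / (n - 2 + qt(0.975, n - 2)^2))
  hits <- vapply(1:100, function(s) {
    s0 <- generate_severity(sim$phenotypes, sim$expression, drv,
                            coupling = 0, seed = s)
    abs(cor(s0[cases], sim$expression[drv, cases])) < r_crit
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ph_nocase <- sim$phenotypes
  ph_nocase$group <- "HC"
  expect_error(generate_severity(ph_nocase, sim$expression, drv, 1, 1),
               "no case")
})
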