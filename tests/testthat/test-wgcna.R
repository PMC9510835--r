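test_that("scale-free fit index is +1 for a decaying power law, -1 for a rising one", {
  # connectivity values 1..10 placed so each lands in its own equal-width
  # bin; frequency exactly proportional to k^-1 gives a perfect log-linear
  # fit with slope -1 and signed R^2 = +1
  k_dec <- rep(1:10, times = 2520 / (1:10))
  fit <- scale_free_fit(k_dec, n_bins = 10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(fit$slope, -1, tolerance = 1e-6)

  k_inc <- rep(1:10, times = (1:10)^2)
  fit2 <- scale_free_fit(k_inc, n_bins = 10)
  expect_equal(fit2$r_squared, -1, tolerance = 1e-6)
  expect_equal(fit2$slope, 2, tolerance = 1e-6)

  expect_error(scale_free_fit(rep(3, 50)), "degenerate")
})

test_that("soft-threshold scan matches a cell-by-cell brute-force rescan", {
  set.seed(1)
  mat <- matrix(rnorm(100 * 30), 100, 30,
                dimnames = list(sprintf("G%03d", 1:100), sprintf("S%02d", 1:30)))
  st <- suppressWarnings(pick_soft_threshold(mat, powers = 1:10))

  # brute force: adjacency entry by entry, connectivity by explicit sums
  brute <- sapply(1:10, function(beta) {
    n <- nrow(mat)
    k <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) {
        if (i == j) next
        s <- s + abs(cor(mat[i, ], mat[j, ]))^beta
      }
      k[i] <- s
    }
    c(scale_free_fit(k)$r_squared, mean(k))
  })
  expect_equal(st$scan$r_squared[1:10], brute[1, ], tolerance = 1e-10)
  expect_equal(st$scan$mean_k[1:10], brute[2, ], tolerance = 1e-10)

  # chosen beta is minimal among adequate powers
  ok <- which(st$scan$r_squared >= 0.9)
  if (length(ok)) {
    expect_equal(st$beta, st$scan$power[min(ok)])
    expect_true(all(st$scan$r_squared[st$scan$power < st$beta] < 0.9,
                    na.rm = TRUE))
  }

  # degenerate input (all correlations 1) is flagged
  ones <- outer(1:40, seq_len(12)) + 0
  dimnames(ones) <- list(sprintf("G%02d", 1:40), sprintf("S%02d", 1:12))
  expect_error(suppressWarnings(pick_soft_threshold(ones)), "degenerate")
})

test_that("adjacency transform follows the power law in |cor|", {
  expect_equal(adjacency_from_cor(matrix(c(1, -0.5, -0.5, 1), 2), 1)[1, 2], 0.5)
  expect_equal(adjacency_from_cor(matrix(c(1, 1, 1, 1), 2), 7)[1, 2], 1)
  set.seed(2)
  cm <- cor(matrix(rnorm(200), 20, 10))
  a1 <- adjacency_from_cor(cm, 1)
  a2 <- adjacency_from_cor(cm, 2)
  expect_equal(a2, a1^2)
  expect_error(adjacency_from_cor(cm, 0.5), "beta")
  # signed variant
  s <- adjacency_from_cor(matrix(c(1, -1, -1, 1), 2), 2, mode = "signed")
  expect_equal(s[1, 2], 0)
})

test_that("TOM matches the formula by hand and by triple loop", {
  # two genes, a_12 = 1, no other neighbors: TOM = (0+1)/(min(1,1)+1-1) = 1
  a <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(tom_similarity(a)[1, 2], 1)

  # zero adjacency -> identity
  z <- matrix(0, 4, 4)
  expect_equal(tom_similarity(z), diag(4))

  set.seed(11)
  r <- matrix(runif(36), 6, 6)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  expect_equal(tom_similarity(r), oracle_tom(r), tolerance = 1e-12)

  # bounds on random adjacencies
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(runif(100), 10, 10); r <- (r + t(r)) / 2; diag(r) <- 0
    tm <- tom_similarity(r)
    expect_true(all(tm >= 0 - 1e-12 & tm <= 1 + 1e-12))
    expect_equal(tm, t(tm))
  }
})

test_that("module detection recovers planted blocks and applies the size rule", {
  # two noise-free blocks with exactly orthogonal factors
  f1 <- rep(c(1, -1), 10)
  f2 <- rep(c(1, 1, -1, -1), 5)
  mat <- rbind(outer(seq(0.5, 1.5, length.out = 40), f1),
               outer(seq(0.5, 1.5, length.out = 40), f2))
  dimnames(mat) <- list(sprintf("G%03d", 1:80), sprintf("S%02d", 1:20))
  tom <- tom_similarity(adjacency_from_cor(cor(t(mat)), 6))
  mod <- detect_modules(tom, mat, min_size = 30)
  expect_equal(length(mod$sizes), 2L)
  expect_true(all(mod$sizes == 40))
  expect_false(any(mod$labels == "grey"))
  # labels constant within each planted block
  expect_equal(length(unique(mod$labels[1:40])), 1L)
  expect_equal(length(unique(mod$labels[41:80])), 1L)

  # a block smaller than min_size goes grey
  small <- mat[1:10, ]
  tom_s <- tom_similarity(adjacency_from_cor(cor(t(small)), 6))
  expect_warning(mod_s <- detect_modules(tom_s, small, min_size = 30),
                 "min_size")
  expect_true(all(mod_s$labels == "grey"))
})

test_that("module detection is invariant to gene input order", {
  cfg <- synthetic_config(n_genes = 300, n_samples_case = 20,
                          n_samples_control = 16, n_modules = 3,
                          module_sizes = rep(60L, 3), factor_loading = 0.9,
                          noise_sd = 0.5, n_discriminative = 0,
                          factor_shift = 0, seed = 14)
  mat <- generate_expression(cfg)$expression
  tom <- tom_similarity(adjacency_from_cor(cor(t(mat)), 6))
  mod <- detect_modules(tom, mat)

  set.seed(1)
  perm <- sample(nrow(mat))
  mat_p <- mat[perm, ]
  tom_p <- tom_similarity(adjacency_from_cor(cor(t(mat_p)), 6))
  mod_p <- detect_modules(tom_p, mat_p)
  common <- rownames(mat)
  expect_equal(adjusted_rand_index(mod$labels[common], mod_p$labels[common]), 1)
})

test_that("module eigengene has unit norm, sign convention, and exact variance share", {
  # identical genes: variance explained is 1
  base <- rnorm(10)
  sub <- outer(rep(1, 5), base) + 3
  dimnames(sub) <- list(paste0("G", 1:5), paste0("S", 1:10))
  me <- module_eigengene(sub)
  expect_equal(me$var_explained, 1)
  expect_gte(cor(me$eigengene, scale(base)[, 1]), 0.999)

  # negating the data leaves the sign convention intact
  me_neg <- module_eigengene(-sub)
  z <- t(scale(t(-sub)))
  expect_gte(cor(me_neg$eigengene, colMeans(z)), 0)

  # random module: variance explained equals the leading eigenvalue share
  set.seed(2)
  sub2 <- matrix(rnorm(200), 20, 10,
                 dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
  me2 <- module_eigengene(sub2)
  z2 <- t(scale(t(sub2)))
  ev <- eigen(t(z2) %*% z2, symmetric = TRUE)$values
  expect_equal(me2$var_explained, ev[1] / sum(ev), tolerance = 1e-10)
  expect_equal(sum(me2$eigengene^2), 1, tolerance = 1e-12)

  sub3 <- sub2; sub3[1, ] <- 5
  expect_warning(module_eigengene(sub3), "zero-variance")
})

test_that("module-trait correlation selects by |r| >= cutoff with t-test p", {
  ph <- data.frame(sample_id = sprintf("S%02d", 1:20),
                   group = rep(c("AS", "HC"), each = 10))
  trait <- as.numeric(ph$group == "AS")
  me <- cbind(perfect = trait,
              orth = rep(c(1, -1), 10))
  rownames(me) <- ph$sample_id
  mt <- module_trait_correlation(me, ph, cutoff = 0.3)
  expect_equal(mt$r[mt$module == "perfect"], 1)
  expect_true(mt$selected[mt$module == "perfect"])
  expect_equal(mt$r[mt$module == "orth"], 0)
  expect_false(mt$selected[mt$module == "orth"])

  me_bad <- cbind(flat = rep(1, 20)); rownames(me_bad) <- ph$sample_id
  expect_error(module_trait_correlation(me_bad, ph), "constant")
})

test_that("trait-linked module attains the largest |module-trait r| across seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_genes = 300, n_samples_case = 26,
                            n_samples_control = 10, n_modules = 3,
                            module_sizes = rep(60L, 3), factor_loading = 0.8,
                            factor_shift = 1.0, n_discriminative = 0,
                            noise_sd = 1, seed = s)
    sim <- generate_expression(cfg)
    lab <- sim$truth$module_label_per_gene
    me <- sapply(paste0("M", 1:3), function(m) {
      module_eigengene(sim$expression[lab == m, ])$eigengene
    })
    mt <- module_trait_correlation(me, sim$phenotypes)
    mt$module[which.max(abs(mt$r))] == "M1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("gene significance and module membership behave as correlations", {
  cfg <- synthetic_config(n_genes = 200, n_samples_case = 20,
                          n_samples_control = 16, n_modules = 2,
                          module_sizes = c(50L, 50L), factor_loading = 0.9,
                          factor_shift = 1, n_discriminative = 30,
                          noise_sd = 0.5, seed = 19)
  sim <- generate_expression(cfg)
  lab <- sim$truth$module_label_per_gene
  me <- sapply(c("M1", "M2"), function(m) {
    module_eigengene(sim$expression[lab == m, ])$eigengene
  })
  # a pseudo-gene equal to an eigengene has MM = 1
  mat2 <- rbind(sim$expression, EGENE = me[, "M1"])
  gts <- gene_trait_stats(mat2, me, sim$phenotypes,
                          labels = c(lab, EGENE = "M1"))
  expect_equal(unname(gts$mm["EGENE", "M1"]), 1, tolerance = 1e-12)
  expect_true(all(gts$gs >= 0 & gts$gs <= 1))
  expect_true(all(gts$mm >= -1 & gts$mm <= 1))

  # MM vs GS positive in the trait-linked module
  expect_gt(gts$module_summary$cor_mm_gs[gts$module_summary$module == "M1"], 0)

  # trait-independent noise gene: GS below the critical |r| in >= 90% of seeds
  n <- ncol(sim$expression)
  tcrit <- qt(0.975, n - 2)
  r_crit <- sqrt(tcrit^2 / (n - 2 + tcrit^2))
  trait <- as.numeric(sim$phenotypes$group == "AS")
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    abs(cor(rnorm(n), trait)) < r_crit
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("preservation Z separates planted modules from random labelings", {
  # noise-free planted module scores far above a random gene subset
  f <- rnorm(24)
  mat <- rbind(outer(seq(0.5, 1.5, length.out = 30), f),
               matrix(rnorm(70 * 24), 70, 24))
  dimnames(mat) <- list(sprintf("G%03d", 1:100), sprintf("S%02d", 1:24))
  lab <- setNames(c(rep("planted", 30), rep("grey", 70)), rownames(mat))
  lab_null <- lab
  set.seed(3)
  lab_null[] <- "grey"
  lab_null[sample(100, 30)] <- "rand"
  z_planted <- preservation_z(mat, lab, n_permutations = 50, seed = 1)
  z_rand <- preservation_z(mat, lab_null, n_permutations = 50, seed = 1)
  expect_gt(z_planted[["planted"]], z_rand[["rand"]])
  expect_gt(z_planted[["planted"]], 3)

  # null calibration: random subsets of pure noise rarely reach |Z| = 3
  noise <- matrix(rnorm(60 * 20), 60, 20,
                  dimnames = list(sprintf("G%02d", 1:60), sprintf("S%02d", 1:20)))
  zs <- vapply(1:50, function(s) {
    set.seed(s)
    l <- setNames(rep("grey", 60), rownames(noise))
    l[sample(60, 20)] <- "m"
    preservation_z(noise, l, n_permutations = 60, seed = s)[["m"]]
  }, numeric(1))
  expect_gte(mean(abs(zs) < 3), 0.9)

  expect_error(preservation_z(noise, setNames(rep("m", 60), rownames(noise)),
                              n_permutations = 0), "n_permutations")
})
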