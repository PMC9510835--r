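test_that("hand-evaluated centralities on the 3-path, triangle and star", {
  # path A - B - C
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  g <- graph_from_adj(A, c("A", "B", "C"))
  ct <- compute_centralities(g, epc_trials = 10, epc_keep_prob = 1)
  expect_equal(ct["B", "Betweenness"], 1)
  expect_equal(ct["B", "Stress"], 1)
  expect_equal(ct["B", "Closeness"], 2)
  expect_equal(ct["B", "Degree"], 2)
  expect_equal(ct["B", "Eccentricity"], 1)
  expect_equal(ct["B", "Radiality"], 2)
  expect_equal(ct["A", ], ct["C", ], ignore_attr = TRUE)

  # triangle
  Tr <- matrix(1, 3, 3); diag(Tr) <- 0
  gt <- graph_from_adj(Tr)
  ctt <- compute_centralities(gt, epc_trials = 10, epc_keep_prob = 1)
  expect_true(all(ctt$MCC == 2))
  expect_true(all(ctt$ClusteringCoefficient == 1))
  expect_true(all(ctt$MNC == 2))
  expect_true(all(abs(ctt$DMNC - 1 / 2^1.7) < 1e-12))

  # star K1,4 with the hub as first node
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1
  gs <- graph_from_adj(S, c("hub", paste0("leaf", 1:4)))
  cts <- compute_centralities(gs, epc_trials = 10, epc_keep_prob = 1)
  expect_equal(cts["hub", "MNC"], 1)
  expect_equal(cts["hub", "MCC"], 4)
  expect_equal(cts["hub", "Betweenness"], 6)

  # EPC with keep probability 1 equals n - 1 on any connected graph
  expect_true(all(cts$EPC == 4))

  expect_error(compute_centralities(gs, measures = "Foo"), "unknown")
})

test_that("centralities match brute force on all graphs up to 5 nodes", {
  for (n in 2:5) {
    for (A in nonisomorphic_graphs(n)) {
      got <- compute_centralities(graph_from_adj(A), epc_trials = 1,
                                  epc_keep_prob = 1, seed = 1)
      want <- oracle_centralities(A)
      for (m in setdiff(names(want), "EPC1")) {
        expect_equal(got[[m]], want[[m]], tolerance = 1e-10,
                     label = paste0(m, " (n=", n, ")"))
      }
      expect_equal(got$EPC, want$EPC1, tolerance = 1e-10)
    }
  }
})

test_that("EPC on K4 is within 3 Monte-Carlo SEs of its exact expectation", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  # exact expectation by enumerating all 2^6 edge subsets at keep prob 0.5
  edges <- which(upper.tri(K4), arr.ind = TRUE)
  vals <- matrix(0, 2^6, 4)
  for (b in 0:(2^6 - 1)) {
    B <- matrix(0, 4, 4)
    for (e in 1:6) {
      if (bitwAnd(b %/% 2^(e - 1), 1)) {
        B[edges[e, 1], edges[e, 2]] <- 1
        B[edges[e, 2], edges[e, 1]] <- 1
      }
    }
    reach <- diag(4) + B
    for (i in 1:3) reach <- (reach %*% (diag(4) + B)) > 0
    vals[b + 1, ] <- rowSums(reach) - 1
  }
  exact_mean <- colMeans(vals)
  exact_var <- apply(vals, 2, var)

  trials <- 2000
  got <- compute_centralities(graph_from_adj(K4), epc_trials = trials,
                              epc_keep_prob = 0.5, seed = 7)$EPC
  se <- sqrt(exact_var / trials)
  expect_true(all(abs(got - exact_mean) <= 3 * se))
})

test_that("centralities are invariant under node relabeling", {
  g <- generate_ppi_graph(25, 2, 6, edge_prob = 0.15, seed = 9)$graph
  ct <- compute_centralities(g, epc_trials = 50, seed = 1)
  set.seed(2)
  newnames <- paste0("X", sample(sprintf("%02d", 1:25)))
  g2 <- g
  igraph::V(g2)$name <- newnames
  ct2 <- compute_centralities(g2, epc_trials = 50, seed = 1)
  # EPC excluded: relabeling changes which vertices get which random draws.
  # BottleNeck excluded: its deterministic smallest-id parent rule makes the
  # shortest-path tree (and hence the score) depend on the labeling whenever
  # several parents are tied, by construction.
  det_meas <- setdiff(centrality_measures(), c("EPC", "BottleNeck"))
  old_of_new <- setNames(igraph::V(g)$name, newnames)
  expect_equal(as.matrix(ct2[, det_meas]),
               as.matrix(ct[old_of_new[rownames(ct2)], det_meas]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("adding an edge never decreases Degree or MCC of its endpoints", {
  set.seed(4)
  for (i in 1:5) {
    g <- generate_ppi_graph(12, 1, 3, edge_prob = 0.2, seed = i)$graph
    non_edges <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(matrix(0, 12, 12)), arr.ind = TRUE)
    if (!nrow(non_edges)) next
    pick <- non_edges[1, ]
    g2 <- igraph::add_edges(g, igraph::V(g)$name[c(pick[1], pick[2])])
    before <- compute_centralities(g, epc_trials = 1, epc_keep_prob = 1,
                                   measures = c("Degree", "MCC"))
    after <- compute_centralities(g2, epc_trials = 1, epc_keep_prob = 1,
                                  measures = c("Degree", "MCC"))
    ends <- igraph::V(g)$name[c(pick[1], pick[2])]
    expect_true(all(after[ends, "Degree"] >= before[ends, "Degree"]))
    expect_true(all(after[ends, "MCC"] >= before[ends, "MCC"]))
  }
})

test_that("top-fraction selection sizes, ties, and ordering are deterministic", {
  sc <- setNames(c(5, 4, 3, 2, 1, 1, 1, 0), paste0("n", 1:8))
  expect_equal(top_fraction(sc, 0.25), c("n1", "n2"))
  expect_equal(top_fraction(sc, 1), names(sort(-sc)))
  ties <- setNames(rep(2, 8), paste0("n", 8:1))
  expect_equal(top_fraction(ties, 0.25), c("n1", "n2"))
  expect_error(top_fraction(numeric(0)), "empty")
  expect_error(top_fraction(sc, 0), "fraction")
})

test_that("consensus hub rule counts occurrences with a strict threshold", {
  set.seed(1)
  n <- 20
  tab <- as.data.frame(replicate(12, rnorm(n), simplify = FALSE),
                       col.names = centrality_measures())
  rownames(tab) <- sprintf("v%02d", 1:n)

  # identical scores across all measures: hubs = the top 25%, occurrence 12
  same <- tab
  same[] <- tab[[1]]
  hs <- consensus_hubs(same)
  top <- top_fraction(setNames(same[[1]], rownames(same)), 0.25)
  expect_setequal(hs$hubs, top)
  expect_true(all(hs$occurrence[hs$hubs] == 12))

  # a node in exactly 4 lists is not a hub ("more than 4" is strict)
  tab4 <- tab
  tab4[, 1:4] <- 0; tab4["v01", 1:4] <- 10    # v01 tops measures 1-4 only
  tab4[, 5:12] <- matrix(rep(n:1, 8), n)      # v20 ... ordering elsewhere
  tab4["v01", 5:12] <- -1
  hs4 <- consensus_hubs(tab4)
  expect_equal(unname(hs4$occurrence["v01"]), 4L)
  expect_false("v01" %in% hs4$hubs)

  # column order cannot matter
  hs_perm <- consensus_hubs(tab[, sample(12)])
  expect_identical(consensus_hubs(tab)$hubs, hs_perm$hubs)

  expect_warning(consensus_hubs(tab, min_count = 13), "exceeds")
})

test_that("planted hubs are recovered by the consensus rule", {
  sim <- generate_ppi_graph(60, 5, 12, edge_prob = 0.05, seed = 3)
  ct <- compute_centralities(sim$graph, epc_trials = 500, seed = 1)
  hs <- consensus_hubs(ct, fraction = 0.25, min_count = 5)
  expect_true(all(sim$truth$planted_hubs %in% hs$hubs))
})
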