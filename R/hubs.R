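#' The twelve node-centrality measures
#'
#' Computes, for every node of an undirected simple graph, the twelve
#' topological scores used for consensus hub ranking: Degree, Betweenness,
#' Closeness (harmonic, so disconnected graphs are handled and larger is
#' always more central), Eccentricity (reciprocal of the within-component
#' eccentricity), Radiality, Stress, ClusteringCoefficient, MNC (maximum
#' neighborhood component), DMNC (density of the maximum neighborhood
#' component, E/V^1.7), MCC (maximal clique centrality, sum of
#' (|clique|-1)! over maximal cliques containing the node), BottleNeck
#' (over BFS shortest-path trees from every root, made deterministic by a
#' smallest-id parent rule), and EPC (edge percolated component: expected
#' number of nodes still connected to the node when each edge is kept
#' independently with probability `epc_keep_prob`, estimated over
#' `epc_trials` seeded trials).
#'
#' All scores are oriented so that larger means more central. Distances
#' are unweighted; pairs in different components contribute nothing.
#'
#' @param g Undirected simple igraph with named vertices.
#' @param epc_trials Monte-Carlo trials for EPC.
#' @param epc_keep_prob Edge retention probability for EPC.
#' @param seed Integer seed (EPC is the only stochastic measure).
#' @param measures Character subset of the twelve (default all).
#' @return data.frame, one row per node (rownames = node ids), one column
#'   per requested measure.
#' @export
compute_centralities <- function(g, epc_trials = 1000, epc_keep_prob = 0.5,
                                 seed = 1, measures = centrality_measures()) {
  stopifnot(igraph::vcount(g) >= 2L, !igraph::is_directed(g))
  unknown <- setdiff(measures, centrality_measures())
  if (length(unknown)) stop("unknown measure(s): ", paste(unknown, collapse = ", "))
  # canonical vertex order (sorted names) so id-based tie rules are stable
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  g <- igraph::permute(g, match(nm, sort(nm)))
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  D <- igraph::distances(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  comp <- igraph::components(g)
  comp_id <- comp$membership
  comp_size <- comp$csize[comp_id]

  out <- list()
  if ("Degree" %in% measures) out$Degree <- as.numeric(igraph::degree(g))
  if ("Betweenness" %in% measures) {
    out$Betweenness <- as.numeric(igraph::betweenness(g, directed = FALSE))
  }
  if ("Closeness" %in% measures) {
    inv <- 1 / D; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    out$Closeness <- rowSums(inv)
  }
  if ("Eccentricity" %in% measures) {
    ecc <- apply(D, 1L, function(r) {
      r <- r[is.finite(r) & r > 0]
      if (!length(r)) 0 else 1 / max(r)
    })
    out$Eccentricity <- as.numeric(ecc)
  }
  if ("Radiality" %in% measures) {
    rad <- numeric(n)
    for (c_ in seq_len(comp$no)) {
      idx <- which(comp_id == c_)
      if (length(idx) < 2L) next
      sub <- D[idx, idx, drop = FALSE]
      delta <- max(sub)
      rad[idx] <- (rowSums(delta + 1 - sub) - (delta + 1)) / (length(idx) - 1)
    }
    out$Radiality <- rad
  }
  need_sigma <- any(c("Stress", "BottleNeck") %in% measures)
  sigma <- if ("Stress" %in% measures) .sp_counts(adj, D, n) else NULL
  if ("Stress" %in% measures) {
    stress <- numeric(n)
    for (v in seq_len(n)) {
      through <- outer(D[, v], D[v, ], `+`) == D
      through[!is.finite(D)] <- FALSE
      through[v, ] <- FALSE; through[, v] <- FALSE
      diag(through) <- FALSE
      paths <- outer(sigma[, v], sigma[v, ]) * through
      stress[v] <- sum(paths) / 2
    }
    out$Stress <- stress
  }
  if ("ClusteringCoefficient" %in% measures) {
    out$ClusteringCoefficient <-
      igraph::transitivity(g, type = "local", isolates = "zero")
  }
  if (any(c("MNC", "DMNC") %in% measures)) {
    mnc <- numeric(n); dmnc <- numeric(n)
    for (v in seq_len(n)) {
      nb <- adj[[v]]
      if (!length(nb)) next
      sub <- igraph::induced_subgraph(g, nb)
      cc <- igraph::components(sub)
      best <- which(cc$csize == max(cc$csize))
      if (length(best) > 1L) {  # tie: component with most edges
        ec <- vapply(best, function(b) igraph::ecount(
          igraph::induced_subgraph(sub, which(cc$membership == b))), numeric(1L))
        best <- best[which.max(ec)]
      } else best <- best[1L]
      vs <- which(cc$membership == best)
      mnc[v] <- length(vs)
      if (length(vs) > 1L) {
        m_edges <- igraph::ecount(igraph::induced_subgraph(sub, vs))
        dmnc[v] <- m_edges / length(vs)^1.7
      }
    }
    if ("MNC" %in% measures) out$MNC <- mnc
    if ("DMNC" %in% measures) out$DMNC <- dmnc
  }
  if ("MCC" %in% measures) {
    mcc <- numeric(n)
    cliques <- igraph::max_cliques(g)
    for (cl in cliques) {
      idx <- as.integer(cl)
      mcc[idx] <- mcc[idx] + factorial(length(idx) - 1L)
    }
    out$MCC <- mcc
  }
  if ("BottleNeck" %in% measures) {
    bn <- numeric(n)
    for (s in seq_len(n)) {
      idx <- which(comp_id == comp_id[s])
      if (length(idx) < 2L) next
      sub_size <- .bfs_subtree_sizes(adj, D, s, idx)
      big <- idx[idx != s & sub_size[idx] > length(idx) / 4]
      bn[big] <- bn[big] + 1
    }
    out$BottleNeck <- bn
  }
  if ("EPC" %in% measures) {
    set.seed(seed)
    m <- igraph::ecount(g)
    acc <- numeric(n)
    for (t_ in seq_len(epc_trials)) {
      keep <- which(stats::runif(m) < epc_keep_prob)
      sg <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
      cc <- igraph::components(sg)
      acc <- acc + (cc$csize[cc$membership] - 1)
    }
    out$EPC <- acc / epc_trials
  }
  df <- as.data.frame(out[intersect(centrality_measures(), measures)],
                      row.names = nodes)
  df
}

#' @rdname compute_centralities
#' @export
centrality_measures <- function() {
  c("Degree", "Betweenness", "Closeness", "Eccentricity", "Radiality",
    "Stress", "ClusteringCoefficient", "MNC", "DMNC", "MCC",
    "BottleNeck", "EPC")
}

# shortest-path counts sigma[s, v] by BFS layers
.sp_counts <- function(adj, D, n) {
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- D[s, ]
    sigma[s, s] <- 1
    reach <- which(is.finite(d) & d > 0)
    for (v in reach[order(d[reach])]) {
      prev <- adj[[v]][d[adj[[v]]] == d[v] - 1]
      sigma[s, v] <- sum(sigma[s, prev])
    }
  }
  sigma
}

# subtree sizes of the deterministic BFS tree rooted at s (parent =
# neighbor one layer up with smallest index); sizes include the node itself
.bfs_subtree_sizes <- function(adj, D, s, comp_idx) {
  d <- D[s, ]
  size <- numeric(length(adj))
  size[comp_idx] <- 1
  ord <- comp_idx[order(d[comp_idx], decreasing = TRUE)]
  for (v in ord) {
    if (v == s || !is.finite(d[v]) || d[v] == 0) next
    parents <- adj[[v]][d[adj[[v]]] == d[v] - 1]
    par <- min(parents)
    size[par] <- size[par] + size[v]
  }
  size
}

#' Top fraction of nodes by a score
#'
#' @param scores Named numeric vector.
#' @param fraction Fraction to keep, in (0, 1]; ceil(fraction * n) nodes.
#' @return Node ids in descending score order; boundary ties broken by
#'   ascending node id.
#' @export
top_fraction <- function(scores, fraction = 0.25) {
  if (!length(scores)) stop("empty score vector")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- ceiling(fraction * length(scores))
  ord <- order(-scores, names(scores))
  names(scores)[ord][seq_len(n_keep)]
}

#' Consensus hub selection across centrality rankings
#'
#' Takes the top `fraction` of nodes under each centrality, counts in how
#' many of the per-measure lists each node occurs, and calls a node a hub
#' when it occurs in at least `min_count` lists (default 5, i.e. strictly
#' more than 4 of the 12).
#'
#' @param table Centrality data.frame from [compute_centralities()].
#' @param fraction Top fraction per measure (default 0.25).
#' @param min_count Minimum occurrence count for hub status (default 5).
#' @return list(top_lists, occurrence = named counts, hubs = sorted ids).
#' @export
consensus_hubs <- function(table, fraction = 0.25, min_count = 5) {
  if (ncol(table) < 1L) stop("no centrality measures in table")
  if (min_count > ncol(table)) {
    warning("min_count exceeds the number of measures: no hubs possible")
  }
  top_lists <- lapply(table, function(col) {
    top_fraction(stats::setNames(col, rownames(table)), fraction)
  })
  occurrence <- table(unlist(top_lists, use.names = FALSE))
  occ <- stats::setNames(rep(0L, nrow(table)), rownames(table))
  occ[names(occurrence)] <- as.integer(occurrence)
  list(top_lists = top_lists,
       occurrence = occ,
       hubs = sort(names(occ)[occ >= min_count]))
}
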