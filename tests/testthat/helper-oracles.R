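# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph where feasible): distances and path counts by
# exhaustive simple-path enumeration, cliques by bitmask, BH by the
# double-loop definition, AUC by pair counting.

## ---- BH double loop -------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, min(1, ps[j] * m / j))
    adj[i] <- best
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

## ---- AUC pair counting ----------------------------------------------
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## ---- TOM triple loop ------------------------------------------------
oracle_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj; diag(a) <- 0
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  out
}

## ---- GSEA walk recomputation ----------------------------------------
oracle_es <- function(ranked, set, p = 1) {
  hit <- names(ranked) %in% set
  n <- length(ranked); nh <- sum(hit)
  nr <- sum(abs(ranked[hit])^p)
  walk <- numeric(n); run <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(ranked[i])^p / nr else -1 / (n - nh)
    walk[i] <- run
  }
  walk[which.max(abs(walk))]
}

## ---- graph primitives on adjacency matrices -------------------------
# all simple paths s -> t; returns list of integer vectors (incl. endpoints)
.all_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (u in which(A[v, ] > 0)) if (!(u %in% path)) rec(c(path, u))
  }
  rec(s)
  out
}

# distance, shortest-path count, and per-vertex through-count for one pair
.pair_stats <- function(A, s, t) {
  paths <- .all_paths(A, s, t)
  if (!length(paths)) return(list(d = Inf, sigma = 0, through = numeric(nrow(A))))
  lens <- lengths(paths) - 1L
  d <- min(lens)
  sp <- paths[lens == d]
  through <- numeric(nrow(A))
  for (p_ in sp) {
    interior <- setdiff(p_, c(s, t))
    through[interior] <- through[interior] + 1
  }
  list(d = d, sigma = length(sp), through = through)
}

oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  SIG <- matrix(0, n, n); diag(SIG) <- 1
  THR <- array(0, c(n, n, n))           # through[v] for pair (s,t)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- .pair_stats(A, s, t)
    D[s, t] <- ps$d; SIG[s, t] <- ps$sigma; THR[s, t, ] <- ps$through
  }
  comp_of <- integer(n); cid <- 0L
  for (v in seq_len(n)) if (comp_of[v] == 0L) {
    cid <- cid + 1L
    comp_of[is.finite(D[v, ])] <- cid
  }

  deg <- rowSums(A)
  btw <- str_ <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || SIG[s, t] == 0) next
      btw[v] <- btw[v] + THR[s, t, v] / SIG[s, t]
      str_[v] <- str_[v] + THR[s, t, v]
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]; sum(1 / d[is.finite(d)])
  }, numeric(1))
  ecc <- vapply(seq_len(n), function(v) {
    d <- D[v, ]; d <- d[is.finite(d) & d > 0]
    if (!length(d)) 0 else 1 / max(d)
  }, numeric(1))
  rad <- vapply(seq_len(n), function(v) {
    idx <- which(comp_of == comp_of[v])
    if (length(idx) < 2L) return(0)
    delta <- max(D[idx, idx][is.finite(D[idx, idx])])
    sum(delta + 1 - D[v, setdiff(idx, v)]) / (length(idx) - 1)
  }, numeric(1))
  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2L) return(0)
    e <- 0
    for (i in seq_along(nb)) for (j in seq_len(i - 1)) {
      e <- e + A[nb[i], nb[j]]
    }
    2 * e / (length(nb) * (length(nb) - 1))
  }, numeric(1))

  # components of an induced subgraph, by reachability closure
  sub_components <- function(idx) {
    if (!length(idx)) return(list())
    B <- A[idx, idx, drop = FALSE]
    left <- seq_along(idx); comps <- list()
    while (length(left)) {
      grp <- left[1L]
      repeat {
        nxt <- unique(c(grp, which(rowSums(B[, grp, drop = FALSE]) > 0)))
        if (length(nxt) == length(grp)) break
        grp <- nxt
      }
      comps[[length(comps) + 1L]] <- idx[grp]
      left <- setdiff(left, grp)
    }
    comps
  }
  mnc <- dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    comps <- sub_components(nb)
    if (!length(comps)) next
    sz <- lengths(comps)
    cand <- which(sz == max(sz))
    edges_in <- vapply(cand, function(ci) {
      m <- comps[[ci]]; sum(A[m, m]) / 2
    }, numeric(1))
    best <- cand[which.max(edges_in)]
    mnc[v] <- sz[best]
    if (sz[best] > 1L) dmnc[v] <- edges_in[which.max(edges_in)] / sz[best]^1.7
  }

  # maximal cliques by bitmask
  mcc <- numeric(n)
  subsets <- seq_len(2^n - 1)
  members <- lapply(subsets, function(b) which(bitwAnd(b, 2^(seq_len(n) - 1)) > 0))
  is_clique <- vapply(members, function(m) {
    if (length(m) == 1L) return(TRUE)
    all(A[m, m][upper.tri(diag(length(m)))] > 0)
  }, logical(1))
  for (i in subsets) {
    if (!is_clique[i]) next
    m <- members[[i]]
    maximal <- TRUE
    for (v in setdiff(seq_len(n), m)) {
      if (all(A[v, m] > 0)) { maximal <- FALSE; break }
    }
    if (maximal) mcc[m] <- mcc[m] + factorial(length(m) - 1L)
  }

  # BottleNeck with the smallest-id parent rule
  bn <- numeric(n)
  for (s in seq_len(n)) {
    idx <- which(comp_of == comp_of[s])
    if (length(idx) < 2L) next
    parent <- rep(NA_integer_, n)
    for (v in idx) {
      if (v == s) next
      cand <- which(A[v, ] > 0 & D[s, ] == D[s, v] - 1)
      parent[v] <- min(cand)
    }
    size <- rep(0, n); size[idx] <- 1
    for (v in idx[order(D[s, idx], decreasing = TRUE)]) {
      if (v == s) next
      size[parent[v]] <- size[parent[v]] + size[v]
    }
    for (v in setdiff(idx, s)) {
      if (size[v] > length(idx) / 4) bn[v] <- bn[v] + 1
    }
  }

  epc1 <- vapply(seq_len(n), function(v) sum(comp_of == comp_of[v]) - 1,
                 numeric(1))

  data.frame(Degree = deg, Betweenness = btw, Closeness = clo,
             Eccentricity = ecc, Radiality = rad, Stress = str_,
             ClusteringCoefficient = cc, MNC = mnc, DMNC = dmnc, MCC = mcc,
             BottleNeck = bn, EPC1 = epc1)
}

## ---- enumeration of non-isomorphic graphs on <= 6 nodes -------------
# graphs encoded as bitmasks over the upper-triangle edge positions;
# canonical code = min over all vertex permutations of the re-encoded mask
nonisomorphic_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  npairs <- nrow(pairs)
  pair_index <- matrix(0L, n, n)
  for (e in seq_len(npairs)) {
    pair_index[pairs[e, 1], pairs[e, 2]] <- e
    pair_index[pairs[e, 2], pairs[e, 1]] <- e
  }
  perms <- .permutations(n)
  codes <- 0:(2^npairs - 1)
  canon <- rep(.Machine$integer.max, length(codes))
  bits <- lapply(seq_len(npairs), function(e) bitwAnd(codes %/% 2^(e - 1), 1L))
  for (p_ in perms) {
    newcode <- integer(length(codes))
    for (e in seq_len(npairs)) {
      tgt <- pair_index[p_[pairs[e, 1]], p_[pairs[e, 2]]]
      newcode <- newcode + bits[[e]] * 2^(tgt - 1)
    }
    canon <- pmin(canon, newcode)
  }
  reps <- sort(unique(canon))
  lapply(reps, function(code) {
    A <- matrix(0, n, n)
    for (e in seq_len(npairs)) {
      if (bitwAnd(code %/% 2^(e - 1), 1L) == 1L) {
        A[pairs[e, 1], pairs[e, 2]] <- 1
        A[pairs[e, 2], pairs[e, 1]] <- 1
      }
    }
    A
  })
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p_ in .permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p_, n, after = pos - 1L)
    }
  }
  out
}

## ---- misc fixtures ---------------------------------------------------
graph_from_adj <- function(A, names_ = NULL) {
  if (is.null(names_)) names_ <- sprintf("v%02d", seq_len(nrow(A)))
  dimnames(A) <- list(names_, names_)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# noise-free two-block expression matrix (for module detection fixtures)
block_matrix <- function(block_sizes, n_samples, seed = 1, noise = 0) {
  set.seed(seed)
  factors <- matrix(stats::rnorm(length(block_sizes) * n_samples),
                    length(block_sizes), n_samples)
  rows <- do.call(rbind, lapply(seq_along(block_sizes), function(b) {
    loading <- seq(0.5, 1.5, length.out = block_sizes[b])
    outer(loading, factors[b, ])
  }))
  rows <- rows + matrix(stats::rnorm(length(rows), sd = noise), nrow(rows))
  dimnames(rows) <- list(sprintf("G%03d", seq_len(nrow(rows))),
                         sprintf("S%02d", seq_len(n_samples)))
  rows
}

phen_for <- function(mat, n_case) {
  data.frame(sample_id = colnames(mat),
             group = c(rep("AS", n_case), rep("HC", ncol(mat) - n_case)),
             stringsAsFactors = FALSE)
}
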