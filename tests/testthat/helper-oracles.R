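# Independent brute-force oracles and toy-network builders used across the
# test files. These deliberately avoid the package's own computational paths
# (igraph, the C++ census, fisher.test/wilcox.test).

toy_network <- function(edge_rows, mh = character(), name = "toy") {
  edges <- do.call(rbind, lapply(edge_rows, function(r) {
    data.frame(source = r[[1]], target = r[[2]], type = r[[3]],
               directed = if (length(r) >= 4) r[[4]] else TRUE)
  }))
  ids <- unique(c(edges$source, edges$target, mh))
  nodes <- data.frame(gene_id = ids, is_mh = ids %in% mh)
  interaction_network(edges, nodes, name = name, quiet = TRUE)
}

random_toy_network <- function(n, p_edge, seed, p_neg = 0.3,
                               p_binding = 0, mh_frac = 0.2) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  u <- runif(nrow(pairs))
  type <- ifelse(u < p_binding, "binding",
                 ifelse(runif(nrow(pairs)) < p_neg, "inhibition",
                        "activation"))
  edges <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      type = type, directed = type != "binding")
  nodes <- data.frame(gene_id = ids,
                      is_mh = runif(n) < mh_frac)
  interaction_network(edges, nodes, name = "random-toy", quiet = TRUE)
}

# undirected presence matrix of a network's simple projection
undirected_adjacency <- function(net) {
  ids <- net$nodes$gene_id
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$source[i]; b <- net$edges$target[i]
    if (a != b) { m[a, b] <- TRUE; m[b, a] <- TRUE }
  }
  m
}

# all-pairs shortest paths by Floyd-Warshall on the undirected projection
oracle_floyd_warshall <- function(net) {
  adj <- undirected_adjacency(net)
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# giant component size by union-find
oracle_gcs_union_find <- function(net) {
  ids <- net$nodes$gene_id
  if (length(ids) == 0L) return(0L)
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(net$edges))) {
    a <- find(match(net$edges$source[r], ids))
    b <- find(match(net$edges$target[r], ids))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(ids), find, 1L)
  max(table(roots))
}

# Watts-Strogatz local clustering by explicit triangle counting
oracle_local_clustering <- function(net) {
  adj <- undirected_adjacency(net)
  ids <- rownames(adj)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (v in ids) {
    nb <- ids[adj[v, ]]
    k <- length(nb)
    if (k < 2) { out[v] <- 0; next }
    links <- 0L
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (adj[nb[i], nb[j]]) links <- links + 1L
      }
    }
    out[v] <- 2 * links / (k * (k - 1))
  }
  out
}

# symmetric Hausdorff distance over all point pairs
oracle_hausdorff <- function(a, b) {
  dmat <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                              nrow(a) + seq_len(nrow(b)),
                                              drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

# exact one-sided ("x less") Wilcoxon p by enumeration of rank assignments
oracle_wilcoxon_less <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(m)])
  idx <- utils::combn(m + length(y), m)
  null <- apply(idx, 2, function(s) sum(r[s]))
  mean(null <= obs)
}

# exact one-sided ("greater") Fisher p by enumeration over fixed margins
oracle_fisher_greater <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  lp <- vapply(lo:hi, function(aa) {
    lchoose(r1, aa) + lchoose(r2, c1 - aa) - lchoose(r1 + r2, c1)
  }, numeric(1))
  sum(exp(lp[(lo:hi) >= a]))
}

# weak connectivity of a node subset under a signed code matrix
subset_connected <- function(code, nodes) {
  k <- length(nodes)
  und <- (code[nodes, nodes] != 0) | t(code[nodes, nodes] != 0)
  reach <- logical(k); reach[1] <- TRUE
  repeat {
    new <- reach | apply(und[, reach, drop = FALSE], 1, any)
    if (all(new == reach)) break
    reach <- new
  }
  all(reach)
}

# brute-force census: enumerate all k-subsets, keep weakly connected ones,
# label each induced signed subgraph with the package's canonical_label
# (labeling itself is verified separately against permutation isomorphism)
oracle_census_counts <- function(net, k) {
  ids <- net$nodes$gene_id
  n <- length(ids)
  code <- matrix(0L, n, n, dimnames = list(ids, ids))
  e <- net$edges[net$edges$sign != 0 & net$edges$source != net$edges$target, ]
  for (i in seq_len(nrow(e))) {
    bit <- if (e$sign[i] > 0) 1L else 2L
    code[e$source[i], e$target[i]] <- bitwOr(code[e$source[i], e$target[i]],
                                             bit)
  }
  labels <- character(0)
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    if (!subset_connected(code, sub)) next
    adj <- matrix(0, k, k)
    cc <- code[sub, sub]
    adj[cc == 1] <- 1
    adj[cc == 2] <- -1
    adj[cc == 3] <- NA
    labels <- c(labels, canonical_label(adj))
  }
  if (length(labels) == 0L) return(integer(0))
  tab <- table(labels)
  stats::setNames(as.integer(tab), names(tab))
}

# are two signed adjacencies isomorphic? brute force over permutations
oracle_sign_isomorphic <- function(a, b) {
  k <- nrow(a)
  if (nrow(b) != k) return(FALSE)
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
    }
    out
  }
  for (p in perms(seq_len(k))) {
    if (identical(a[p, p], b)) return(TRUE)
  }
  FALSE
}
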