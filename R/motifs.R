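# Signed network motifs: census of connected 3- and 4-node induced
# subgraphs of the regulatory network, significance against sign-stratified
# degree-preserving randomizations, Boolean bistability and feedback-circuit
# classification, motif conservation, and motif-cluster statistics.
#
# Canonical class labels are "k:" followed by the lexicographically minimal
# row-major encoding of the signed adjacency over all k! node relabelings,
# with per-pair codes 0 = no edge, 1 = positive, 2 = negative, 3 = both
# signs present (sign-ambiguous).

# deduplicated signed directed edges for motif work; self-loops dropped
motif_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  e <- net$edges
  if (any(e$sign == 0L)) {
    stop("motif analysis requires a regulatory network (all edges signed); ",
         "apply to_regulatory() first")
  }
  e <- e[e$source != e$target, , drop = FALSE]
  e[!duplicated(paste(e$source, e$target, e$sign)), , drop = FALSE]
}

#' Canonical label of a signed motif adjacency
#'
#' Two signed digraphs receive the same label iff they are sign-isomorphic;
#' the label is minimal over all node relabelings (brute force, k <= 4).
#'
#' @param adjacency k x k matrix; entry (i, j) is the sign of edge i -> j
#'   (+1, -1, 0 = absent, NA = both signs present).
#' @return Label string `"k:<codes>"`.
#' @export
#' @examples
#' toggle <- matrix(c(0, -1, -1, 0), 2, 2)
#' canonical_label(toggle)
canonical_label <- function(adjacency) {
  m <- as.matrix(adjacency)
  if (nrow(m) != ncol(m)) stop("adjacency must be square")
  code <- matrix(0L, nrow(m), ncol(m))
  code[!is.na(m) & m == 1] <- 1L
  code[!is.na(m) & m == -1] <- 2L
  code[is.na(m)] <- 3L
  canonical_label_cpp(code)
}

#' Decode a canonical label into a signed adjacency
#'
#' @param label A label produced by [canonical_label()] or the census.
#' @return k x k matrix with entries +1, -1, 0, or NA (sign-ambiguous pair).
#' @export
label_to_adjacency <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  codes <- as.integer(strsplit(parts[2], "")[[1]])
  vals <- c(0, 1, -1, NA)[codes + 1L]
  matrix(vals, k, k, byrow = TRUE)  # codes are row-major
}

#' Number of directed interactions encoded in a motif label
#' @param label Canonical label string.
#' @return Integer edge count (a sign-ambiguous pair counts as two edges).
#' @export
motif_n_edges <- function(label) {
  codes <- as.integer(strsplit(strsplit(label, ":", fixed = TRUE)[[1]][2],
                               "")[[1]])
  sum((codes == 1L) + (codes == 2L) + 2L * (codes == 3L))
}

#' Motif size encoded in a label
#' @param label Canonical label string.
#' @return Integer k.
#' @export
motif_size <- function(label) {
  as.integer(strsplit(label, ":", fixed = TRUE)[[1]][1])
}

#' Enumerate connected induced k-node subgraphs
#'
#' ESU census of the regulatory network: every weakly connected induced
#' k-node subgraph is enumerated exactly once and assigned its canonical
#' signed class label. Self-loops are ignored.
#'
#' @param net A regulatory `interaction_network` (all edges signed).
#' @param k Subgraph size, 3 or 4.
#' @return Data frame with columns `class_label` and `nodes` (list column of
#'   gene-id vectors), one row per instance.
#' @export
enumerate_connected_subgraphs <- function(net, k) {
  if (!k %in% c(3L, 4L)) stop("subgraph size k must be 3 or 4")
  e <- motif_edges(net)
  ids <- net$nodes$gene_id
  res <- esu_census_cpp(length(ids), match(e$source, ids),
                        match(e$target, ids), e$sign, as.integer(k),
                        collect = TRUE)
  nodes <- apply(res$nodes, 1L, function(ix) ids[ix], simplify = FALSE)
  out <- data.frame(class_label = as.character(res$labels))
  out$nodes <- nodes
  out
}

#' Motif class counts of a network
#'
#' @param net A regulatory `interaction_network`.
#' @param k Subgraph size, 3 or 4.
#' @return Named integer vector: instance count per canonical class label.
#' @export
motif_counts <- function(net, k) {
  if (!k %in% c(3L, 4L)) stop("subgraph size k must be 3 or 4")
  e <- motif_edges(net)
  ids <- net$nodes$gene_id
  res <- esu_census_cpp(length(ids), match(e$source, ids),
                        match(e$target, ids), e$sign, as.integer(k),
                        collect = FALSE)
  res$counts
}

#' Degree-preserving randomization of a signed network
#'
#' Edge-swap randomization performed separately within each sign class, so
#' every node's in- and out-degree per sign is preserved exactly; swaps that
#' would create self-loops or duplicate same-sign edges are rejected.
#'
#' @param net A regulatory `interaction_network`.
#' @param exchanges_per_edge Swap trials per edge (default 3).
#' @param attempts Retries per trial before skipping (default 3).
#' @param seed Optional integer seed.
#' @return A randomized `interaction_network`.
#' @export
degree_preserving_randomize <- function(net, exchanges_per_edge = 3,
                                        attempts = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- motif_edges(net)
  ids <- net$nodes$gene_id
  res <- rewire_signed_cpp(length(ids), match(e$source, ids),
                           match(e$target, ids), e$sign,
                           exchanges_per_edge, as.integer(attempts))
  edges <- data.frame(source = ids[res$from], target = ids[res$to],
                      type = e$type, directed = TRUE)
  interaction_network(edges, net$nodes, name = paste0(net$name, " (random)"),
                      quiet = TRUE)
}

#' Motif significance against the randomized null
#'
#' Compares observed class counts to `n_random` sign-stratified
#' degree-preserving randomizations. Classes with more nodes than directed
#' interactions are removed (simplistic motifs). A class is significant when
#' z >= `z_min` and empirical p <= `p_max` (defaults 2 and 0.05).
#'
#' @param net A regulatory `interaction_network`.
#' @param k Subgraph size, 3 or 4.
#' @param n_random Number of randomized networks (default 1000).
#' @param exchanges_per_edge,attempts Randomizer parameters.
#' @param z_min,p_max Significance cutoffs.
#' @param seed Optional integer seed.
#' @return Data frame per observed class: `class_label`, `k`, `n_edges`,
#'   `count_observed`, `null_mean`, `null_sd`, `z` (NA when sd = 0),
#'   `p_empirical` (fraction of null counts >= observed), `significant`.
#' @export
motif_significance <- function(net, k, n_random = 1000,
                               exchanges_per_edge = 3, attempts = 3,
                               z_min = 2, p_max = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- motif_counts(net, k)
  obs <- obs[vapply(names(obs), motif_n_edges, 1L) >= k]
  if (length(obs) == 0L) {
    return(data.frame(class_label = character(), k = integer(),
                      n_edges = integer(), count_observed = integer(),
                      null_mean = numeric(), null_sd = numeric(),
                      z = numeric(), p_empirical = numeric(),
                      significant = logical()))
  }
  e <- motif_edges(net)
  ids <- net$nodes$gene_id
  from <- match(e$source, ids); to <- match(e$target, ids)
  s <- numeric(length(obs)); s2 <- numeric(length(obs))
  tail_ge <- integer(length(obs))
  for (r in seq_len(n_random)) {
    rw <- rewire_signed_cpp(length(ids), from, to, e$sign,
                            exchanges_per_edge, as.integer(attempts))
    cnt <- esu_census_cpp(length(ids), rw$from, rw$to, rw$sign,
                          as.integer(k), collect = FALSE)$counts
    null_c <- ifelse(names(obs) %in% names(cnt),
                     cnt[names(obs)], 0L)
    null_c[is.na(null_c)] <- 0L
    s <- s + null_c
    s2 <- s2 + null_c^2
    tail_ge <- tail_ge + (null_c >= obs)
  }
  null_mean <- s / n_random
  null_var <- pmax(0, (s2 - n_random * null_mean^2) / (n_random - 1))
  null_sd <- sqrt(null_var)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, NA_real_)
  p_emp <- tail_ge / n_random
  out <- data.frame(class_label = names(obs), k = as.integer(k),
                    n_edges = vapply(names(obs), motif_n_edges, 1L),
                    count_observed = as.integer(obs),
                    null_mean = null_mean, null_sd = null_sd, z = z,
                    p_empirical = p_emp,
                    significant = !is.na(z) & z >= z_min & p_emp <= p_max)
  rownames(out) <- NULL
  out[order(-out$z, out$p_empirical, method = "radix",
            na.last = TRUE), , drop = FALSE]
}

# synchronous Boolean update of one state vector under the logic rule:
# a node is ON next iff (it has no activators, or some activator is ON)
# and no inhibitor is ON; nodes without any input are clamped OFF.
boolean_update <- function(adjacency, state) {
  k <- nrow(adjacency)
  nxt <- integer(k)
  for (j in seq_len(k)) {
    ins <- which(adjacency[, j] != 0)
    if (length(ins) == 0L) { nxt[j] <- 0L; next }
    act <- ins[adjacency[ins, j] > 0]
    inh <- ins[adjacency[ins, j] < 0]
    on <- (length(act) == 0L || any(state[act] == 1L)) &&
      !any(state[inh] == 1L)
    nxt[j] <- as.integer(on)
  }
  nxt
}

#' Boolean fixed points of a signed motif
#'
#' States invariant under the synchronous Boolean logic update: a node turns
#' ON iff (it has no activators or at least one activator is ON) and no
#' inhibitor is ON; input-free nodes are clamped OFF. The update is a pure
#' Boolean function of the state, so its interaction graph matches the motif
#' signs and the positive-circuit (Thomas) condition for multistationarity
#' applies.
#'
#' @param motif Signed adjacency matrix (entries +1/-1/0) or a canonical
#'   label string.
#' @return Integer matrix, one row per fixed point (columns = nodes).
#' @export
#' @examples
#' toggle <- matrix(c(0, -1, -1, 0), 2, 2)
#' boolean_fixed_points(toggle)  # rows 10 and 01
boolean_fixed_points <- function(motif) {
  adj <- if (is.character(motif)) label_to_adjacency(motif) else
    as.matrix(motif)
  if (anyNA(adj)) stop("motif has a sign-ambiguous pair; dynamics undefined")
  k <- nrow(adj)
  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(states) <- NULL
  fixed <- apply(states, 1L, function(s) {
    all(boolean_update(adj, as.integer(s)) == s)
  })
  states[fixed, , drop = FALSE]
}

#' Is a signed motif bistable?
#'
#' TRUE iff the motif admits at least two Boolean fixed points. Returns NA
#' for motifs containing a sign-ambiguous pair (both a positive and a
#' negative edge between the same ordered node pair).
#'
#' @param motif Signed adjacency matrix or canonical label string.
#' @return Logical (or NA).
#' @export
is_bistable <- function(motif) {
  adj <- if (is.character(motif)) label_to_adjacency(motif) else
    as.matrix(motif)
  if (anyNA(adj)) return(NA)
  nrow(boolean_fixed_points(adj)) >= 2L
}

#' Elementary feedback circuits of a signed motif
#'
#' All elementary directed cycles (length >= 2; self-loops excluded from
#' motif machinery) with the sign of each cycle as the product of its edge
#' signs.
#'
#' @param motif Signed adjacency matrix or canonical label string.
#' @return List of lists with elements `nodes` (integer cycle, minimal node
#'   first) and `sign` (+1 or -1; NA if an edge is sign-ambiguous).
#' @export
feedback_circuits <- function(motif) {
  adj <- if (is.character(motif)) label_to_adjacency(motif) else
    as.matrix(motif)
  k <- nrow(adj)
  circuits <- list()
  for (len in 2:max(2, k)) {
    if (len > k) break
    for (start in seq_len(k)) {
      rest <- setdiff(seq_len(k), seq_len(start))  # only nodes > start
      if (length(rest) < len - 1L) next
      combos <- combn(rest, len - 1L, simplify = FALSE)
      for (cmb in combos) {
        perms <- permutations_of(cmb)
        for (p in perms) {
          cyc <- c(start, p)
          edges_ok <- TRUE
          sgn <- 1
          for (i in seq_len(len)) {
            a <- cyc[i]; b <- cyc[if (i == len) 1L else i + 1L]
            v <- adj[a, b]
            if (!is.na(v) && v == 0) { edges_ok <- FALSE; break }
            sgn <- if (is.na(v) || is.na(sgn)) NA_real_ else sgn * v
          }
          if (edges_ok) {
            circuits[[length(circuits) + 1L]] <-
              list(nodes = cyc, sign = sgn)
          }
        }
      }
    }
  }
  circuits
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Does a signed motif contain a positive feedback circuit?
#'
#' @param motif Signed adjacency matrix or canonical label string.
#' @return Logical.
#' @export
has_positive_circuit <- function(motif) {
  circ <- feedback_circuits(motif)
  any(vapply(circ, function(cc) !is.na(cc$sign) && cc$sign > 0, logical(1)))
}

#' Is a motif instance evolutionarily conserved?
#'
#' A motif instance is conserved iff all its interactions are conserved in a
#' common set of at least `k_min` species, i.e. the intersection of the
#' per-edge species presence sets has size >= `k_min`.
#'
#' @param species_sets List of character vectors: the species presence set
#'   of each interaction of the instance.
#' @param k_min Minimum common species count (default 7).
#' @return Logical.
#' @export
#' @examples
#' motif_instance_conserved(list(as.character(1:7), as.character(1:7)))
#' motif_instance_conserved(list(as.character(1:7), as.character(3:9)))
motif_instance_conserved <- function(species_sets, k_min = 7L) {
  if (length(species_sets) == 0L) return(FALSE)
  common <- Reduce(intersect, species_sets)
  length(common) >= k_min
}

#' Annotate motif instances with MH, conservation and bistability flags
#'
#' For each instance: `is_mh` iff it encompasses at least one MH gene;
#' `n_species_common` is the size of the intersection of species presence
#' sets over all its interactions (taken from the network's conserved edge
#' annotation or from `edge_labels`); `conserved` iff that intersection has
#' at least `k_min` species; `bistable` is the Boolean bistability of the
#' instance's class.
#'
#' @param instances Data frame from [enumerate_connected_subgraphs()].
#' @param net The regulatory `interaction_network` the census ran on.
#' @param edge_labels Optional edge-level `conservation_labels` (otherwise
#'   the `species` list column of `net$edges`, as set by
#'   [conserved_subnetwork()], is used).
#' @param k_min Minimum common species count (default 7).
#' @return The `instances` data frame with columns `is_mh`,
#'   `n_species_common`, `conserved`, `bistable` added.
#' @export
annotate_motif_instances <- function(instances, net, edge_labels = NULL,
                                     k_min = 7L) {
  stopifnot(inherits(net, "interaction_network"))
  if (!is.null(edge_labels)) {
    keys <- edge_labels$entity
    sets <- edge_labels$species
  } else if (!is.null(net$edges$species)) {
    keys <- pair_key(net$edges$source, net$edges$target)
    sets <- net$edges$species
  } else {
    stop("no species presence sets: pass edge_labels or use a ",
         "conserved_subnetwork()")
  }
  sets <- sets[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  set_of <- setNames(sets, keys)
  e <- motif_edges(net)
  epairs <- unique(pair_key(e$source, e$target))
  mh <- setNames(net$nodes$is_mh, net$nodes$gene_id)
  n_common <- integer(nrow(instances))
  is_mh <- logical(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    genes <- instances$nodes[[i]]
    is_mh[i] <- any(mh[genes])
    prs <- combn(sort(genes), 2L)
    pks <- pair_key(prs[1, ], prs[2, ])
    pks <- pks[pks %in% epairs]
    ssets <- lapply(pks, function(p) {
      if (p %in% names(set_of)) set_of[[p]] else character()
    })
    common <- Reduce(intersect, ssets)
    n_common[i] <- length(common)
  }
  instances$is_mh <- is_mh
  instances$n_species_common <- n_common
  instances$conserved <- n_common >= k_min
  bist_by_class <- vapply(unique(instances$class_label), is_bistable,
                          logical(1))
  instances$bistable <- unname(bist_by_class[instances$class_label])
  instances
}

#' Enrichment of MH genes within motif instances
#'
#' 2x2 one-sided Fisher exact test of MH status against participation in
#' the given motif instances, over a gene universe (typically the genes of
#' the conserved regulatory network).
#'
#' @param instances Motif instance data frame (usually filtered to the
#'   conserved bistable instances).
#' @param net `interaction_network` supplying MH flags.
#' @param universe Gene universe (default: all genes of `net`).
#' @return An `enrichment_result`.
#' @export
motif_gene_enrichment <- function(instances, net, universe = NULL) {
  if (is.null(universe)) universe <- net$nodes$gene_id
  in_motif <- unique(unlist(instances$nodes))
  in_motif <- intersect(in_motif, universe)
  mh <- setNames(net$nodes$is_mh, net$nodes$gene_id)[universe]
  inm <- universe %in% in_motif
  fisher_exact_one_sided(sum(mh & inm), sum(mh & !inm),
                         sum(!mh & inm), sum(!mh & !inm))
}

#' Induced subnetwork on a gene set
#' @param net An `interaction_network`.
#' @param genes Gene ids to keep.
#' @return An `interaction_network` with only those nodes and the edges
#'   among them.
#' @export
induced_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "interaction_network"))
  keep_e <- net$edges$source %in% genes & net$edges$target %in% genes
  nodes <- net$nodes[net$nodes$gene_id %in% genes, , drop = FALSE]
  edges <- net$edges[keep_e, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 name = paste0(net$name, " (induced)")),
            class = "interaction_network")
}

#' Motif cluster analysis
#'
#' Takes the union of the genes of the given motif instances as the motif
#' cluster, extracts the induced subnetwork, and compares the local
#' clustering coefficients of cluster genes to those of all other network
#' genes with a one-sided Wilcoxon rank-sum test (alternative "greater").
#'
#' @param instances Motif instance data frame.
#' @param net The `interaction_network` the instances live in.
#' @return List with `subnetwork`, `p_value`, `cluster_genes`.
#' @export
motif_cluster_analysis <- function(instances, net) {
  cluster_genes <- unique(unlist(instances$nodes))
  if (length(cluster_genes) < 2L) {
    stop("motif cluster has fewer than two genes; test undefined")
  }
  others <- setdiff(net$nodes$gene_id, cluster_genes)
  if (length(others) < 2L) {
    stop("fewer than two genes outside the motif cluster; test undefined")
  }
  cc <- local_clustering(net)
  p <- suppressWarnings(wilcox.test(cc[cluster_genes], cc[others],
                                    alternative = "greater"))$p.value
  list(subnetwork = induced_subnetwork(net, cluster_genes),
       p_value = p, cluster_genes = cluster_genes)
}

#' Enumerate canonical classes of connected signed digraphs
#'
#' Exhaustive enumeration over all sign assignments on the ordered node
#' pairs of `k` nodes (k <= 3; 3^(k(k-1)) graphs), keeping weakly connected
#' ones, partitioned into canonical classes. Used to verify labeling and
#' the positive-circuit property of bistability exhaustively.
#'
#' @param k Number of nodes (2 or 3).
#' @return Character vector of distinct canonical class labels.
#' @export
enumerate_signed_classes <- function(k) {
  if (!k %in% c(2L, 3L)) stop("exhaustive enumeration supports k in {2, 3}")
  pairs <- which(diag(k) == 0, arr.ind = TRUE)
  n_pairs <- nrow(pairs)
  assign_grid <- expand.grid(rep(list(c(0, 1, -1)), n_pairs))
  labels <- character(0)
  for (r in seq_len(nrow(assign_grid))) {
    adj <- matrix(0, k, k)
    adj[pairs] <- as.numeric(assign_grid[r, ])
    # weak connectivity
    und <- (adj != 0) | t(adj != 0)
    reach <- logical(k); reach[1] <- TRUE
    repeat {
      new <- reach | apply(und[, reach, drop = FALSE], 1L, any)
      if (all(new == reach)) break
      reach <- new
    }
    if (!all(reach)) next
    labels <- c(labels, canonical_label(adj))
  }
  unique(labels)
}
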