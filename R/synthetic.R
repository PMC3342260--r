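# Synthetic data with the statistical structure the analysis assumes:
# a random signed/typed interaction network with flagged MH genes, an
# orthology table with an MH vs non-MH conservation-rate difference,
# per-species interaction catalogs with an analogous edge-retention
# difference, network-proximity-coupled phenoprints, and planted bistable
# motifs with a guaranteed common conserved species set. Every generator is
# deterministic under the spec seed and emits exactly the file formats the
# other modules consume, so the whole pipeline runs without downloads.

#' Default nine-species metazoan panel
#' @return Character vector of species identifiers.
#' @export
default_species_panel <- function() {
  c("C.elegans", "D.melanogaster", "D.rerio", "G.gallus", "P.troglodytes",
    "M.musculus", "R.norvegicus", "C.familiaris", "B.taurus")
}

#' Default planted bistable motif: a toggle-switch triad
#'
#' Mutual inhibition between two nodes plus an activation onto a third
#' (A -| B, B -| A, A -> C): Boolean-bistable and carrying a positive
#' 2-circuit.
#'
#' @return 3 x 3 signed adjacency matrix.
#' @export
toggle_triad <- function() {
  matrix(c(0, -1, 1,
           -1, 0, 0,
           0, 0, 0), 3, 3, byrow = TRUE)
}

#' Synthetic study specification
#'
#' Bundles all generator parameters: network size and density, MH gene
#' count, sign balance and the fraction of unsigned binding edges, the
#' species panel, per-species gene and edge conservation rates for MH vs
#' other entities, the phenotype-coupling parameters (community radius,
#' trajectory length, noise), and the planted-motif settings.
#'
#' @param n_genes Number of genes.
#' @param n_mh Number of MH genes (must not exceed `n_genes`).
#' @param edge_density Overall edge density: the expected number of edges is
#'   `edge_density * n_genes * (n_genes - 1)`.
#' @param sign_balance Fraction of signed edges that are positive.
#' @param p_binding Fraction of edges that are unsigned binding edges.
#' @param n_communities Number of network communities. With the default
#'   (> 1) the network is a community graph whose inter-community bridges
#'   preferentially run through MH genes, so MH interactions are
#'   load-bearing for global connectivity; `n_communities = 1` gives a
#'   homogeneous directed G(n, p) graph.
#' @param bridge_mh_frac Probability that a bridge edge is anchored at an
#'   MH gene.
#' @param species Species panel (character vector).
#' @param p_gene_mh,p_gene_other Per-species homolog presence probability
#'   for MH / other genes.
#' @param q_edge_mh,q_edge_other Per-species interaction retention
#'   probability for MH / other interactions.
#' @param d0 Network radius of the phenoprint communities.
#' @param n_time Time points per phenoprint trajectory.
#' @param noise_sd Gaussian noise sd added to trajectory archetypes.
#' @param motif_adjacency Signed adjacency of the planted motif class.
#' @param motif_copies Number of disjoint planted instances.
#' @param motif_on_mh Plant on MH genes preferentially.
#' @param conserve_planted Force planted motif edges to share a common
#'   7-species presence set.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_genes = 500L, n_mh = 30L, edge_density = 0.006,
                           sign_balance = 0.7, p_binding = 0.3,
                           n_communities = 25L, bridge_mh_frac = 0.9,
                           species = default_species_panel(),
                           p_gene_mh = 0.90, p_gene_other = 0.60,
                           q_edge_mh = 0.80, q_edge_other = 0.70,
                           d0 = 2L, n_time = 8L, noise_sd = 0.03,
                           motif_adjacency = toggle_triad(),
                           motif_copies = 15L, motif_on_mh = TRUE,
                           conserve_planted = TRUE, seed = 1L) {
  probs <- c(edge_density, sign_balance, p_binding, bridge_mh_frac,
             p_gene_mh, p_gene_other, q_edge_mh, q_edge_other)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_mh > n_genes) stop("n_mh cannot exceed n_genes")
  if (d0 < 1L) stop("community radius d0 must be >= 1")
  if (n_communities < 1L || n_communities > n_genes) {
    stop("n_communities must be between 1 and n_genes")
  }
  structure(list(n_genes = as.integer(n_genes), n_mh = as.integer(n_mh),
                 edge_density = edge_density, sign_balance = sign_balance,
                 p_binding = p_binding,
                 n_communities = as.integer(n_communities),
                 bridge_mh_frac = bridge_mh_frac, species = species,
                 p_gene_mh = p_gene_mh, p_gene_other = p_gene_other,
                 q_edge_mh = q_edge_mh, q_edge_other = q_edge_other,
                 d0 = as.integer(d0), n_time = as.integer(n_time),
                 noise_sd = noise_sd, motif_adjacency = motif_adjacency,
                 motif_copies = as.integer(motif_copies),
                 motif_on_mh = isTRUE(motif_on_mh),
                 conserve_planted = isTRUE(conserve_planted),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

syn_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a random signed interaction network
#'
#' With `n_communities = 1`: a directed G(n, p) graph without self-loops at
#' `p = edge_density`. With the default `n_communities > 1`: genes are
#' assigned round-robin to equally sized communities; edges within a
#' community are Bernoulli at a density chosen so the expected total edge
#' count still equals `edge_density * n * (n - 1)`; the communities are tied
#' together by a random community spanning tree plus an equal number of
#' extra bridges, and each bridge is anchored at an MH gene of its community
#' with probability `bridge_mh_frac`. Inter-community connectivity therefore
#' runs preferentially through MH interactions — the topological role the
#' fragmentation analysis is designed to detect.
#'
#' Each edge is a binding (unsigned, undirected) edge with probability
#' `p_binding`, otherwise a signed directed regulatory edge (positive with
#' probability `sign_balance`). The first `n_mh` genes are flagged MH and
#' are spread across communities by the round-robin assignment.
#'
#' @param spec A `synthetic_spec`.
#' @return An `interaction_network` whose nodes carry a `community` column.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  nc <- spec$n_communities
  ids <- syn_gene_ids(n)
  mh <- c(rep(TRUE, spec$n_mh), rep(FALSE, n - spec$n_mh))
  comm <- rep(seq_len(nc), length.out = n)
  nodes <- data.frame(gene_id = ids, is_mh = mh)
  target_edges <- spec$edge_density * n * (n - 1)

  pairs <- NULL
  if (nc == 1L) {
    all_pairs <- which(diag(n) == 0, arr.ind = TRUE)
    keep <- runif(nrow(all_pairs)) < spec$edge_density
    pairs <- all_pairs[keep, , drop = FALSE]
  } else if (target_edges > 0) {
    # bridges: random community spanning tree plus as many extra links
    tree_order <- sample(nc)
    bridges <- lapply(2:nc, function(i) {
      c(tree_order[i], tree_order[sample.int(i - 1L, 1L)])
    })
    for (b in seq_len(nc)) {
      bridges[[length(bridges) + 1L]] <- sample.int(nc, 2L)
    }
    pick_endpoint <- function(cm) {
      members <- which(comm == cm)
      mh_members <- members[mh[members]]
      if (length(mh_members) > 0L && runif(1) < spec$bridge_mh_frac) {
        mh_members[sample.int(length(mh_members), 1L)]
      } else {
        members[sample.int(length(members), 1L)]
      }
    }
    # MH anchoring on one side only: the bridge is an MH interaction, but
    # distance-1 MH-MH pairs across communities stay rare, so the
    # phenotype-community coupling is not diluted
    pick_uniform <- function(cm) {
      members <- which(comm == cm & !mh)
      if (length(members) == 0L) members <- which(comm == cm)
      members[sample.int(length(members), 1L)]
    }
    bridge_pairs <- t(vapply(bridges, function(b) {
      c(pick_endpoint(b[1]), pick_uniform(b[2]))
    }, integer(2)))
    # intra-community edges carry the remaining density budget
    intra_budget <- max(0, target_edges - nrow(bridge_pairs))
    comm_sizes <- tabulate(comm, nc)
    n_intra_pairs <- sum(comm_sizes * (comm_sizes - 1L))
    p_intra <- min(1, intra_budget / n_intra_pairs)
    intra <- do.call(rbind, lapply(seq_len(nc), function(cm) {
      members <- which(comm == cm)
      if (length(members) < 2L) return(NULL)
      prs <- expand.grid(a = members, b = members)
      prs <- prs[prs$a != prs$b, , drop = FALSE]
      as.matrix(prs[runif(nrow(prs)) < p_intra, , drop = FALSE])
    }))
    pairs <- rbind(intra, bridge_pairs)
  }
  if (is.null(pairs) || nrow(pairs) == 0L) {
    net <- interaction_network(NULL, nodes, name = "synthetic", quiet = TRUE)
    net$nodes$community <- comm[match(net$nodes$gene_id, ids)]
    return(net)
  }
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  m <- nrow(pairs)
  is_binding <- runif(m) < spec$p_binding
  positive <- runif(m) < spec$sign_balance
  type <- ifelse(is_binding, "binding",
                 ifelse(positive, "activation", "inhibition"))
  edges <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      type = type, directed = !is_binding)
  net <- interaction_network(edges, nodes, name = "synthetic", quiet = TRUE)
  net$nodes$community <- comm[match(net$nodes$gene_id, ids)]
  net
}

#' Plant disjoint motif instances into a network
#'
#' Inserts `copies` node-disjoint embeddings of the signed motif class given
#' by `adjacency`, preferring MH genes when `on_mh`. Existing edges between
#' chosen tuples are replaced by the motif edges so the induced subgraph
#' matches the class exactly.
#'
#' @param net An `interaction_network`.
#' @param adjacency Signed k x k motif adjacency.
#' @param copies Number of instances.
#' @param on_mh Prefer MH genes for the embeddings.
#' @param seed Optional integer seed.
#' @return List with `network` (the modified network) and `instances`
#'   (data frame: `class_label`, `nodes` list column — the ground truth).
#' @export
plant_motifs <- function(net, adjacency, copies, on_mh = TRUE, seed = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(adjacency)
  mh_ids <- net$nodes$gene_id[net$nodes$is_mh]
  other_ids <- net$nodes$gene_id[!net$nodes$is_mh]
  pool <- if (on_mh) c(sample(mh_ids), sample(other_ids)) else
    sample(net$nodes$gene_id)
  if (copies * k > length(pool)) {
    stop("not enough genes for ", copies, " disjoint instances of size ", k)
  }
  if (copies == 0L) {
    gt <- data.frame(class_label = character())
    gt$nodes <- list()
    return(list(network = net, instances = gt))
  }
  label <- canonical_label(adjacency)
  tuples <- lapply(seq_len(copies), function(i) {
    pool[seq((i - 1L) * k + 1L, i * k)]
  })
  planted_nodes <- unlist(tuples)
  # drop existing edges among each tuple, then insert the motif edges
  edges <- net$edges
  for (tup in tuples) {
    drop <- edges$source %in% tup & edges$target %in% tup
    edges <- edges[!drop, , drop = FALSE]
  }
  new_rows <- do.call(rbind, lapply(tuples, function(tup) {
    idx <- which(adjacency != 0, arr.ind = TRUE)
    data.frame(source = tup[idx[, 1]], target = tup[idx[, 2]],
               type = ifelse(adjacency[idx] > 0, "activation", "inhibition"),
               directed = TRUE)
  }))
  edges <- rbind(edges[, c("source", "target", "type", "directed")],
                 new_rows)
  out <- interaction_network(edges, net$nodes, name = net$name, quiet = TRUE)
  gt <- data.frame(class_label = rep(label, copies))
  gt$nodes <- tuples
  list(network = out, instances = gt)
}

#' Generate an orthology table with an MH conservation-rate difference
#'
#' Per gene, independent per-species homolog presence with probability
#' `p_gene_mh` for MH genes and `p_gene_other` otherwise.
#'
#' @param spec A `synthetic_spec`.
#' @param net The `interaction_network` supplying gene ids and MH flags.
#' @return An `orthology_table`.
#' @export
generate_orthology <- function(spec, net) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  S <- length(spec$species)
  p <- ifelse(net$nodes$is_mh, spec$p_gene_mh, spec$p_gene_other)
  m <- matrix(rbinom(nrow(net$nodes) * S, 1L, rep(p, S)) == 1L,
              nrow = nrow(net$nodes), ncol = S,
              dimnames = list(net$nodes$gene_id, spec$species))
  orthology_table(m)
}

#' Generate per-species interaction catalogs
#'
#' Each distinct unordered interaction of the network is retained in each
#' species independently with probability `q_edge_mh` (MH interactions) or
#' `q_edge_other`. When `conserve_planted` and planted instances are given,
#' the interactions of every planted motif are forced present in the first
#' seven panel species, so planted instances satisfy motif-level
#' conservation by construction.
#'
#' @param spec A `synthetic_spec`.
#' @param net The `interaction_network`.
#' @param planted Optional planted-instance data frame from
#'   [plant_motifs()].
#' @return A `species_edge_catalog`.
#' @export
generate_species_edge_sets <- function(spec, net, planted = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  keys <- unique(pair_key(net$edges$source, net$edges$target))
  first_by_key <- match(keys, pair_key(net$edges$source, net$edges$target))
  mh_edge <- mh_edge_flags(net)[first_by_key]
  q <- ifelse(mh_edge, spec$q_edge_mh, spec$q_edge_other)
  forced <- character(0)
  if (spec$conserve_planted && !is.null(planted) && nrow(planted) > 0L) {
    adj <- net$edges
    forced <- unique(unlist(lapply(planted$nodes, function(tup) {
      within <- adj$source %in% tup & adj$target %in% tup
      pair_key(adj$source[within], adj$target[within])
    })))
  }
  catalog <- lapply(seq_along(spec$species), function(s) {
    present <- runif(length(keys)) < q
    if (s <= 7L) present <- present | (keys %in% forced)
    keys[present]
  })
  names(catalog) <- spec$species
  species_edge_catalog(catalog)
}

# greedy radius-d0 communities of MH genes on the undirected projection
mh_communities <- function(net, d0) {
  mh_ids <- net$nodes$gene_id[net$nodes$is_mh]
  if (length(mh_ids) == 0L) return(list())
  d <- shortest_path_distances(net, targets = mh_ids)
  unassigned <- mh_ids
  communities <- list()
  while (length(unassigned) > 0L) {
    seed_gene <- unassigned[1]
    members <- unassigned[d[seed_gene, unassigned] <= d0]
    communities[[length(communities) + 1L]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  communities
}

# random point on the 7-class simplex
simplex_point <- function(k = length(phenotype_classes())) {
  x <- rgamma(k, shape = 1)
  x / sum(x)
}

#' Generate proximity-coupled phenoprints for the MH genes
#'
#' MH genes are partitioned greedily into network communities of radius
#' `d0`; each community gets a random piecewise-linear archetype trajectory
#' between two points of the phenotype-class simplex; each gene's phenoprint
#' is its community archetype plus Gaussian noise, clipped at 0. Genes close
#' in the network therefore have similar phenoprints — the coupling the
#' sliding-threshold analysis is designed to detect.
#'
#' @param spec A `synthetic_spec`.
#' @param net The `interaction_network` (MH flags set).
#' @return A `phenoprint_set` over the MH genes.
#' @export
generate_phenoprints <- function(spec, net) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  communities <- mh_communities(net, spec$d0)
  ncls <- length(phenotype_classes())
  tt <- seq(0, 1, length.out = spec$n_time)
  prints <- list()
  for (comm in communities) {
    a <- simplex_point(ncls)
    b <- simplex_point(ncls)
    archetype <- outer(1 - tt, a) + outer(tt, b)
    for (g in comm) {
      traj <- archetype + matrix(rnorm(length(archetype), 0, spec$noise_sd),
                                 nrow = nrow(archetype))
      prints[[g]] <- pmax(traj, 0)
    }
  }
  phenoprint_set(prints)
}

#' Generate a complete synthetic dataset
#'
#' Runs all generators under the spec seed and returns every input the
#' pipeline consumes, together with the planted ground truth.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `spec`, `network` (motifs planted), `orthology`,
#'   `catalog`, `phenoprints`, and `planted` (ground-truth instances).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  net <- generate_network(spec)
  pl <- plant_motifs(net, spec$motif_adjacency, spec$motif_copies,
                     on_mh = spec$motif_on_mh, seed = spec$seed + 4L)
  net <- pl$network
  list(spec = spec,
       network = net,
       orthology = generate_orthology(spec, net),
       catalog = generate_species_edge_sets(spec, net,
                                            planted = pl$instances),
       phenoprints = generate_phenoprints(spec, net),
       planted = pl$instances)
}

#' Write a synthetic dataset to disk
#'
#' Emits the edge-list TSV, annotation TSV, orthology TSV, long-format
#' species catalog TSV, phenoprint CSV, and a ground-truth JSON.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, "edges.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             orthology = file.path(dir, "orthology.tsv"),
             catalog = file.path(dir, "species_catalog.tsv"),
             phenoprints = file.path(dir, "phenoprints.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_network(dataset$network, paths[["edges"]], paths[["annotation"]])
  write_orthology(dataset$orthology, paths[["orthology"]])
  write_species_catalog(dataset$catalog, paths[["catalog"]])
  write_phenoprints(dataset$phenoprints, paths[["phenoprints"]])
  gt <- list(seed = dataset$spec$seed,
             planted_class = if (nrow(dataset$planted) > 0L)
               dataset$planted$class_label[1] else NULL,
             planted_instances = dataset$planted$nodes)
  jsonlite::write_json(gt, paths[["ground_truth"]], auto_unbox = TRUE)
  invisible(paths)
}
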