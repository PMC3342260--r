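# Signed motif census, canonical labeling, randomization null, Boolean
# bistability, feedback circuits, and motif conservation.

toggle <- matrix(c(0, -1, -1, 0), 2, 2, byrow = TRUE)

random_signed_adj <- function(k, seed) {
  set.seed(seed)
  adj <- matrix(sample(c(0, 1, -1), k * k, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)), k, k)
  diag(adj) <- 0
  adj
}

test_that("canonical labels are invariant under relabeling and separate
           non-isomorphic signed digraphs", {
  perm <- c(2, 1)
  expect_equal(canonical_label(toggle), canonical_label(toggle[perm, perm]))
  act3 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  inh3 <- -act3
  expect_false(canonical_label(act3) == canonical_label(inh3))
  for (s in 1:10) {
    adj <- random_signed_adj(4, 600 + s)
    p <- sample(4)
    expect_equal(canonical_label(adj), canonical_label(adj[p, p]))
  }
})

test_that("label partition equals brute-force isomorphism classes for all
           size-2 signed digraphs", {
  grids <- expand.grid(e12 = c(0, 1, -1), e21 = c(0, 1, -1))
  adjs <- lapply(seq_len(nrow(grids)), function(i) {
    matrix(c(0, grids$e12[i], grids$e21[i], 0), 2, 2, byrow = TRUE)
  })
  labels <- vapply(adjs, canonical_label, "")
  # partition by explicit pairwise isomorphism testing
  classes <- list()
  for (a in adjs) {
    hit <- FALSE
    for (ci in seq_along(classes)) {
      if (oracle_sign_isomorphic(classes[[ci]], a)) { hit <- TRUE; break }
    }
    if (!hit) classes[[length(classes) + 1]] <- a
  }
  expect_equal(length(unique(labels)), length(classes))
  # same-label pairs are isomorphic, different-label pairs are not
  for (i in seq_along(adjs)) {
    for (j in seq_along(adjs)) {
      expect_equal(labels[i] == labels[j],
                   oracle_sign_isomorphic(adjs[[i]], adjs[[j]]))
    }
  }
})

test_that("census equals brute-force enumeration over node subsets", {
  tri <- toy_network(list(c("a", "b", "activation"),
                          c("b", "c", "activation"),
                          c("c", "a", "activation")))
  inst <- enumerate_connected_subgraphs(tri, 3)
  expect_equal(nrow(inst), 1)

  # complete digraph on 4 nodes: every triple induces a connected subgraph
  k4 <- list()
  for (i in 1:4) for (j in 1:4) {
    if (i != j) k4[[length(k4) + 1]] <-
        c(paste0("v", i), paste0("v", j), "activation")
  }
  expect_equal(nrow(enumerate_connected_subgraphs(toy_network(k4), 3)),
               choose(4, 3))

  for (s in 1:4) {
    net <- random_toy_network(12, 0.15, seed = 700 + s, p_neg = 0.4)
    for (k in c(3, 4)) {
      counts <- motif_counts(net, k)
      ref <- oracle_census_counts(net, k)
      expect_equal(counts[sort(names(counts))], ref[sort(names(ref))])
      # instance labels match the canonical label of their induced subgraph
      inst <- enumerate_connected_subgraphs(net, k)
      expect_equal(sum(lengths(split(inst$class_label, inst$class_label))),
                   sum(ref))
    }
  }
  expect_error(enumerate_connected_subgraphs(tri, 5), "3 or 4")
})

test_that("degree-preserving randomization preserves per-sign in/out degree
           sequences and actually moves edges on dense graphs", {
  net <- random_toy_network(30, 0.15, seed = 19, p_neg = 0.4)
  rnd <- degree_preserving_randomize(net, seed = 23)
  for (sg in c(1L, -1L)) {
    e0 <- net$edges[net$edges$sign == sg, ]
    e1 <- rnd$edges[rnd$edges$sign == sg, ]
    expect_equal(table(factor(e1$source, levels = net$nodes$gene_id)),
                 table(factor(e0$source, levels = net$nodes$gene_id)))
    expect_equal(table(factor(e1$target, levels = net$nodes$gene_id)),
                 table(factor(e0$target, levels = net$nodes$gene_id)))
    expect_false(any(duplicated(paste(e1$source, e1$target))))
    expect_false(any(e1$source == e1$target))
  }
  key0 <- sort(paste(net$edges$source, net$edges$target, net$edges$sign))
  key1 <- sort(paste(rnd$edges$source, rnd$edges$target, rnd$edges$sign))
  expect_false(identical(key0, key1))

  # two edges with no legal swap stay unchanged
  frozen <- toy_network(list(c("a", "b", "activation"),
                             c("b", "a", "activation")))
  rnd2 <- degree_preserving_randomize(frozen, seed = 1)
  expect_setequal(paste(rnd2$edges$source, rnd2$edges$target),
                  c("a b", "b a"))
})

test_that("motif significance flags planted over-represented classes and
           removes classes with more nodes than edges", {
  base <- generate_network(synthetic_spec(n_genes = 120, n_mh = 20,
                                          edge_density = 0.012,
                                          n_communities = 1, p_binding = 0,
                                          motif_copies = 0, seed = 55))
  pl <- plant_motifs(base, toggle_triad(), copies = 10, seed = 56)
  reg <- to_regulatory(pl$network)
  sig <- motif_significance(reg, 3, n_random = 150, seed = 57)
  expect_true(all(sig$n_edges >= 3))  # chains of 2 edges were dropped
  planted_label <- pl$instances$class_label[1]
  row <- sig[sig$class_label == planted_label, ]
  expect_equal(nrow(row), 1)
  expect_true(row$significant)
  expect_gte(row$count_observed, 10)

  # an unperturbed sparse random network yields few significant classes
  reg0 <- to_regulatory(base)
  sig0 <- motif_significance(reg0, 3, n_random = 150, seed = 58)
  expect_lte(sum(sig0$significant), max(1, nrow(sig0) %/% 5))
})

test_that("Boolean fixed points reproduce the canonical small circuits", {
  mutual_act <- matrix(c(0, 1, 1, 0), 2, 2)
  fp <- boolean_fixed_points(mutual_act)
  expect_setequal(apply(fp, 1, paste, collapse = ""), c("00", "11"))

  fp_t <- boolean_fixed_points(toggle)
  states <- apply(fp_t, 1, paste, collapse = "")
  expect_true(all(c("10", "01") %in% states))
  expect_true(is_bistable(toggle))

  # single edge: the source is input-free and clamped off
  single <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  fp_s <- boolean_fixed_points(single)
  expect_equal(nrow(fp_s), 1)
  expect_equal(unname(fp_s[1, ]), c(0L, 0L))
  expect_false(is_bistable(single))

  neg3 <- matrix(c(0, 1, 0, 0, 0, 1, -1, 0, 0), 3, 3, byrow = TRUE)
  expect_false(is_bistable(neg3))
  expect_true(is_bistable(toggle_triad()))
})

test_that("feedback circuits carry the product sign of their edges", {
  circ_t <- feedback_circuits(toggle)
  expect_equal(length(circ_t), 1)
  expect_equal(circ_t[[1]]$sign, 1)  # (-1) * (-1)
  expect_true(has_positive_circuit(toggle))

  act2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(feedback_circuits(act2)[[1]]$sign, 1)

  neg3 <- matrix(c(0, 1, 0, 0, 0, 1, -1, 0, 0), 3, 3, byrow = TRUE)
  circ_n <- feedback_circuits(neg3)
  expect_equal(length(circ_n), 1)
  expect_equal(circ_n[[1]]$sign, -1)
  expect_false(has_positive_circuit(neg3))
})

test_that("every bistable signed motif contains a positive circuit
           (exhaustive at size <= 3, sampled at size 4)", {
  for (k in 2:3) {
    for (lab in enumerate_signed_classes(k)) {
      bist <- is_bistable(lab)
      if (isTRUE(bist)) {
        expect_true(has_positive_circuit(lab),
                    info = paste("bistable class without positive circuit:",
                                 lab))
      }
    }
  }
  for (s in 1:40) {
    adj <- random_signed_adj(4, 900 + s)
    if (isTRUE(is_bistable(adj))) {
      expect_true(has_positive_circuit(adj))
    }
  }
})

test_that("motif instance conservation requires a common species set across
           all instance edges", {
  expect_true(motif_instance_conserved(list(as.character(1:7),
                                            as.character(1:7))))
  expect_false(motif_instance_conserved(list(as.character(1:7),
                                             as.character(3:9))))
  expect_false(motif_instance_conserved(list(as.character(1:7),
                                             character())))

  net <- toy_network(list(c("a", "b", "activation"),
                          c("b", "c", "inhibition"),
                          c("c", "a", "activation")),
                     mh = "a")
  sp_com <- paste0("s", 1:7)
  catalog <- stats::setNames(lapply(1:9, function(s) {
    if (s <= 7) pair_key(c("a", "b", "c"), c("b", "c", "a")) else character()
  }), paste0("s", 1:9))
  lab <- classify_edges(net, species_edge_catalog(catalog), f = 0.7)
  inst <- enumerate_connected_subgraphs(net, 3)
  ann <- annotate_motif_instances(inst, net, edge_labels = lab)
  expect_true(ann$conserved)
  expect_equal(ann$n_species_common, 7L)
  expect_true(ann$is_mh)
})

test_that("MH enrichment within motifs and the motif-cluster clustering
           test behave on constructed graphs", {
  # a clique of MH genes hanging off a path of non-MH genes
  rows <- list()
  cl <- paste0("m", 1:5)
  for (i in 1:4) for (j in (i + 1):5) {
    rows[[length(rows) + 1]] <- c(cl[i], cl[j], "activation")
  }
  for (i in 1:9) {
    rows[[length(rows) + 1]] <- c(paste0("t", i), paste0("t", i + 1),
                                  "activation")
  }
  rows[[length(rows) + 1]] <- c("m1", "t1", "activation")
  net <- toy_network(rows, mh = cl)
  inst <- enumerate_connected_subgraphs(net, 3)
  clique_inst <- inst[vapply(inst$nodes, function(nd) all(nd %in% cl),
                             logical(1)), ]
  enr <- motif_gene_enrichment(clique_inst, net)
  expect_lt(enr$p_value, 0.01)

  res <- motif_cluster_analysis(clique_inst, net)
  expect_lt(res$p_value, 0.01)
  expect_setequal(res$cluster_genes, cl)
  expect_equal(nrow(res$subnetwork$edges), 10)  # the clique's edges

  single <- inst[1, ]
  single$nodes <- list("m1")
  expect_error(motif_cluster_analysis(single, net), "fewer than two")

  none <- inst[0, ]
  expect_equal(motif_gene_enrichment(none, net)$p_value, 1)
  expect_true(motif_gene_enrichment(none, net)$degenerate)
})
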