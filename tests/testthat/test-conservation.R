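# Conservation classification of genes and interactions, and Fisher
# enrichment.

make_orth <- function(counts, S = 9, species = paste0("s", 1:9)) {
  m <- t(vapply(counts, function(k) seq_len(S) <= k, logical(S)))
  rownames(m) <- sprintf("g%d", seq_along(counts))
  colnames(m) <- species
  orthology_table(m)
}

test_that("gene conservation cutoff uses the ceiling rule", {
  expect_equal(conservation_k_min(0.7, 9), 7L)
  expect_equal(conservation_k_min(0.6, 9), 6L)
  expect_equal(conservation_k_min(0.8, 9), 8L)
  expect_equal(conservation_k_min(0.7, 7), 5L)
  expect_error(conservation_k_min(1.5, 9), "0, 1")

  orth <- make_orth(c(7, 6, 9, 0))
  lab7 <- classify_genes(orth, f = 0.7)
  expect_equal(lab7$conserved, c(TRUE, FALSE, TRUE, FALSE))
  lab6 <- classify_genes(orth, f = 0.6)
  expect_true(lab6$conserved[2])  # ceiling(5.4) = 6
  # gene absent from the table counts as present nowhere
  lab_q <- classify_genes(orth, f = 0.7, genes = c("g1", "missing"))
  expect_equal(lab_q$n_species, c(7L, 0L))
  expect_equal(lab_q$conserved, c(TRUE, FALSE))
})

test_that("raising the cutoff never makes a non-conserved entity conserved", {
  set.seed(13)
  orth <- make_orth(sample(0:9, 40, replace = TRUE))
  prev <- rep(TRUE, 40)
  for (f in c(0.3, 0.5, 0.7, 0.9, 1.0)) {
    cur <- classify_genes(orth, f = f)$conserved
    expect_true(all(!prev | cur == (cur & prev)))  # cur subset of prev
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("edge conservation counts species catalogs containing the
           unordered pair", {
  net <- toy_network(list(c("a", "b", "activation"),
                          c("c", "d", "activation")))
  cat7 <- species_edge_catalog(c(
    lapply(1:7, function(i) data.frame(gene_a = "b", gene_b = "a")),
    lapply(8:9, function(i) data.frame(gene_a = "x", gene_b = "y"))
  ) |> stats::setNames(paste0("s", 1:9)))
  lab <- classify_edges(net, cat7, f = 0.7)
  expect_equal(lab$n_species, c(7L, 0L))
  expect_equal(lab$conserved, c(TRUE, FALSE))

  # random catalogs match a per-edge counting oracle
  set.seed(4)
  net2 <- random_toy_network(10, 0.3, seed = 44)
  keys <- pair_key(net2$edges$source, net2$edges$target)
  catalog <- lapply(1:9, function(s) {
    unique(keys[runif(length(keys)) < 0.5])
  })
  names(catalog) <- paste0("s", 1:9)
  lab2 <- classify_edges(net2, species_edge_catalog(catalog), f = 0.7)
  ref <- vapply(keys, function(k) {
    sum(vapply(catalog, function(ck) k %in% ck, logical(1)))
  }, integer(1))
  expect_equal(lab2$n_species, unname(ref))
  expect_equal(lab2$conserved, unname(ref) >= 7)
})

test_that("one-sided Fisher agrees with margin-fixed enumeration and
           handles degenerate margins", {
  expect_equal(fisher_exact_one_sided(3, 1, 1, 3)$p_value,
               oracle_fisher_greater(3, 1, 1, 3), tolerance = 1e-12)
  set.seed(8)
  for (r in 1:15) {
    cnt <- sample(0:8, 4, replace = TRUE)
    res <- fisher_exact_one_sided(cnt[1], cnt[2], cnt[3], cnt[4])
    ref <- oracle_fisher_greater(cnt[1], cnt[2], cnt[3], cnt[4])
    if (res$degenerate) {
      expect_equal(res$p_value, 1)
    } else {
      expect_equal(res$p_value, ref, tolerance = 1e-9)
      # the two one-sided tests overlap on the observed table
      less <- stats::fisher.test(matrix(cnt, 2, byrow = TRUE),
                                 alternative = "less")$p.value
      expect_gte(res$p_value + less, 1 - 1e-9)
    }
  }
  deg <- fisher_exact_one_sided(0, 5, 0, 7)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("conservation enrichment builds the MH-by-conserved table and a
           planted rate difference is detected", {
  orth <- make_orth(c(9, 9, 9, 2, 2, 2))
  lab <- classify_genes(orth, f = 0.7)
  mh <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  res <- conservation_enrichment(lab, mh)
  expect_equal(unname(res$table[1, ]), c(2, 1))  # MH: conserved, not
  expect_equal(unname(res$table[2, ]), c(1, 2))
  expect_equal(res$p_value,
               oracle_fisher_greater(2, 1, 1, 2), tolerance = 1e-9)

  # planted difference p_mh = 0.9 vs p_other = 0.6 on 2000 genes
  nodes <- data.frame(gene_id = sprintf("G%04d", 1:2000),
                      is_mh = rep(c(TRUE, FALSE), c(200, 1800)))
  fake_net <- interaction_network(NULL, nodes, quiet = TRUE)
  sp <- synthetic_spec(seed = 77)
  orth_big <- generate_orthology(sp, fake_net)
  enr <- conservation_enrichment(classify_genes(orth_big, 0.7,
                                                genes = nodes$gene_id),
                                 nodes$is_mh)
  expect_lt(enr$p_value, 1e-3)
})

test_that("conserved subnetwork keeps conserved edges with their species
           sets and incident nodes", {
  net <- random_toy_network(12, 0.25, seed = 15)
  keys <- pair_key(net$edges$source, net$edges$target)
  set.seed(2)
  catalog <- stats::setNames(lapply(1:9, function(s) {
    unique(keys[runif(length(keys)) < 0.6])
  }), paste0("s", 1:9))
  lab <- classify_edges(net, species_edge_catalog(catalog), f = 0.7)
  sub <- conserved_subnetwork(net, lab)
  expect_equal(nrow(sub$edges), sum(lab$conserved))
  expect_setequal(sub$nodes$gene_id,
                  unique(c(sub$edges$source, sub$edges$target)))
  expect_true(all(sub$edges$n_species >= 7))
  expect_true(all(lengths(sub$edges$species) == sub$edges$n_species))

  all_lab <- lab; all_lab$conserved <- TRUE
  expect_equal(nrow(conserved_subnetwork(net, all_lab)$edges),
               nrow(net$edges))
  none_lab <- lab; none_lab$conserved <- FALSE
  expect_equal(nrow(conserved_subnetwork(net, none_lab)$edges), 0)
})

test_that("per-category set enrichment matches the enumeration oracle and
           ranks the self-category first", {
  universe <- sprintf("u%d", 1:10)
  members <- universe[1:4]
  cats <- list(self = members,
               disjoint = universe[5:8],
               partial = universe[3:7])
  res <- set_enrichment(members, cats, universe)
  expect_equal(res$category[1], "self")
  expect_equal(res$p_value[res$category == "disjoint"], 1)
  for (nm in names(cats)) {
    a <- length(intersect(members, cats[[nm]]))
    b <- length(members) - a
    c_ <- length(cats[[nm]]) - a
    d <- 10 - a - b - c_
    expect_equal(res$p_value[res$category == nm],
                 oracle_fisher_greater(a, b, c_, d), tolerance = 1e-9)
  }
  expect_error(set_enrichment(c("zz"), cats, universe), "subset")
})
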