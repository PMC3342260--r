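# Signed network container, IO, regulatory filter, and graph statistics.

test_that("edge ingestion maps types to signs, collapses duplicates, and
           auto-creates unannotated nodes", {
  net <- toy_network(list(c("a", "b", "activation"),
                          c("b", "c", "inhibition"),
                          c("a", "c", "binding", FALSE)))
  expect_equal(nrow(net$edges), 3)
  expect_equal(sort(net$edges$sign), c(-1L, 0L, 1L))

  empty <- interaction_network(NULL, NULL)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(giant_component_size(empty), 0L)

  # duplicated (source, target, type) collapses to the distinct triples
  dup <- data.frame(source = c("a", "a", "a"), target = c("b", "b", "b"),
                    type = c("activation", "activation", "expression"),
                    directed = TRUE)
  net2 <- interaction_network(dup, quiet = TRUE)
  key_set <- unique(paste(dup$source, dup$target, dup$type))
  expect_equal(nrow(net2$edges), length(key_set))

  # unknown type falls back to "other" with sign 0
  net3 <- interaction_network(data.frame(source = "x", target = "y",
                                         type = "phosphorylation",
                                         directed = TRUE), quiet = TRUE)
  expect_equal(net3$edges$type, "other")
  expect_equal(net3$edges$sign, 0L)

  # endpoint absent from annotation is added as non-MH, with a warning
  expect_warning(
    net4 <- interaction_network(
      data.frame(source = "a", target = "b", type = "binding",
                 directed = FALSE),
      nodes = data.frame(gene_id = "a", is_mh = TRUE)),
    "absent")
  expect_false(net4$nodes$is_mh[net4$nodes$gene_id == "b"])
})

test_that("network read/write round trip is lossless and malformed input is
           reported by line", {
  net <- random_toy_network(12, 0.2, seed = 7, p_binding = 0.3)
  edge_file <- withr::local_tempfile(fileext = ".tsv")
  ann_file <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, edge_file, ann_file)
  back <- read_network(edge_file, ann_file)
  expect_equal(back$edges[order(back$edges$source, back$edges$target,
                                back$edges$type), ],
               net$edges[order(net$edges$source, net$edges$target,
                               net$edges$type), ],
               ignore_attr = TRUE)
  expect_equal(back$nodes, net$nodes)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\ttype\tdirected",
               "a\tb\tactivation\t1",
               "b\tc\tinhibition\tmaybe"), bad)
  expect_error(read_network(bad), "line.*2")
})

test_that("regulatory filter keeps exactly the signed edges, directed, and
           is idempotent", {
  net <- toy_network(list(c("a", "b", "activation"),
                          c("a", "c", "binding", FALSE)))
  reg <- to_regulatory(net)
  expect_equal(nrow(reg$edges), 1)
  expect_equal(reg$edges$sign, 1L)
  expect_false("c" %in% reg$nodes$gene_id)  # isolated node dropped

  none <- to_regulatory(toy_network(list(c("a", "b", "binding", FALSE))))
  expect_equal(nrow(none$edges), 0)

  mixed <- random_toy_network(10, 0.3, seed = 3, p_binding = 0.4)
  reg_m <- to_regulatory(mixed)
  expect_equal(nrow(reg_m$edges), sum(mixed$edges$sign != 0))
  expect_true(all(reg_m$edges$directed))
  # idempotent, edge subset, MH flags preserved
  reg_mm <- to_regulatory(reg_m)
  expect_equal(reg_mm$edges[, c("source", "target", "type", "sign")],
               reg_m$edges[, c("source", "target", "type", "sign")])
  mh_in <- mixed$nodes$is_mh[match(reg_m$nodes$gene_id,
                                   mixed$nodes$gene_id)]
  expect_equal(reg_m$nodes$is_mh, mh_in)
})

test_that("shortest-path distances match the Floyd-Warshall oracle and obey
           metric properties", {
  path <- toy_network(list(c("a", "b", "binding", FALSE),
                           c("b", "c", "binding", FALSE)))
  d <- shortest_path_distances(path, c("a", "c"))
  expect_equal(d["a", "c"], 2)

  two <- toy_network(list(c("a", "b", "binding", FALSE),
                          c("x", "y", "binding", FALSE)))
  expect_equal(shortest_path_distances(two, c("a", "x"))["a", "x"], Inf)

  expect_error(shortest_path_distances(path, c("a", "zz")), "zz")

  net <- random_toy_network(20, 0.12, seed = 11, p_binding = 0.5)
  d_all <- shortest_path_distances(net, net$nodes$gene_id)
  ref <- oracle_floyd_warshall(net)
  expect_equal(d_all, ref[rownames(d_all), colnames(d_all)])
  expect_equal(diag(d_all), stats::setNames(rep(0, 20), rownames(d_all)))
  expect_equal(d_all, t(d_all))
  fin <- is.finite(d_all)
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (fin[i, k] && fin[k, j]) {
      expect_lte(d_all[i, j], d_all[i, k] + d_all[k, j])
    }
  }
})

test_that("giant component size matches union-find and shrinks
           monotonically under deletion", {
  comp <- toy_network(list(c("a", "b", "binding", FALSE),
                           c("b", "c", "binding", FALSE),
                           c("c", "d", "binding", FALSE),
                           c("d", "e", "binding", FALSE),
                           c("x", "y", "binding", FALSE),
                           c("y", "z", "binding", FALSE)))
  expect_equal(giant_component_size(comp), 5L)

  for (s in 1:5) {
    net <- random_toy_network(15, 0.12, seed = 100 + s, p_binding = 0.5)
    expect_equal(giant_component_size(net), oracle_gcs_union_find(net))
    # node deletion cannot grow the giant component
    drop <- sample(net$nodes$gene_id, 3)
    expect_lte(targeted_removal_gcs(net, nodes = drop),
               giant_component_size(net))
  }
})

test_that("local clustering matches brute-force triangle counting", {
  tri <- toy_network(list(c("a", "b", "binding", FALSE),
                          c("b", "c", "binding", FALSE),
                          c("c", "a", "binding", FALSE)))
  expect_equal(unname(local_clustering(tri)), rep(1, 3))

  star <- toy_network(list(c("h", "l1", "binding", FALSE),
                           c("h", "l2", "binding", FALSE),
                           c("h", "l3", "binding", FALSE)))
  expect_equal(unname(local_clustering(star)["h"]), 0)

  net <- random_toy_network(15, 0.25, seed = 21, p_binding = 0.5)
  cc <- local_clustering(net)
  ref <- oracle_local_clustering(net)
  expect_equal(cc[sort(names(cc))], ref[sort(names(ref))])
})

test_that("an interaction is MH iff it touches at least one MH gene", {
  net <- toy_network(list(c("m1", "m2", "binding", FALSE),
                          c("m1", "o1", "binding", FALSE),
                          c("o1", "o2", "binding", FALSE)),
                     mh = c("m1", "m2"))
  labs <- mh_edge_labels(net)
  expect_equal(unname(labs), c("MH", "MH", "non-MH"))
})
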