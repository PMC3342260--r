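# Phenoprints and the phenotype-vs-network distance analysis.
#
# A phenoprint is a gene's time course of cell-population fractions over
# seven phenotype classes observed after silencing that gene (mitotic delay,
# binuclear, polylobed, grape, large, dynamic, cell death). Trajectories are
# compared with the Hausdorff distance between their point sets in 7-space,
# and phenotypic similarity is related to network proximity through a
# sliding-threshold one-sided Wilcoxon procedure and mirrored Ward trees.

#' The seven phenotype classes
#' @return Character vector of class names (column schema of phenoprints).
#' @export
phenotype_classes <- function() {
  c("mitotic_delay", "binuclear", "polylobed", "grape", "large", "dynamic",
    "cell_death")
}

#' Construct a phenoprint set
#'
#' @param trajectories Named list; element i is the trajectory of gene i as a
#'   numeric matrix with one row per time point and one column per phenotype
#'   class (all values non-negative).
#' @return Object of class `phenoprint_set` (the validated named list).
#' @export
phenoprint_set <- function(trajectories) {
  if (is.null(names(trajectories)) || any(names(trajectories) == "")) {
    stop("trajectories must be a named list (gene ids)")
  }
  ncls <- length(phenotype_classes())
  trajectories <- lapply(trajectories, function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 1L) stop("empty trajectory")
    if (ncol(m) != ncls) {
      stop("trajectory must have ", ncls, " phenotype-class columns")
    }
    if (any(m < 0)) stop("phenotype class fractions must be non-negative")
    colnames(m) <- phenotype_classes()
    m
  })
  structure(trajectories, class = "phenoprint_set")
}

#' Read phenoprints from CSV
#'
#' Expected columns: `gene_id`, `time`, then the seven phenotype-class
#' columns named as in [phenotype_classes()].
#'
#' @param file Path to the CSV.
#' @return A `phenoprint_set`.
#' @export
read_phenoprints <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("gene_id", "time", phenotype_classes())
  if (!all(need %in% names(df))) {
    stop("phenoprint CSV lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[order(df$gene_id, df$time), , drop = FALSE]
  mats <- lapply(split(df, df$gene_id), function(d) {
    as.matrix(d[, phenotype_classes(), drop = FALSE])
  })
  phenoprint_set(mats)
}

#' Write phenoprints to CSV
#' @param prints A `phenoprint_set`.
#' @param file Output path.
#' @return Invisibly, `prints`.
#' @export
write_phenoprints <- function(prints, file) {
  stopifnot(inherits(prints, "phenoprint_set"))
  rows <- lapply(names(prints), function(g) {
    m <- prints[[g]]
    data.frame(gene_id = g, time = seq_len(nrow(m)) - 1L, m,
               check.names = FALSE)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  invisible(prints)
}

#' Hausdorff distance between two trajectories
#'
#' Trajectories are treated as point sets in phenotype space (time stamps do
#' not enter the metric); the distance is the symmetric Hausdorff distance
#' under the Euclidean base metric, i.e. the larger of the two directed
#' Hausdorff distances.
#'
#' @param a,b Numeric matrices (rows = time points, columns = phenotype
#'   classes) with the same number of columns.
#' @return Non-negative scalar.
#' @export
#' @examples
#' a <- matrix(0, 1, 7); b <- matrix(c(1, rep(0, 6)), 1, 7)
#' hausdorff_distance(a, b)  # 1
hausdorff_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty trajectory")
  if (ncol(a) != ncol(b)) stop("trajectories have different class schemas")
  pracma::hausdorff_dist(a, b)
}

#' Pairwise Hausdorff distance matrix
#'
#' @param prints A `phenoprint_set` (at least two genes).
#' @param genes Optional gene subset; all must be present.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
phenotype_distance_matrix <- function(prints, genes = NULL) {
  stopifnot(inherits(prints, "phenoprint_set"))
  if (is.null(genes)) genes <- names(prints)
  absent <- setdiff(genes, names(prints))
  if (length(absent) > 0L) {
    stop("no phenoprint for gene(s): ", paste(absent, collapse = ", "))
  }
  if (length(genes) < 2L) stop("need at least two phenoprints")
  n <- length(genes)
  d <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- hausdorff_distance(prints[[genes[i]]],
                                               prints[[genes[j]]])
    }
  }
  d
}

#' One-sided Wilcoxon rank-sum test ("x less than y")
#'
#' P-value for the alternative that `x` is stochastically smaller than `y`.
#' The exact permutation distribution is used for small untied samples; the
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y Non-empty numeric samples.
#' @return P-value.
#' @export
wilcoxon_one_sided_less <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  suppressWarnings(wilcox.test(x, y, alternative = "less"))$p.value
}

#' Sliding-threshold analysis of phenotype vs network distance
#'
#' For every distinct finite network distance `d` (ascending), MH gene pairs
#' are split into group I (network distance <= d) and group II (the rest),
#' and a one-sided Wilcoxon rank-sum test asks whether group I phenotypic
#' distances are smaller. Pairs at infinite network distance are excluded
#' throughout.
#'
#' @param net_d,phen_d Distance matrices over the same gene set (same
#'   dimnames; `net_d` may contain `Inf`).
#' @return Data frame with one row per threshold: `threshold`, `p_value`,
#'   `n_pairs_group1`, `n_pairs_group2`, `n_group1_genes`,
#'   `fraction_group1`, `group2_empty`. When group II is empty (maximal
#'   threshold) the row is emitted with `p_value = NA` and
#'   `group2_empty = TRUE`.
#' @export
sliding_threshold_analysis <- function(net_d, phen_d) {
  genes <- rownames(net_d)
  if (is.null(genes) || !setequal(genes, rownames(phen_d))) {
    stop("distance matrices must be indexed by the same gene set")
  }
  phen_d <- phen_d[genes, genes, drop = FALSE]
  idx <- which(upper.tri(net_d), arr.ind = TRUE)
  nd <- net_d[idx]
  pd <- phen_d[idx]
  finite <- is.finite(nd)
  idx <- idx[finite, , drop = FALSE]
  nd <- nd[finite]
  pd <- pd[finite]
  if (length(nd) == 0L) stop("no finite network distances among gene pairs")
  thresholds <- sort(unique(nd))
  n_total_genes <- length(unique(c(genes[idx[, 1]], genes[idx[, 2]])))
  rows <- lapply(thresholds, function(d) {
    g1 <- nd <= d
    genes1 <- unique(c(genes[idx[g1, 1]], genes[idx[g1, 2]]))
    empty2 <- !any(!g1)
    p <- if (empty2) NA_real_ else wilcoxon_one_sided_less(pd[g1], pd[!g1])
    data.frame(threshold = d, p_value = p,
               n_pairs_group1 = sum(g1), n_pairs_group2 = sum(!g1),
               n_group1_genes = length(genes1),
               fraction_group1 = length(genes1) / n_total_genes,
               group2_empty = empty2)
  })
  do.call(rbind, rows)
}

# min-max scale the off-diagonal entries of a distance matrix to [0, 1]
scale_unit <- function(d) {
  off <- d[upper.tri(d) | lower.tri(d)]
  rng <- range(off)
  if (rng[2] > rng[1]) {
    d <- (d - rng[1]) / (rng[2] - rng[1])
  } else {
    d[] <- 0
  }
  diag(d) <- 0
  d
}

#' Mirrored Ward trees of network and phenotype distances
#'
#' Both matrices are min-max scaled to \[0, 1\] and clustered with Ward
#' linkage. The per-leaf correspondence depth counts, starting from the root,
#' how many successive levels (cuts into k = 1, 2, ... clusters) place the
#' leaf in clusters with identical gene content on both sides; it is the
#' quantity rendered as line thickness in a tanglegram.
#'
#' Genes at non-finite network distance from any other gene are dropped with
#' a warning (they cannot be placed on the network tree).
#'
#' @param net_d,phen_d Distance matrices over the same gene set.
#' @param method Agglomeration method passed to [stats::hclust()]; default
#'   `"ward.D2"` (Ward criterion on the scaled dissimilarities).
#' @return Object of class `mirrored_trees`: list with `tree_network` and
#'   `tree_phenotype` (hclust objects), `depth` (named integer vector) and
#'   `leaves`.
#' @export
mirrored_trees <- function(net_d, phen_d, method = "ward.D2") {
  genes <- rownames(net_d)
  if (is.null(genes) || !setequal(genes, rownames(phen_d))) {
    stop("distance matrices must be indexed by the same gene set")
  }
  finite_all <- apply(is.finite(net_d), 1L, all)
  if (!all(finite_all)) {
    warning("dropping ", sum(!finite_all),
            " gene(s) at non-finite network distance")
    genes <- genes[finite_all]
  }
  if (length(genes) < 3L) stop("need at least three leaves")
  nd <- scale_unit(net_d[genes, genes])
  pd <- scale_unit(phen_d[genes, genes])
  h1 <- hclust(as.dist(nd), method = method)
  h2 <- hclust(as.dist(pd), method = method)
  n <- length(genes)
  depth <- setNames(integer(n), genes)
  memb1 <- lapply(seq_len(n), function(k) cutree(h1, k = k))
  memb2 <- lapply(seq_len(n), function(k) cutree(h2, k = k))
  for (g in genes) {
    d <- 0L
    for (k in seq_len(n)) {
      set1 <- names(memb1[[k]])[memb1[[k]] == memb1[[k]][g]]
      set2 <- names(memb2[[k]])[memb2[[k]] == memb2[[k]][g]]
      if (setequal(set1, set2)) d <- d + 1L else break
    }
    depth[g] <- d
  }
  structure(list(tree_network = h1, tree_phenotype = h2, depth = depth,
                 leaves = genes),
            class = "mirrored_trees")
}

#' @export
print.mirrored_trees <- function(x, ...) {
  cat("Mirrored Ward trees over", length(x$leaves), "leaves\n")
  cat("  correspondence depth: median", stats::median(x$depth),
      "max", max(x$depth), "\n")
  invisible(x)
}

#' Export mirrored trees as Newick files
#'
#' @param mt A `mirrored_trees` object.
#' @param network_file,phenotype_file Output paths.
#' @return Invisibly, `mt`.
#' @export
write_mirrored_trees <- function(mt, network_file, phenotype_file) {
  stopifnot(inherits(mt, "mirrored_trees"))
  ape::write.tree(ape::as.phylo(mt$tree_network), network_file)
  ape::write.tree(ape::as.phylo(mt$tree_phenotype), phenotype_file)
  invisible(mt)
}
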