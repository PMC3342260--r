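# Evolutionary conservation of genes and interactions, and Fisher
# enrichment of mitotic-hit entities among the conserved ones.
#
# A gene is conserved when it has homologs in at least a cutoff fraction
# (default 70%) of the species panel; an interaction is conserved when the
# unordered gene pair is retained in at least that fraction of the species'
# interaction catalogs. Conservation is pair-level and type-agnostic:
# orthologous interactions are inferred from conservation of the interacting
# genes, so direction and interaction type do not enter the classification.

#' Minimum species count for a conservation cutoff
#' @param f Cutoff fraction in (0, 1].
#' @param n_species Size of the species panel.
#' @return `ceiling(f * n_species)`.
#' @export
#' @examples
#' conservation_k_min(0.7, 9)  # 7
conservation_k_min <- function(f, n_species) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop("cutoff must be in (0, 1]")
  as.integer(ceiling(f * n_species))
}

#' Construct an orthology table
#'
#' @param presence Logical (or 0/1) matrix, genes x species, with gene ids as
#'   row names and species as column names.
#' @return Object of class `orthology_table` (the logical matrix).
#' @export
orthology_table <- function(presence) {
  m <- as.matrix(presence)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs gene row names and species column names")
  }
  storage.mode(m) <- "logical"
  structure(m, class = c("orthology_table", class(m)))
}

#' Read an orthology table from TSV
#'
#' First column `gene_id`, then one 0/1 column per species (header carries
#' the species names).
#'
#' @param file Path to the TSV.
#' @return An `orthology_table`.
#' @export
read_orthology <- function(file) {
  df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1
  rownames(m) <- df[[1]]
  orthology_table(m)
}

#' Write an orthology table to TSV
#' @param orth An `orthology_table`.
#' @param file Output path.
#' @return Invisibly, `orth`.
#' @export
write_orthology <- function(orth, file) {
  df <- data.frame(gene_id = rownames(orth),
                   apply(unclass(orth), 2L, as.integer),
                   check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(orth)
}

#' Classify genes as evolutionarily conserved
#'
#' A gene is conserved iff it is present in at least `ceiling(f * S)` of the
#' `S` panel species. Genes queried but absent from the table count as
#' present in no species.
#'
#' @param orth An `orthology_table`.
#' @param f Conservation cutoff fraction (default 0.7).
#' @param genes Optional gene universe (default: rows of `orth`).
#' @return Object of class `conservation_labels`: data frame with columns
#'   `entity`, `n_species`, `conserved`; attributes `entity_type = "gene"`,
#'   `k_min`, `f`, `n_panel`.
#' @export
classify_genes <- function(orth, f = 0.7, genes = NULL) {
  stopifnot(inherits(orth, "orthology_table"))
  S <- ncol(orth)
  k_min <- conservation_k_min(f, S)
  if (is.null(genes)) genes <- rownames(orth)
  counts <- integer(length(genes))
  hit <- genes %in% rownames(orth)
  counts[hit] <- rowSums(unclass(orth)[genes[hit], , drop = FALSE])
  out <- data.frame(entity = genes, n_species = counts,
                    conserved = counts >= k_min)
  structure(out, class = c("conservation_labels", "data.frame"),
            entity_type = "gene", k_min = k_min, f = f, n_panel = S)
}

#' Construct a per-species interaction catalog
#'
#' @param catalog Named list (names = species); each element a data frame
#'   with columns `gene_a`, `gene_b` giving the interacting pairs of that
#'   species mapped into the reference gene-id space. Self-pairs are
#'   dropped.
#' @return Object of class `species_edge_catalog`: named list of character
#'   vectors of unordered pair keys.
#' @export
species_edge_catalog <- function(catalog) {
  if (is.null(names(catalog)) || any(names(catalog) == "")) {
    stop("catalog must be a named list (species names)")
  }
  keys <- lapply(catalog, function(d) {
    if (is.character(d)) return(unique(d))
    a <- as.character(d$gene_a); b <- as.character(d$gene_b)
    keep <- a != b
    unique(pair_key(a[keep], b[keep]))
  })
  structure(keys, class = "species_edge_catalog")
}

#' Read a species edge catalog from a long-format TSV
#'
#' Columns `species`, `gene_a`, `gene_b`.
#'
#' @param file Path to the TSV.
#' @return A `species_edge_catalog`.
#' @export
read_species_catalog <- function(file) {
  df <- read.delim(file, comment.char = "#", colClasses = "character",
                   stringsAsFactors = FALSE)
  species_edge_catalog(split(df[, c("gene_a", "gene_b")], df$species))
}

#' Write a species edge catalog to a long-format TSV
#' @param cat A `species_edge_catalog`.
#' @param file Output path.
#' @return Invisibly, `cat`.
#' @export
write_species_catalog <- function(cat, file) {
  rows <- lapply(names(cat), function(s) {
    parts <- strsplit(cat[[s]], "|", fixed = TRUE)
    data.frame(species = s,
               gene_a = vapply(parts, `[`, "", 1L),
               gene_b = vapply(parts, `[`, "", 2L))
  })
  write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(cat)
}

#' Classify interactions as evolutionarily conserved
#'
#' Per network edge, the presence set is the set of species whose catalog
#' contains the unordered endpoint pair; the edge is conserved iff that set
#' reaches `ceiling(f * S)` species.
#'
#' @param net An `interaction_network`.
#' @param catalog A `species_edge_catalog`.
#' @param f Conservation cutoff fraction (default 0.7).
#' @return A `conservation_labels` data frame with one row per edge of
#'   `net`: columns `entity` (pair key), `n_species`, `conserved`, and a
#'   list column `species` with the presence set; attribute
#'   `entity_type = "edge"`.
#' @export
classify_edges <- function(net, catalog, f = 0.7) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(catalog, "species_edge_catalog"))
  S <- length(catalog)
  k_min <- conservation_k_min(f, S)
  keys <- pair_key(net$edges$source, net$edges$target)
  present <- vapply(catalog, function(sp_keys) keys %in% sp_keys,
                    logical(length(keys)))
  if (length(keys) == 1L) present <- matrix(present, nrow = 1L)
  if (length(keys) == 0L) present <- matrix(logical(), 0L, S)
  counts <- as.integer(rowSums(present))
  sp_sets <- apply(present, 1L, function(row) names(catalog)[row],
                   simplify = FALSE)
  out <- data.frame(entity = keys, n_species = counts,
                    conserved = counts >= k_min)
  out$species <- sp_sets
  structure(out, class = c("conservation_labels", "data.frame"),
            entity_type = "edge", k_min = k_min, f = f, n_panel = S)
}

#' One-sided Fisher exact test on a 2x2 table
#'
#' Hypergeometric one-sided p-value for over-representation of conserved
#' entities in the MH row (alternative "greater").
#'
#' @param a MH conserved count.
#' @param b MH non-conserved count.
#' @param c_ Other conserved count.
#' @param d Other non-conserved count.
#' @return Object of class `enrichment_result`: list with `table` (2x2
#'   matrix), `odds_ratio` (sample odds ratio a*d / (b*c)), `p_value`,
#'   `alternative = "greater"`, `degenerate` (TRUE when a table margin is
#'   zero, in which case p = 1).
#' @export
#' @examples
#' fisher_exact_one_sided(398, 165, 11170, 6533)$p_value  # ~1e-4
fisher_exact_one_sided <- function(a, b, c_, d) {
  counts <- c(a, b, c_, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  tab <- matrix(as.numeric(counts), nrow = 2L, byrow = TRUE,
                dimnames = list(c("MH", "other"),
                                c("conserved", "non-conserved")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else {
    fisher.test(tab, alternative = "greater")$p.value
  }
  odds <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, odds_ratio = odds, p_value = p,
                 alternative = "greater", degenerate = degenerate),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  cat("odds ratio:", signif(x$odds_ratio, 4),
      " one-sided p:", signif(x$p_value, 4),
      if (x$degenerate) " [degenerate margin]" else "", "\n")
  invisible(x)
}

#' Conservation enrichment of MH entities
#'
#' Builds the 2x2 table (MH / other) x (conserved / non-conserved) and
#' delegates to [fisher_exact_one_sided()].
#'
#' @param labels A `conservation_labels` data frame.
#' @param mh Logical vector aligned with the rows of `labels` (for edges:
#'   TRUE iff at least one endpoint is an MH gene, see [mh_edge_flags()]).
#' @return An `enrichment_result`.
#' @export
conservation_enrichment <- function(labels, mh) {
  stopifnot(inherits(labels, "conservation_labels"),
            length(mh) == nrow(labels))
  mh <- as.logical(mh)
  fisher_exact_one_sided(sum(mh & labels$conserved),
                         sum(mh & !labels$conserved),
                         sum(!mh & labels$conserved),
                         sum(!mh & !labels$conserved))
}

#' Conserved subnetwork
#'
#' Retains only the conserved edges and their incident nodes. The per-edge
#' species presence sets are carried along in the edge table (`species` list
#' column and `n_species`), as needed by motif conservation analysis.
#'
#' @param net An `interaction_network`.
#' @param labels Edge-level `conservation_labels` aligned with `net$edges`.
#' @return An `interaction_network`.
#' @export
conserved_subnetwork <- function(net, labels) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(labels, "conservation_labels"),
            attr(labels, "entity_type") == "edge",
            nrow(labels) == nrow(net$edges))
  keep <- labels$conserved
  edges <- net$edges[keep, , drop = FALSE]
  edges$n_species <- labels$n_species[keep]
  edges$species <- labels$species[keep]
  ids <- unique(c(edges$source, edges$target))
  nodes <- net$nodes[net$nodes$gene_id %in% ids, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 name = paste0(net$name, " (conserved)")),
            class = "interaction_network")
}

#' Per-category Fisher enrichment of a gene set
#'
#' One-sided Fisher exact test per category against a background universe,
#' with Benjamini-Hochberg adjusted q-values reported alongside the raw
#' p-values (the raw p-values are primary).
#'
#' @param members Gene set of interest (must be a subset of `background`).
#' @param categories Named list of gene sets (e.g. pathways or pathway
#'   classes).
#' @param background Universe gene set.
#' @return Data frame with one row per category: `category`, `n_overlap`,
#'   `n_members`, `n_category`, `odds_ratio`, `p_value`, `q_value`.
#' @export
set_enrichment <- function(members, categories, background) {
  members <- unique(members)
  background <- unique(background)
  if (!all(members %in% background)) {
    stop("members must be a subset of the background universe")
  }
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(categories[[nm]]), background)
    a <- length(intersect(members, cat_genes))
    b <- length(members) - a
    c_ <- length(cat_genes) - a
    d <- length(background) - a - b - c_
    res <- fisher_exact_one_sided(a, b, c_, d)
    data.frame(category = nm, n_overlap = a, n_members = length(members),
               n_category = length(cat_genes), odds_ratio = res$odds_ratio,
               p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), , drop = FALSE]
}
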