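# Signed, typed molecular interaction networks.
#
# The central container mirrors a KEGG-style molecular interaction network
# (MIN): an edge list of typed interactions (activation, inhibition, binding,
# ...) over opaque gene identifiers, with a per-node flag marking "mitotic
# hit" (MH) genes, i.e. genes whose silencing perturbed mitosis in the
# genome-wide RNAi screen the annotation derives from.

#' Closed vocabulary of interaction types and their regulatory signs
#'
#' Positive regulatory types (activation, expression, positive indirect
#' effect) carry sign +1, negative types (inhibition, repression, negative
#' indirect effect) carry sign -1, and everything else (binding and
#' unclassified types) is unsigned (0).
#'
#' @return Named integer vector mapping interaction type to sign.
#' @export
#' @examples
#' interaction_signs()[["activation"]]
interaction_signs <- function() {
  c(activation = 1L, expression = 1L, `indirect-effect-positive` = 1L,
    inhibition = -1L, repression = -1L, `indirect-effect-negative` = -1L,
    binding = 0L, other = 0L)
}

#' Construct a signed interaction network
#'
#' Builds an `interaction_network` from an edge table and (optionally) a node
#' annotation table. Interaction types outside the closed vocabulary are
#' mapped to `"other"` (sign 0). Duplicate (source, target, type) triples are
#' collapsed. Edge endpoints missing from the annotation are auto-created as
#' non-MH nodes.
#'
#' @param edges Data frame with columns `source`, `target`, `type`,
#'   `directed` (logical). Extra columns are preserved.
#' @param nodes Optional data frame with columns `gene_id`, `is_mh`.
#' @param name Label for the network.
#' @param quiet Suppress the warning about auto-created nodes.
#' @return An object of class `interaction_network`: a list with elements
#'   `nodes` (data frame `gene_id`, `is_mh`), `edges` (data frame `source`,
#'   `target`, `type`, `sign`, `directed`), and `name`.
#' @export
#' @examples
#' net <- interaction_network(data.frame(
#'   source = "a", target = "b", type = "activation", directed = TRUE))
#' net$edges$sign
interaction_network <- function(edges, nodes = NULL, name = "network",
                                quiet = FALSE) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), directed = logical())
  }
  required <- c("source", "target", "type", "directed")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0L) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$type <- as.character(edges$type)
  edges$directed <- as.logical(edges$directed)
  if (anyNA(edges$source) || anyNA(edges$target) || anyNA(edges$directed)) {
    bad <- which(is.na(edges$source) | is.na(edges$target) |
                   is.na(edges$directed))
    stop("malformed edge row(s): ", paste(bad, collapse = ", "))
  }
  vocab <- interaction_signs()
  edges$type[!edges$type %in% names(vocab)] <- "other"
  edges$sign <- unname(vocab[edges$type])
  # de-duplicate on the (source, target, type) triple
  key <- paste(edges$source, edges$target, edges$type, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL

  if (is.null(nodes)) {
    nodes <- data.frame(gene_id = character(), is_mh = logical())
  }
  if (!all(c("gene_id", "is_mh") %in% names(nodes))) {
    stop("annotation table must have columns gene_id and is_mh")
  }
  nodes <- data.frame(gene_id = as.character(nodes$gene_id),
                      is_mh = as.logical(nodes$is_mh))
  nodes <- nodes[!duplicated(nodes$gene_id), , drop = FALSE]
  endpoint_ids <- unique(c(edges$source, edges$target))
  unknown <- setdiff(endpoint_ids, nodes$gene_id)
  if (length(unknown) > 0L) {
    if (!quiet) {
      warning(length(unknown),
              " edge endpoint(s) absent from annotation; added as non-MH")
    }
    nodes <- rbind(nodes, data.frame(gene_id = unknown, is_mh = FALSE))
  }
  nodes <- nodes[order(nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "interaction_network")
}

#' Read a network from edge-list and annotation files
#'
#' The edge list is tab-separated with columns `source`, `target`, `type`,
#' `directed` (0/1 or TRUE/FALSE); lines starting with `#` are comments. The
#' annotation file is tab-separated with columns `gene_id`, `is_mh` (0/1).
#'
#' @param edge_file Path to the edge-list TSV.
#' @param annotation_file Optional path to the node annotation TSV.
#' @param name Network label (defaults to the edge file name).
#' @return An [interaction_network()].
#' @export
read_network <- function(edge_file, annotation_file = NULL, name = NULL) {
  edges <- read.delim(edge_file, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    dirs <- parse_flag(edges$directed)
    if (anyNA(dirs)) {
      stop("malformed 'directed' value at data line(s): ",
           paste(which(is.na(dirs)), collapse = ", "), " of ", edge_file)
    }
    edges$directed <- dirs
  } else {
    edges$directed <- logical()
  }
  nodes <- NULL
  if (!is.null(annotation_file)) {
    ann <- read.delim(annotation_file, comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE)
    flags <- parse_flag(ann$is_mh)
    if (anyNA(flags)) {
      stop("malformed 'is_mh' value at data line(s): ",
           paste(which(is.na(flags)), collapse = ", "), " of ",
           annotation_file)
    }
    nodes <- data.frame(gene_id = ann$gene_id, is_mh = flags)
  }
  if (is.null(name)) name <- basename(edge_file)
  interaction_network(edges, nodes, name = name)
}

parse_flag <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t")] <- TRUE
  out[x %in% c("0", "false", "f")] <- FALSE
  out
}

#' Write a network to edge-list and annotation files
#'
#' Inverse of [read_network()]: a read-write-read round trip reproduces the
#' network.
#'
#' @param net An `interaction_network`.
#' @param edge_file,annotation_file Output paths.
#' @return Invisibly, `net`.
#' @export
write_network <- function(net, edge_file, annotation_file = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  out <- net$edges[, c("source", "target", "type", "directed")]
  out$directed <- as.integer(out$directed)
  write.table(out, edge_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_file)) {
    ann <- data.frame(gene_id = net$nodes$gene_id,
                      is_mh = as.integer(net$nodes$is_mh))
    write.table(ann, annotation_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(net)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network:", x$name, "\n")
  cat("  nodes:", nrow(x$nodes), " (MH:", sum(x$nodes$is_mh), ")\n")
  cat("  edges:", nrow(x$edges),
      " (signed:", sum(x$edges$sign != 0L), ")\n")
  invisible(x)
}

#' Convert a network to an igraph object
#'
#' In `"undirected"` mode every edge becomes an undirected edge (the
#' undirected projection used for path lengths, components and clustering
#' coefficients). In `"directed"` mode undirected edges are expanded into
#' both directions.
#'
#' @param net An `interaction_network`.
#' @param mode `"undirected"` or `"directed"`.
#' @return An igraph graph whose vertex names are gene ids; in undirected
#'   mode edge i corresponds to edge row i of `net$edges`.
#' @export
as_igraph <- function(net, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "interaction_network"))
  el <- net$edges[, c("source", "target")]
  if (mode == "directed") {
    undir <- !net$edges$directed
    if (any(undir)) {
      el <- rbind(el, data.frame(source = net$edges$target[undir],
                                 target = net$edges$source[undir]))
    }
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = net$nodes$gene_id)
  } else {
    g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = net$nodes$gene_id)
  }
  g
}

#' Regulatory subnetwork
#'
#' Retains only signed edges (activation-, expression- and positive-indirect
#' types, and their negative counterparts), makes them all directed, and
#' drops nodes left without any edge. MH flags are preserved. This is the
#' "regulatory MIN" filter applied to a mixed functional/physical network.
#'
#' @param net An `interaction_network`.
#' @return An `interaction_network` containing only regulatory edges.
#' @export
to_regulatory <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  edges <- net$edges[net$edges$sign != 0L, , drop = FALSE]
  edges$directed <- rep(TRUE, nrow(edges))
  keep <- unique(c(edges$source, edges$target))
  nodes <- net$nodes[net$nodes$gene_id %in% keep, , drop = FALSE]
  rownames(edges) <- rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 name = paste0(net$name, " (regulatory)")),
            class = "interaction_network")
}

#' Shortest-path distance matrix between target genes
#'
#' Breadth-first (unit-weight) distances on the undirected projection by
#' default; unreachable pairs are `Inf`. Direction-respecting distances are
#' available via `directed = TRUE`.
#'
#' @param net An `interaction_network`.
#' @param targets Character vector of gene ids (default: all MH genes).
#' @param directed Respect edge direction (default `FALSE`).
#' @return Symmetric (for `directed = FALSE`) numeric matrix with zero
#'   diagonal, dimnames = targets.
#' @export
shortest_path_distances <- function(net, targets = NULL, directed = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  if (is.null(targets)) targets <- net$nodes$gene_id[net$nodes$is_mh]
  missing_t <- setdiff(targets, net$nodes$gene_id)
  if (length(missing_t) > 0L) {
    stop("target gene(s) not in network: ", paste(missing_t, collapse = ", "))
  }
  g <- as_igraph(net, mode = if (directed) "directed" else "undirected")
  d <- igraph::distances(g, v = targets, to = targets,
                         mode = if (directed) "out" else "all")
  d[targets, targets, drop = FALSE]
}

#' Giant component size
#'
#' Node count of the largest (weakly) connected component of the undirected
#' projection; 0 for an empty network.
#'
#' @param net An `interaction_network`.
#' @return Integer count.
#' @export
giant_component_size <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$nodes) == 0L) return(0L)
  comp <- igraph::components(as_igraph(net, "undirected"))
  as.integer(max(comp$csize))
}

#' Local clustering coefficients
#'
#' Watts-Strogatz local clustering coefficient of every node on the simple
#' undirected projection (self-loops and parallel edges removed). Nodes with
#' degree < 2 get coefficient 0.
#'
#' @param net An `interaction_network`.
#' @return Named numeric vector in \[0, 1\].
#' @export
local_clustering <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$nodes) == 0L) return(setNames(numeric(), character()))
  g <- igraph::simplify(as_igraph(net, "undirected"))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  setNames(cc, igraph::V(g)$name)
}

#' Label edges as MH or non-MH
#'
#' An interaction is an MH interaction iff at least one endpoint is an MH
#' gene.
#'
#' @param net An `interaction_network`.
#' @return Character vector (`"MH"` / `"non-MH"`), one entry per edge row.
#' @export
mh_edge_labels <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  mh <- setNames(net$nodes$is_mh, net$nodes$gene_id)
  ifelse(mh[net$edges$source] | mh[net$edges$target], "MH", "non-MH")
}

#' Logical MH flag per edge
#' @param net An `interaction_network`.
#' @return Logical vector, one entry per edge row.
#' @export
mh_edge_flags <- function(net) {
  mh_edge_labels(net) == "MH"
}

#' Export a network to GraphML
#'
#' @param net An `interaction_network`.
#' @param file Output path.
#' @return Invisibly, `net`.
#' @export
write_graphml <- function(net, file) {
  g <- as_igraph(net, "directed")
  igraph::V(g)$is_mh <- net$nodes$is_mh[match(igraph::V(g)$name,
                                              net$nodes$gene_id)]
  igraph::write_graph(g, file, format = "graphml")
  invisible(net)
}

#' Unordered endpoint-pair key
#'
#' Canonical `"min|max"` key of an unordered gene pair, used wherever
#' conservation and interaction removal are pair-level.
#'
#' @param a,b Character vectors of gene ids (recycled together).
#' @return Character vector of pair keys.
#' @export
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}
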