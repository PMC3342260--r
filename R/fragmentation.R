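# Network fragmentation: giant-component degradation after targeted removal
# of MH genes or MH interactions, compared to a resampling null in which the
# same number of randomly chosen genes/interactions is removed. Significance
# of the decrease is a one-sided Z-test against the resampled mean and sd.

#' Giant component size after targeted removal
#'
#' Removes either a set of nodes (with their incident edges) or a set of
#' interactions (all parallel edges between each unordered endpoint pair)
#' and returns the resulting giant component size.
#'
#' @param net An `interaction_network`.
#' @param nodes Character vector of gene ids to remove.
#' @param edges Data frame with columns `source`, `target` (unordered pairs)
#'   to remove, or a character vector of pair keys.
#' @return Integer giant component size.
#' @export
targeted_removal_gcs <- function(net, nodes = NULL, edges = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (!is.null(nodes)) {
    unknown <- setdiff(nodes, net$nodes$gene_id)
    if (length(unknown) > 0L) {
      stop("unknown node(s): ", paste(unknown, collapse = ", "))
    }
  }
  keys <- pair_key(net$edges$source, net$edges$target)
  if (!is.null(edges)) {
    want <- if (is.character(edges)) edges else
      pair_key(as.character(edges$source), as.character(edges$target))
    unknown <- setdiff(want, keys)
    if (length(unknown) > 0L) {
      stop("unknown interaction(s): ", paste(unknown, collapse = ", "))
    }
  }
  keep_edges <- rep(TRUE, nrow(net$edges))
  if (!is.null(edges)) keep_edges <- !(keys %in% want)
  keep_nodes <- rep(TRUE, nrow(net$nodes))
  if (!is.null(nodes)) {
    keep_nodes <- !(net$nodes$gene_id %in% nodes)
    keep_edges <- keep_edges & !(net$edges$source %in% nodes) &
      !(net$edges$target %in% nodes)
  }
  sub <- structure(list(nodes = net$nodes[keep_nodes, , drop = FALSE],
                        edges = net$edges[keep_edges, , drop = FALSE],
                        name = net$name),
                   class = "interaction_network")
  giant_component_size(sub)
}

#' Resampling null for random removals
#'
#' Repeatedly removes `k` uniformly chosen entities (nodes, or distinct
#' unordered interactions) without replacement from the whole network and
#' records the giant component size. Reproducible under `seed`.
#'
#' @param net An `interaction_network`.
#' @param k Number of entities removed per draw.
#' @param mode `"nodes"` or `"edges"`.
#' @param reps Number of draws (default 5000).
#' @param seed Optional integer seed.
#' @return List with `mean`, `sd` (sample sd, n-1 denominator) and `samples`
#'   (integer vector of length `reps`).
#' @export
random_removal_null <- function(net, k, mode = c("nodes", "edges"),
                                reps = 5000L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "interaction_network"))
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net, "undirected")
  if (mode == "nodes") {
    pool <- net$nodes$gene_id
  } else {
    # distinct unordered interactions; removing one removes all its
    # parallel typed edges
    all_keys <- pair_key(net$edges$source, net$edges$target)
    pool <- unique(all_keys)
  }
  if (k > length(pool)) {
    stop("cannot remove ", k, " ", mode, " from a pool of ", length(pool))
  }
  if (k == 0L) {
    gcs0 <- giant_component_size(net)
    return(list(mean = gcs0, sd = 0, samples = rep(gcs0, reps)))
  }
  samples <- integer(reps)
  for (r in seq_len(reps)) {
    drawn <- sample(pool, k)
    h <- if (mode == "nodes") {
      igraph::delete_vertices(g, drawn)
    } else {
      igraph::delete_edges(g, which(all_keys %in% drawn))
    }
    comp <- igraph::components(h)
    samples[r] <- if (comp$no == 0L) 0L else as.integer(max(comp$csize))
  }
  list(mean = mean(samples), sd = sd(samples), samples = samples)
}

#' One-sided Z-test for a giant-component decrease
#'
#' `z = (observed - null_mean) / null_sd`; the p-value is the standard
#' normal CDF at `z` (alternative: observed smaller than the null).
#'
#' @param observed Observed giant component size.
#' @param null_mean,null_sd Mean and sd of the resampling null.
#' @return List with `z`, `p_value` and `degenerate` (TRUE when
#'   `null_sd = 0`, in which case p is 0 or 1 by direct comparison).
#' @export
#' @examples
#' z_test_decrease(1383, 1388.3, 13.95)$p_value  # ~0.35
z_test_decrease <- function(observed, null_mean, null_sd) {
  if (null_sd < 0) stop("null_sd must be non-negative")
  if (null_sd == 0) {
    return(list(z = NA_real_,
                p_value = if (observed < null_mean) 0 else 1,
                degenerate = TRUE))
  }
  z <- (observed - null_mean) / null_sd
  list(z = z, p_value = pnorm(z), degenerate = FALSE)
}

#' Full fragmentation analysis for one removal mode
#'
#' Removes the complete target set (typically the conserved MH genes or MH
#' interactions), builds the matched random-removal null, and tests the
#' decrease.
#'
#' @param net An `interaction_network` (typically a conserved subnetwork).
#' @param mode `"nodes"` or `"edges"`.
#' @param targets For `"nodes"`: gene ids (default: all MH genes). For
#'   `"edges"`: pair keys or a `source`/`target` data frame (default: all
#'   distinct MH interactions).
#' @param reps Null draws (default 5000).
#' @param seed Optional integer seed.
#' @return One-row data frame: `mode`, `n_removed`, `initial_size`,
#'   `observed_gcs`, `null_mean`, `null_sd`, `n_reps`, `z`, `p_value`,
#'   `seed`.
#' @export
fragmentation_analysis <- function(net, mode = c("nodes", "edges"),
                                   targets = NULL, reps = 5000L,
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(targets)) {
    targets <- if (mode == "nodes") {
      net$nodes$gene_id[net$nodes$is_mh]
    } else {
      unique(pair_key(net$edges$source, net$edges$target)[mh_edge_flags(net)])
    }
  }
  if (mode == "edges" && !is.character(targets)) {
    targets <- unique(pair_key(as.character(targets$source),
                               as.character(targets$target)))
  }
  observed <- if (mode == "nodes") {
    targeted_removal_gcs(net, nodes = targets)
  } else {
    targeted_removal_gcs(net, edges = targets)
  }
  null <- random_removal_null(net, k = length(targets), mode = mode,
                              reps = reps, seed = seed)
  zt <- z_test_decrease(observed, null$mean, null$sd)
  data.frame(mode = mode, n_removed = length(targets),
             initial_size = nrow(net$nodes),
             observed_gcs = observed, null_mean = null$mean,
             null_sd = null$sd, n_reps = reps, z = zt$z,
             p_value = zt$p_value,
             seed = if (is.null(seed)) NA_integer_ else seed)
}
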