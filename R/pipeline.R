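# End-to-end orchestration: network build -> regulatory filter ->
# phenotype/network distance analysis -> conservation enrichment per cutoff
# -> conserved subnetworks -> fragmentation -> motif census, significance,
# bistability, conservation and cluster analysis, with one tabular report
# per analysis stage and a machine-readable run log.

#' Pipeline configuration
#'
#' Exactly one of `input_dir` (a directory of input files as written by
#' [write_dataset()]) or `spec` (a [synthetic_spec()]) must be given.
#'
#' @param input_dir Directory with `edges.tsv`, `annotation.tsv`,
#'   `orthology.tsv`, `species_catalog.tsv`, `phenoprints.csv`.
#' @param spec A `synthetic_spec` to generate the inputs instead.
#' @param cutoffs Conservation cutoffs to report enrichment at.
#' @param primary_cutoff Cutoff used for conserved subnetworks,
#'   fragmentation and motif conservation (default 0.7).
#' @param frag_reps Resampling draws for the fragmentation null (default
#'   5000).
#' @param motif_k Motif sizes to census (subset of `c(3, 4)`).
#' @param n_random Randomized networks for motif significance (default
#'   1000).
#' @param z_min,p_max Motif significance cutoffs (defaults 2 and 0.05).
#' @param motif_k_min Minimum common species count for motif conservation
#'   (default 7).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer master seed for all stage seeds.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(input_dir = NULL, spec = NULL,
                            cutoffs = c(0.6, 0.7, 0.8),
                            primary_cutoff = 0.7, frag_reps = 5000L,
                            motif_k = c(3L, 4L), n_random = 1000L,
                            z_min = 2, p_max = 0.05, motif_k_min = 7L,
                            out_dir = NULL, seed = 1L) {
  if (is.null(input_dir) == is.null(spec)) {
    stop("exactly one of input_dir or spec must be given")
  }
  if (any(cutoffs <= 0 | cutoffs > 1) || primary_cutoff <= 0 ||
      primary_cutoff > 1) {
    stop("conservation cutoffs must be in (0, 1]")
  }
  if (!all(motif_k %in% c(3L, 4L))) stop("motif_k must be a subset of {3, 4}")
  if (is.null(out_dir)) stop("out_dir is required")
  structure(list(input_dir = input_dir, spec = spec, cutoffs = cutoffs,
                 primary_cutoff = primary_cutoff,
                 frag_reps = as.integer(frag_reps),
                 motif_k = as.integer(motif_k),
                 n_random = as.integer(n_random), z_min = z_min,
                 p_max = p_max, motif_k_min = as.integer(motif_k_min),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

read_input_dir <- function(dir) {
  list(network = read_network(file.path(dir, "edges.tsv"),
                              file.path(dir, "annotation.tsv")),
       orthology = read_orthology(file.path(dir, "orthology.tsv")),
       catalog = read_species_catalog(file.path(dir, "species_catalog.tsv")),
       phenoprints = read_phenoprints(file.path(dir, "phenoprints.csv")),
       planted = NULL)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes all stages on the configured inputs and writes one report table
#' per stage into `config$out_dir`, plus a JSON run log recording seeds,
#' parameters and the contingency tables behind every reported p-value.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the report bundle: a list with the networks, stage
#'   results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  data <- if (!is.null(config$spec)) generate_dataset(config$spec) else
    read_input_dir(config$input_dir)
  net <- data$network
  reg <- to_regulatory(net)
  bundle <- list(config = config, network = net, regulatory = reg)
  log <- list(seed = config$seed,
              parameters = config[setdiff(names(config),
                                          c("spec", "input_dir"))],
              package_version = as.character(utils::packageVersion("mitonet")),
              contingency_tables = list())

  ## phenotype vs network distance
  mh_genes <- intersect(net$nodes$gene_id[net$nodes$is_mh],
                        names(data$phenoprints))
  if (length(mh_genes) >= 3L) {
    net_d <- shortest_path_distances(net, targets = mh_genes)
    phen_d <- phenotype_distance_matrix(data$phenoprints, mh_genes)
    sliding <- sliding_threshold_analysis(net_d, phen_d)
    write_tsv(sliding, file.path(config$out_dir, "sliding_threshold.tsv"))
    trees <- tryCatch(suppressWarnings(mirrored_trees(net_d, phen_d)),
                      error = function(e) NULL)
    if (!is.null(trees)) {
      write_mirrored_trees(trees,
                           file.path(config$out_dir, "tree_network.nwk"),
                           file.path(config$out_dir, "tree_phenotype.nwk"))
    }
    bundle$sliding <- sliding
    bundle$trees <- trees
  }

  ## conservation enrichment at every cutoff
  gene_universe <- net$nodes$gene_id
  mh_gene_flag <- net$nodes$is_mh
  cons_rows <- list()
  for (f in config$cutoffs) {
    glab <- classify_genes(data$orthology, f = f, genes = gene_universe)
    scopes <- list(genes_network = list(labels = glab, mh = mh_gene_flag),
                   edges_network = list(
                     labels = classify_edges(net, data$catalog, f = f),
                     mh = mh_edge_flags(net)),
                   edges_regulatory = list(
                     labels = classify_edges(reg, data$catalog, f = f),
                     mh = mh_edge_flags(reg)))
    for (sc in names(scopes)) {
      res <- conservation_enrichment(scopes[[sc]]$labels, scopes[[sc]]$mh)
      tab <- res$table
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        cutoff = f, scope = sc,
        mh_conserved = tab[1, 1], mh_nonconserved = tab[1, 2],
        other_conserved = tab[2, 1], other_nonconserved = tab[2, 2],
        odds_ratio = res$odds_ratio, p_value = res$p_value)
    }
  }
  conservation <- do.call(rbind, cons_rows)
  write_tsv(conservation,
            file.path(config$out_dir, "conservation_enrichment.tsv"))
  log$contingency_tables$conservation <- conservation
  bundle$conservation <- conservation

  ## conserved subnetworks at the primary cutoff
  f0 <- config$primary_cutoff
  net_elab <- classify_edges(net, data$catalog, f = f0)
  reg_elab <- classify_edges(reg, data$catalog, f = f0)
  cons_net <- conserved_subnetwork(net, net_elab)
  cons_reg <- conserved_subnetwork(reg, reg_elab)
  bundle$conserved_network <- cons_net
  bundle$conserved_regulatory <- cons_reg

  ## fragmentation
  frag_rows <- list()
  frag_nets <- list(network = cons_net, regulatory = cons_reg)
  i <- 0L
  for (nm in names(frag_nets)) {
    for (mode in c("nodes", "edges")) {
      i <- i + 1L
      row <- fragmentation_analysis(frag_nets[[nm]], mode = mode,
                                    reps = config$frag_reps,
                                    seed = config$seed + 100L + i)
      row <- cbind(data.frame(network = nm), row)
      frag_rows[[i]] <- row
    }
  }
  fragmentation <- do.call(rbind, frag_rows)
  write_tsv(fragmentation, file.path(config$out_dir, "fragmentation.tsv"))
  bundle$fragmentation <- fragmentation

  ## motifs: significance on the full regulatory network, conservation after
  motif_class_rows <- list()
  inst_all <- list()
  for (k in config$motif_k) {
    sig <- motif_significance(reg, k, n_random = config$n_random,
                              z_min = config$z_min, p_max = config$p_max,
                              seed = config$seed + 200L + k)
    sig$bistable <- vapply(sig$class_label, is_bistable, logical(1))
    sig$positive_circuit <- vapply(sig$class_label, has_positive_circuit,
                                   logical(1))
    motif_class_rows[[length(motif_class_rows) + 1L]] <- sig
    inst <- enumerate_connected_subgraphs(reg, k)
    inst <- annotate_motif_instances(inst, reg, edge_labels = reg_elab,
                                     k_min = config$motif_k_min)
    inst_all[[length(inst_all) + 1L]] <- inst
  }
  motif_classes <- do.call(rbind, motif_class_rows)
  write_tsv(motif_classes, file.path(config$out_dir, "motif_classes.tsv"))
  instances <- do.call(rbind, inst_all)
  inst_out <- data.frame(
    class_label = instances$class_label,
    nodes = vapply(instances$nodes, paste, "", collapse = ","),
    is_mh = instances$is_mh, conserved = instances$conserved,
    n_species_common = instances$n_species_common,
    bistable = instances$bistable)
  write_tsv(inst_out, file.path(config$out_dir, "motif_instances.tsv"))
  bundle$motif_classes <- motif_classes
  bundle$motif_instances <- instances

  ## conserved bistable motifs: summary, MH enrichment, cluster statistics
  cb <- instances[!is.na(instances$bistable) & instances$bistable &
                    instances$conserved, , drop = FALSE]
  summary_rows <- lapply(config$motif_k, function(k) {
    sub <- cb[vapply(cb$nodes, length, 1L) == k, , drop = FALSE]
    data.frame(
      k = k,
      mh_instances = sum(sub$is_mh),
      non_mh_instances = sum(!sub$is_mh),
      mh_genes = length(unique(unlist(sub$nodes[sub$is_mh]))),
      non_mh_genes = length(unique(unlist(sub$nodes[!sub$is_mh]))))
  })
  bistable_summary <- do.call(rbind, summary_rows)
  write_tsv(bistable_summary,
            file.path(config$out_dir, "bistable_summary.tsv"))
  bundle$bistable_summary <- bistable_summary

  enr <- motif_gene_enrichment(cb, reg, universe = cons_reg$nodes$gene_id)
  bundle$motif_mh_enrichment <- enr
  log$contingency_tables$motif_mh_enrichment <- as.data.frame(enr$table)
  cluster <- tryCatch(motif_cluster_analysis(cb, cons_reg),
                      error = function(e) list(p_value = NA_real_,
                                               note = conditionMessage(e)))
  bundle$motif_cluster <- cluster
  summary_json <- list(
    network = list(nodes = nrow(net$nodes), edges = nrow(net$edges),
                   mh_genes = sum(net$nodes$is_mh)),
    regulatory = list(nodes = nrow(reg$nodes), edges = nrow(reg$edges)),
    conserved_network = list(nodes = nrow(cons_net$nodes),
                             edges = nrow(cons_net$edges)),
    conserved_regulatory = list(nodes = nrow(cons_reg$nodes),
                                edges = nrow(cons_reg$edges)),
    motif_mh_enrichment_p = enr$p_value,
    motif_cluster_p = cluster$p_value)
  jsonlite::write_json(summary_json,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  bundle$paths <- list.files(config$out_dir, full.names = TRUE)
  invisible(bundle)
}
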