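#' Assemble the inner/outer-circle gene regulatory network
#'
#' Builds one edge per (regulator, target gene) from the binding-region
#' tables: SOX9 -> g for every gene with a SOX9 binding region (SBR),
#' GLI1/GLI3 -> g for every gene with a GLI binding region (GBR).  Edge
#' evidence is upgraded from SBR/GBR to SGBR for genes carrying a linked
#' binding region; edge attributes (region class, TSS distance) come from
#' the regulator's binding region nearest the TSS.  Each target gets a
#' ring attribute: `inner` iff it has an SGBR (joint SOX9+GLI target),
#' `outer` otherwise (singly-targeted).  Node attributes carry the phase
#' cluster, whether the gene is itself a TF, and (when `zone_means` is
#' given) the expression trend across zones used for node colouring.
#'
#' @param degs clustered phasic gene table (`gene_id`, `cluster`); genes
#'   absent from it get cluster NA.
#' @param binding_regions a `binding_regions` table covering all TFs
#'   (rows distinguished by their `tf` column).
#' @param sgbr an `sgbr_table` from [find_sgbr()].
#' @param tf_list character vector of gene ids that encode TFs.
#' @param zone_means optional zone-mean matrix (rownames = gene ids).
#' @return object of class `grn_graph`: list with `nodes`, `edges`
#'   data.frames and `graph`, an [igraph::graph_from_data_frame()] object.
#' @export
assemble_grn <- function(degs, binding_regions, sgbr,
                         tf_list = character(), zone_means = NULL) {
  br <- binding_regions
  sg <- sgbr_genes(sgbr)
  edges <- do.call(rbind, lapply(split(seq_len(nrow(br)),
                                       paste(br$tf, br$gene_id)),
    function(idx) {
      best <- idx[which.min(abs(br$tss_distance[idx]))]
      data.frame(regulator = br$tf[best], target = br$gene_id[best],
                 evidence = if (br$gene_id[best] %in% sg) "SGBR" else
                   if (br$tf[best] == "SOX9") "SBR" else "GBR",
                 region = br$region[best],
                 tss_distance = br$tss_distance[best],
                 stringsAsFactors = FALSE)
    }))
  if (is.null(edges)) {
    edges <- data.frame(regulator = character(), target = character(),
                        evidence = character(), region = character(),
                        tss_distance = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  targets <- unique(edges$target)
  regulators <- unique(edges$regulator)
  node_ids <- union(regulators, targets)
  nodes <- data.frame(
    node = node_ids,
    is_regulator = node_ids %in% regulators,
    is_tf = node_ids %in% c(tf_list, regulators),
    cluster = degs$cluster[match(node_ids, degs$gene_id)],
    ring = ifelse(node_ids %in% sg, "inner",
                  ifelse(node_ids %in% targets, "outer", NA_character_)),
    stringsAsFactors = FALSE)
  if (!is.null(zone_means)) {
    zm <- zone_means[match(node_ids, rownames(zone_means)), ,
                     drop = FALSE]
    colnames(zm) <- paste0("mean_", ZONES)
    nodes <- cbind(nodes, as.data.frame(zm, row.names = NULL))
  }
  graph <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                         vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = graph),
            class = "grn_graph")
}

#' @export
print.grn_graph <- function(x, ...) {
  cat(sprintf("GRN: %d nodes (%d inner, %d outer), %d edges\n",
              nrow(x$nodes),
              sum(x$nodes$ring == "inner", na.rm = TRUE),
              sum(x$nodes$ring == "outer", na.rm = TRUE),
              nrow(x$edges)))
  invisible(x)
}

#' Write a GRN to disk
#'
#' Emits `grn_edges.tsv`, `grn_nodes.tsv` and `grn.graphml`.
#'
#' @param grn a `grn_graph`.
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of written paths.
#' @export
write_grn <- function(grn, dir) {
  stopifnot(inherits(grn, "grn_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(dir, "grn_edges.tsv"),
             nodes = file.path(dir, "grn_nodes.tsv"),
             graphml = file.path(dir, "grn.graphml"))
  write.table(grn$edges, paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(grn$nodes, paths["nodes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(grn$graph, paths["graphml"], format = "graphml")
  invisible(paths)
}
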