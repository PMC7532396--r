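# Coordination-network construction: a coordination is a quadruple
# (enhancer, eRNA, TF, target gene) in which the enhancer and the target
# gene's promoter share a TF-binding motif hit and are linked by a
# chromatin-interaction anchor pair. CTCF mediation is annotated from peak
# occupancy at both loop ends. Degrees count coordination incidences, and
# the network exports to SIF/GraphML with a node-attribute table.

#' Strand-aware promoter regions upstream of gene TSSs
#'
#' For a `+` strand gene the promoter is `[tss - length, tss)`, for a `-`
#' strand gene `[tss + 1, tss + 1 + length)`, truncated at position 0 so
#' regions near a chromosome start can be shorter (but never empty).
#'
#' @param genes Gene table with `gene_id`, `chrom`, `strand`, `tss`.
#' @param length Promoter length in nucleotides (default 2000).
#' @return An interval data.frame whose `id` is the gene id.
#' @export
promoter_region <- function(genes, length = 2000) {
  stopifnot(length >= 1)
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss + 1, pmax(0, genes$tss - length))
  end <- ifelse(minus, genes$tss + 1 + length, genes$tss)
  # a + strand TSS at position 0 has no upstream bases; keep a 1-bp stub
  end <- pmax(end, start + 1)
  out <- data.frame(chrom = genes$chrom, start = start, end = end,
                    id = genes$gene_id, strand = genes$strand,
                    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' TFs with motif hits on both an enhancer and a promoter
#'
#' @param enhancer_hits,promoter_hits Motif-hit tables (`tf_name`,
#'   `region_id`) already keyed to one enhancer and one promoter, or plain
#'   character vectors of TF names.
#' @return Sorted character vector of shared TF names (possibly empty).
#' @export
shared_tfs <- function(enhancer_hits, promoter_hits) {
  tf_of <- function(x) if (is.data.frame(x)) x$tf_name else x
  sort(intersect(unique(tf_of(enhancer_hits)), unique(tf_of(promoter_hits))))
}

#' Is an enhancer-promoter pair supported by an interaction anchor pair?
#'
#' TRUE when some anchor pair has one anchor overlapping the enhancer and
#' the other overlapping the promoter (>= 1 nt each), in either anchor
#' order.
#'
#' @param enhancer,promoter Single-row interval tables.
#' @param pairs Anchor-pair table (see [read_anchor_pairs()]).
#' @return Logical scalar.
#' @export
interaction_supported <- function(enhancer, promoter, pairs) {
  if (is.null(pairs) || !nrow(pairs)) return(FALSE)
  a <- data.frame(chrom = pairs$chrom_a, start = pairs$start_a,
                  end = pairs$end_a, stringsAsFactors = FALSE)
  b <- data.frame(chrom = pairs$chrom_b, start = pairs$start_b,
                  end = pairs$end_b, stringsAsFactors = FALSE)
  ov_ea <- overlap_length(enhancer, a) > 0
  ov_eb <- overlap_length(enhancer, b) > 0
  ov_pa <- overlap_length(promoter, a) > 0
  ov_pb <- overlap_length(promoter, b) > 0
  any((ov_ea & ov_pb) | (ov_eb & ov_pa))
}

#' Build the coordination table
#'
#' For every (eRNA, target gene) pair and every enhancer the eRNA overlaps,
#' emits one coordination per TF that has motif hits on both the enhancer
#' and the gene's promoter, provided the enhancer-promoter link is
#' supported by a chromatin-interaction anchor pair. Deduplicated and
#' deterministically ordered. With `link = "gene_body"` the interaction
#' evidence may land on the gene interval instead of the promoter.
#'
#' @param target_pairs eRNA-target pairs (`probe_id`, `gene_id`; e.g. from
#'   [integrate_with_de_mrna()]).
#' @param calls eRNA call table (see [call_ernas()]) giving each eRNA's
#'   overlapping enhancers.
#' @param catalogue Enhancer catalogue supplying enhancer intervals.
#' @param genes Gene table supplying promoters (and gene bodies).
#' @param enhancer_hits,promoter_hits Motif-hit tables; `region_id` is the
#'   enhancer id / the gene id respectively.
#' @param anchor_pairs Chromatin-interaction anchor pairs.
#' @param promoter_length Promoter length in nucleotides.
#' @param link `"promoter"` (default) or `"gene_body"`: which gene-side
#'   interval the interaction anchor must hit.
#' @return A data.frame with columns `enhancer_id`, `erna_probe_id`,
#'   `tf_name`, `gene_id`, `interaction_supported` (all TRUE),
#'   `ctcf_mediated` (NA until [ctcf_mediated()] is applied).
#' @export
build_coordinations <- function(target_pairs, calls, catalogue, genes,
                                enhancer_hits, promoter_hits, anchor_pairs,
                                promoter_length = 2000,
                                link = c("promoter", "gene_body")) {
  link <- match.arg(link)
  empty <- data.frame(enhancer_id = character(), erna_probe_id = character(),
                      tf_name = character(), gene_id = character(),
                      interaction_supported = logical(),
                      ctcf_mediated = logical(), stringsAsFactors = FALSE)
  if (!nrow(target_pairs)) return(empty)
  promoters <- promoter_region(genes, length = promoter_length)
  gene_side <- if (link == "promoter") promoters else genes
  enh_of <- stats::setNames(strsplit(calls$enhancer_ids, ";", fixed = TRUE),
                            calls$probe_id)
  hits_e <- split(enhancer_hits$tf_name, enhancer_hits$region_id)
  hits_p <- split(promoter_hits$tf_name, promoter_hits$region_id)
  rows <- list()
  for (i in seq_len(nrow(target_pairs))) {
    erna <- target_pairs$probe_id[i]
    gene <- target_pairs$gene_id[i]
    ptf <- hits_p[[gene]]
    gi <- match(gene, gene_side$gene_id)
    if (is.null(ptf) || is.na(gi)) next
    for (enh in enh_of[[erna]]) {
      tfs <- shared_tfs(hits_e[[enh]], ptf)
      if (!length(tfs)) next
      ei <- match(enh, catalogue$id)
      if (is.na(ei)) next
      if (!interaction_supported(catalogue[ei, , drop = FALSE],
                                 gene_side[gi, , drop = FALSE],
                                 anchor_pairs)) next
      rows[[length(rows) + 1]] <- data.frame(
        enhancer_id = enh, erna_probe_id = erna, tf_name = tfs,
        gene_id = gene, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  out$interaction_supported <- TRUE
  out$ctcf_mediated <- NA
  out <- out[order(out$enhancer_id, out$erna_probe_id, out$tf_name,
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate coordinations with CTCF mediation
#'
#' A coordination is CTCF-mediated when at least one CTCF peak overlaps its
#' enhancer and at least one overlaps its target promoter (>= 1 nt each; a
#' single wide peak spanning both ends satisfies both tests).
#'
#' @param coords Coordination table (see [build_coordinations()]).
#' @param ctcf_peaks CTCF peak interval table.
#' @param catalogue Enhancer catalogue.
#' @param genes Gene table.
#' @param promoter_length Promoter length in nucleotides.
#' @return `coords` with the `ctcf_mediated` column filled in.
#' @export
ctcf_mediated <- function(coords, ctcf_peaks, catalogue, genes,
                          promoter_length = 2000) {
  if (!nrow(coords)) return(coords)
  promoters <- promoter_region(genes, length = promoter_length)
  occupied <- function(regions, ids) {
    sub <- regions[match(ids, regions$id), , drop = FALSE]
    if (is.null(ctcf_peaks) || !nrow(ctcf_peaks)) {
      return(stats::setNames(rep(FALSE, length(ids)), ids))
    }
    hits <- intersect_any(sub, ctcf_peaks)
    stats::setNames(ids %in% hits$query_id, ids)
  }
  enh_occ <- occupied(catalogue, unique(coords$enhancer_id))
  pro_occ <- occupied(promoters, unique(coords$gene_id))
  coords$ctcf_mediated <- unname(enh_occ[coords$enhancer_id] &
                                   pro_occ[coords$gene_id])
  coords
}

COORD_ROLES <- c(enhancer = "enhancer_id", eRNA = "erna_probe_id",
                 TF = "tf_name", gene = "gene_id")

#' Node degrees in the coordination network
#'
#' The degree of a node is the number of coordinations it appears in
#' (coordination-incidence count), so degrees within one role sum to the
#' number of coordinations.
#'
#' @param coords Coordination table.
#' @return A data.frame `node`, `role`, `degree`, sorted by role, then
#'   degree descending, then node id.
#' @export
node_degrees <- function(coords) {
  rows <- lapply(names(COORD_ROLES), function(role) {
    t <- table(coords[[COORD_ROLES[[role]]]])
    if (!length(t)) return(NULL)
    data.frame(node = names(t), role = role, degree = as.numeric(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    return(data.frame(node = character(), role = character(),
                      degree = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$role, -out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subnetwork induced by the k highest-degree nodes of one role
#'
#' Ranks the nodes of `role` by degree (ties broken by node id) and returns
#' every coordination incident to the top `k`; `k` larger than the number
#' of nodes returns everything.
#'
#' @param coords Coordination table.
#' @param role One of `"enhancer"`, `"eRNA"`, `"TF"`, `"gene"`.
#' @param k Number of top nodes.
#' @return The incident subset of `coords`.
#' @export
top_k_by_degree <- function(coords, role = c("enhancer", "eRNA", "TF", "gene"),
                            k = 2) {
  role <- match.arg(role)
  deg <- node_degrees(coords)
  deg <- deg[deg$role == role, , drop = FALSE]
  top <- utils::head(deg$node, k)
  coords[coords[[COORD_ROLES[[role]]]] %in% top, , drop = FALSE]
}

#' Export the coordination network
#'
#' The edge model expands each coordination into enhancer-TF
#' (`shares_motif`), TF-gene (`regulates`) and enhancer-eRNA
#' (`transcribed_as`) edges, deduplicated. `"sif"` writes a SIF edge list
#' plus a node-attribute table (`<path base>_nodes.tsv` with role and
#' degree); `"graphml"` writes GraphML via igraph with the same node
#' attributes.
#'
#' @param coords Coordination table.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, the edge data.frame (`from`, `interaction`, `to`).
#' @export
export_network <- function(coords, path, format = c("sif", "graphml")) {
  if (!format[1] %in% c("sif", "graphml")) {
    stop("export_network: unknown format '", format[1], "'")
  }
  format <- match.arg(format)
  edges <- unique(rbind(
    data.frame(from = coords$enhancer_id, interaction = "shares_motif",
               to = coords$tf_name, stringsAsFactors = FALSE),
    data.frame(from = coords$tf_name, interaction = "regulates",
               to = coords$gene_id, stringsAsFactors = FALSE),
    data.frame(from = coords$enhancer_id, interaction = "transcribed_as",
               to = coords$erna_probe_id, stringsAsFactors = FALSE)
  ))
  edges <- edges[order(edges$from, edges$interaction, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- node_degrees(coords)
  if (format == "sif") {
    writeLines(paste(edges$from, edges$interaction, edges$to, sep = "\t"),
               path)
    write_table(nodes, paste0(tools::file_path_sans_ext(path), "_nodes.tsv"))
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "interaction")], directed = FALSE,
      vertices = nodes[, c("node", "role", "degree")]
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(edges)
}

#' Read a SIF edge list back into an edge table
#' @param path SIF file path.
#' @return A data.frame `from`, `interaction`, `to`.
#' @export
read_sif <- function(path) {
  p <- split_fields(path)
  rows <- lapply(seq_along(p$fields), function(i) {
    f <- p$fields[[i]]
    if (length(f) != 3) bad_line(path, p$lineno[i], "SIF needs 3 columns")
    data.frame(from = f[1], interaction = f[2], to = f[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
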