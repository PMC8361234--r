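# Consensus orthology: collapse per-tool calls into supported edges, cut the
# supported bipartite graph into orthology groups, and bucket genes into the
# nameability categories used for reporting.

#' Tally distinct-tool support for every gene pair
#'
#' One edge per unique (query, subject) pair; `support_count` is the number
#' of distinct tools that reported the pair (a tool contributes at most once
#' per pair), and an edge is `supported` when that count reaches
#' `config$min_tools` — the threshold is inclusive, so "three or more"
#' means exactly three qualifies.
#'
#' @param calls data.frame of ortholog calls ([read_ortholog_table()]),
#'   possibly concatenated across tools.
#' @param config A [nomenclature_config()].
#' @return data.frame of consensus edges with columns `query_id`,
#'   `subject_id`, `subject_taxon`, `support_count`, `supported`.
#' @export
tally_support <- function(calls, config = nomenclature_config()) {
  if (nrow(calls) == 0L) {
    return(data.frame(query_id = character(0), subject_id = character(0),
                      subject_taxon = character(0),
                      support_count = integer(0), supported = logical(0),
                      stringsAsFactors = FALSE))
  }
  taxon_by_subject <- tapply(calls$subject_taxon, calls$subject_id,
                             function(t) length(unique(t)))
  if (any(taxon_by_subject > 1L))
    stop("conflicting subject_taxon for subject(s): ",
         paste(names(taxon_by_subject)[taxon_by_subject > 1L], collapse = ", "))

  u <- calls[!duplicated(calls[, c("tool", "query_id", "subject_id")]), ,
             drop = FALSE]
  key <- paste(u$query_id, u$subject_id, sep = "\t")
  cnt <- table(key)
  first <- u[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$query_id, first$subject_id, sep = "\t")
  edges <- data.frame(query_id = first$query_id,
                      subject_id = first$subject_id,
                      subject_taxon = first$subject_taxon,
                      support_count = as.integer(cnt[fkey]),
                      stringsAsFactors = FALSE)
  edges$supported <- edges$support_count >= config$min_tools
  edges <- edges[order_c(edges$query_id, edges$subject_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Classify orthology-group topology
#'
#' Cuts the supported-edge bipartite graph (echinoderm genes vs reference
#' symbols) into connected components and labels each by the counts of its
#' two sides: (1,1) one_one, (1,>1) one_many, (>1,1) many_one, (>1,>1)
#' many_many. Genes from `all_gene_ids` with no supported edge become
#' singleton `orphan` groups, so every gene flows through the naming
#' cascade exactly once.
#'
#' @param edges Consensus-edge data.frame; only rows with `supported ==
#'   TRUE` are used.
#' @param all_gene_ids Optional character vector of every query gene id;
#'   ids without supported edges are emitted as orphans.
#' @return List of orthology groups; each a list with `echino_members`,
#'   `ref_members`, `topology` and `edge_support` (data.frame gene_id,
#'   symbol, support_count).
#' @export
classify_topology <- function(edges, all_gene_ids = character(0)) {
  sup <- edges[edges$supported %||% logical(0), , drop = FALSE]
  groups <- list()
  if (nrow(sup)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = paste0("q|", sup$query_id),
                 to = paste0("s|", sup$subject_id)),
      directed = FALSE)
    comp <- igraph::components(g)
    memb <- comp$membership
    for (ci in seq_len(comp$no)) {
      verts <- names(memb)[memb == ci]
      echino <- sort_c(sub("^q\\|", "", verts[startsWith(verts, "q|")]))
      refs <- sort_c(sub("^s\\|", "", verts[startsWith(verts, "s|")]))
      es <- sup[sup$query_id %in% echino & sup$subject_id %in% refs,
                c("query_id", "subject_id", "support_count")]
      names(es) <- c("gene_id", "symbol", "support_count")
      es <- es[order_c(es$gene_id, es$symbol), , drop = FALSE]
      rownames(es) <- NULL
      topo <- if (length(echino) == 1L && length(refs) == 1L) "one_one"
      else if (length(echino) == 1L) "one_many"
      else if (length(refs) == 1L) "many_one"
      else "many_many"
      groups[[length(groups) + 1L]] <-
        list(echino_members = echino, ref_members = refs,
             topology = topo, edge_support = es)
    }
  }
  orphan_ids <- setdiff(all_gene_ids, sup$query_id)
  for (gid in sort_c(orphan_ids)) {
    groups[[length(groups) + 1L]] <-
      list(echino_members = gid, ref_members = character(0),
           topology = "orphan",
           edge_support = data.frame(gene_id = character(0),
                                     symbol = character(0),
                                     support_count = integer(0)))
  }
  first_member <- vapply(groups, function(g) g$echino_members[1L], "")
  groups[order_c(first_member)]
}

#' Bucket genes into nameability categories
#'
#' Topology is evaluated separately per reference-taxon stratum: a gene in
#' a one:one group against human is `human_one_one`; failing that, one:one
#' against another vertebrate is `vertebrate_one_one`; failing that, any
#' supported invertebrate or non-animal edge gives `invertebrate_only`;
#' genes with no qualifying supported relationship are `unnameable`.
#'
#' @param edges Consensus-edge data.frame (all taxa mixed).
#' @param all_gene_ids Character vector of every gene id to categorize.
#' @param exclude_subjects Subject ids to ignore, typically the cohort's
#'   own gene ids: cross-species echinoderm links travel the tables with
#'   taxon "invertebrate" but are internal evidence, not reference
#'   orthologs.
#' @return Named character vector gene_id -> category.
#' @export
categorize_genes <- function(edges, all_gene_ids,
                             exclude_subjects = character(0)) {
  cat_of <- stats::setNames(rep("unnameable", length(all_gene_ids)),
                            all_gene_ids)
  sup <- edges[edges$supported %||% logical(0), , drop = FALSE]
  sup <- sup[!(sup$subject_id %in% exclude_subjects), , drop = FALSE]
  one_one_ids <- function(taxon) {
    e <- sup[sup$subject_taxon == taxon, , drop = FALSE]
    if (!nrow(e)) return(character(0))
    groups <- classify_topology(transform(e, supported = TRUE))
    unlist(lapply(groups, function(g)
      if (g$topology == "one_one") g$echino_members else character(0)))
  }
  h11 <- intersect(one_one_ids("human"), all_gene_ids)
  v11 <- intersect(one_one_ids("other_vertebrate"), all_gene_ids)
  inv <- intersect(
    unique(sup$query_id[sup$subject_taxon %in% c("invertebrate", "non_animal")]),
    all_gene_ids)
  cat_of[inv] <- "invertebrate_only"
  cat_of[v11] <- "vertebrate_one_one"
  cat_of[h11] <- "human_one_one"
  cat_of
}
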