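# Pseudoduplicate detection. Highly polymorphic echinoderm genomes retain
# both haplotypes of some loci as separate gene models (under-collapsed
# heterozygosity). Gene models -- introns included, plus 1 kb of flank on
# each side -- that match another model at >= 90% identity along >= 90% of
# the longer model's length are flagged as a pseudoduplicate cluster and
# suffixed rather than numbered as true paralogs.

#' Extract a gene-model sequence with flanks
#'
#' Returns the contiguous genomic slice `[start - flank_bp, end + flank_bp]`
#' on the forward strand, clipped to the contig bounds (a clipped flank is
#' reported with a warning). Introns are included by construction.
#'
#' @param gene One gene row (list or single-row data.frame with `gene_id`,
#'   `chrom`, `start`, `end`).
#' @param genome [Biostrings::DNAStringSet] of contigs.
#' @param flank_bp Bases of flank on each side; >= 0.
#' @return Character scalar sequence, with attributes `start` and `end`
#'   giving the 1-based inclusive genomic slice taken.
#' @export
extract_gene_model_sequence <- function(gene, genome, flank_bp = 1000L) {
  stopifnot(flank_bp >= 0L)
  chrom <- as.character(gene$chrom)
  if (!chrom %in% names(genome))
    stop(sprintf("gene %s: contig %s absent from genome", gene$gene_id, chrom))
  clen <- Biostrings::width(genome[chrom])
  if (gene$start < 1L || gene$end > clen || gene$start > gene$end)
    stop(sprintf("gene %s: span %d..%d outside contig %s (length %d)",
                 gene$gene_id, gene$start, gene$end, chrom, clen))
  s <- gene$start - flank_bp
  e <- gene$end + flank_bp
  if (s < 1L || e > clen) {
    warning(sprintf("gene %s: flank clipped to contig bounds (%d upstream, %d downstream taken)",
                    gene$gene_id, gene$start - max(s, 1L), min(e, clen) - gene$end))
    s <- max(s, 1L)
    e <- min(e, clen)
  }
  seq <- as.character(Biostrings::subseq(genome[[chrom]], s, e))
  attr(seq, "start") <- s
  attr(seq, "end") <- e
  seq
}

#' Extract all gene-model sequences of a cohort
#'
#' @param models A `gene_models` object ([read_gene_models()]).
#' @param flank_bp Flank size in bases.
#' @return Named character vector gene_id -> sequence.
#' @export
extract_all_sequences <- function(models, flank_bp = 1000L) {
  genes <- models$genes
  out <- vapply(seq_len(nrow(genes)), function(i) {
    as.character(extract_gene_model_sequence(genes[i, ], models$genome,
                                             flank_bp))
  }, character(1))
  stats::setNames(out, genes$gene_id)
}

#' Does a similarity hit pass the 90/90 rule?
#'
#' TRUE iff `pct_identity >= identity_threshold` AND
#' `100 * aln_length / max(q_len, s_len) >= coverage_threshold`. Both
#' comparisons are inclusive: a hit at exactly 90.0 / 90.0 passes.
#' Identity follows the BLAST `pident` convention (over the alignment).
#'
#' @param hit One or more similarity-hit rows (data.frame).
#' @param config A [nomenclature_config()].
#' @return Logical vector, one element per hit.
#' @export
hit_passes <- function(hit, config = nomenclature_config()) {
  if (nrow(hit) == 0L) return(logical(0))
  stopifnot(all(hit$q_len > 0), all(hit$s_len > 0))
  longer <- pmax(hit$q_len, hit$s_len)
  if (any(hit$aln_length > longer))
    stop("malformed hit: aln_length exceeds the longer sequence length")
  hit$pct_identity >= config$identity_threshold &
    (hit$aln_length / longer) * 100 >= config$coverage_threshold
}

# single best HSP per ordered pair: max aln_length, ties by pct_identity
best_hits_per_pair <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order_c(hits$query_id, hits$subject_id,
                 -hits$aln_length, -hits$pct_identity)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h[, c("query_id", "subject_id")]), , drop = FALSE]
}

#' Cluster pseudoduplicates
#'
#' Keeps the single best HSP per ordered pair (longest alignment, ties by
#' identity), applies the 90/90 rule, treats a pair as passing when either
#' orientation passes, and returns the connected components of size >= 2 of
#' the resulting undirected graph. Chained pairs are merged transitively:
#' the members of one under-collapsed locus need not all match each other
#' directly.
#'
#' @param hits Similarity-hit data.frame ([read_similarity_hits()]).
#' @param config A [nomenclature_config()].
#' @return List of clusters, each a list with `members` (sorted gene ids)
#'   and `evidence` (the passing hits among members); clusters sorted by
#'   first member.
#' @export
cluster_pseudoduplicates <- function(hits, config = nomenclature_config()) {
  if (nrow(hits) == 0L) return(list())
  best <- best_hits_per_pair(hits)
  pass <- best[hit_passes(best, config), , drop = FALSE]
  if (nrow(pass) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = pass$query_id, to = pass$subject_id), directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- sort_c(names(comp$membership)[comp$membership == ci])
    if (length(members) < 2L) next
    ev <- pass[pass$query_id %in% members & pass$subject_id %in% members, ,
               drop = FALSE]
    rownames(ev) <- NULL
    out[[length(out) + 1L]] <- list(members = members, evidence = ev)
  }
  first <- vapply(out, function(cl) cl$members[1L], "")
  out[order_c(first)]
}

#' Compute all-vs-all similarity hits with the internal aligner
#'
#' Fixture-scale fallback so tests and demo runs never need an external
#' BLAST binary: every gene-model pair is locally aligned with
#' [Biostrings::pairwiseAlignment] and reported in the same columns as a
#' BLAST tabular hit (identity over the alignment, alignment length, full
#' sequence lengths). Quadratic in the number of genes -- intended for
#' small cohorts only; supply precomputed BLAST hits for real genomes.
#'
#' @param seqs Named character vector gene_id -> sequence (with flanks).
#' @param min_identity Hits below this percent identity are not reported
#'   (keeps the output comparable to a BLAST run with default cutoffs).
#' @return Similarity-hit data.frame, one row per unordered pair reported.
#' @export
compute_similarity_hits <- function(seqs, min_identity = 50) {
  ids <- names(seqs)
  rows <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]],
                                             type = "local")
        pid <- Biostrings::pid(aln, type = "PID1")
        alen <- Biostrings::nchar(aln)
        if (pid < min_identity) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = ids[i], subject_id = ids[j],
          pct_identity = round(pid, 2), aln_length = alen,
          q_len = nchar(seqs[[i]]), s_len = nchar(seqs[[j]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pseudoduplicate clusters as a table and BED
#'
#' @param clusters List of clusters from [cluster_pseudoduplicates()].
#' @param path Output path for the two-column table (cluster_id, gene_id).
#' @param bed_path Optional BED output of member gene spans (0-based
#'   half-open starts, per BED convention).
#' @param genes Optional genes data.frame (required for `bed_path`).
#' @export
write_clusters <- function(clusters, path, bed_path = NULL, genes = NULL) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    data.frame(cluster_id = sprintf("pd%04d", i),
               gene_id = clusters[[i]]$members, stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(cluster_id = character(0), gene_id = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  if (!is.null(bed_path)) {
    stopifnot(!is.null(genes))
    m <- merge(rows, genes[, c("gene_id", "chrom", "start", "end")],
               by = "gene_id", sort = FALSE)
    bed <- data.frame(chrom = m$chrom, start = m$start - 1L, end = m$end,
                      name = paste(m$cluster_id, m$gene_id, sep = "|"))
    bed <- bed[order_c(bed$chrom, bed$start, bed$name), , drop = FALSE]
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  invisible(path)
}
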