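# All external-format parsing lives in this file: ortholog call tables,
# reference gene tables, gene models (GFF3 + FASTA), BLAST outfmt-6 style
# similarity hits, legacy-identifier and curator-override tables, and the
# assignment / synonym writers. Everything downstream works on plain
# data.frames produced here.

#' Read one tool's ortholog prediction table
#'
#' Expects a tab-separated file with a header and columns `query`, `subject`
#' and `taxon` (extra columns are ignored). The taxon vocabulary is the
#' closed set human / other_vertebrate / invertebrate / non_animal,
#' case-insensitive on read. Duplicate (query, subject) rows are collapsed:
#' one tool contributes at most one call per gene pair.
#'
#' @param path Path to the table.
#' @param tool Name of the tool that produced it; stored with every call.
#' @return A data.frame of ortholog calls with columns `tool`, `query_id`,
#'   `subject_id`, `subject_taxon`.
#' @export
read_ortholog_table <- function(path, tool) {
  stopifnot(is.character(tool), length(tool) == 1L, nzchar(tool))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("query", "subject", "taxon")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("ortholog table %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) {
    warning(sprintf("ortholog table %s is empty", path))
    return(empty_calls())
  }
  taxon <- tolower(trimws(df$taxon))
  bad <- !nzchar(trimws(df$query)) | !nzchar(trimws(df$subject)) |
    !(taxon %in% TAXA)
  if (any(bad)) {
    # +1 for the header line
    warning(sprintf("ortholog table %s: dropped malformed row(s) at line(s) %s",
                    path, paste(which(bad) + 1L, collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
    taxon <- taxon[!bad]
  }
  out <- data.frame(tool = tool,
                    query_id = trimws(df$query),
                    subject_id = trimws(df$subject),
                    subject_taxon = taxon,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("query_id", "subject_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(tool = character(0), query_id = character(0),
             subject_id = character(0), subject_taxon = character(0),
             stringsAsFactors = FALSE)
}

#' Read the reference gene table
#'
#' Tab-separated with header columns `symbol`, `name`, `stem`, `taxon`.
#' A blank stem is stored as `NA` (family membership unknown). A symbol
#' duplicated within one taxon is a hard error.
#'
#' @param path Path to the table.
#' @return A data.frame keyed by `symbol` with columns `symbol`,
#'   `full_name`, `family_stem`, `taxon`.
#' @export
read_reference_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("symbol", "name", "stem", "taxon")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("reference table %s: missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  taxon <- tolower(trimws(df$taxon))
  if (nrow(df) && any(!taxon %in% TAXA))
    stop(sprintf("reference table %s: unknown taxon value(s) %s", path,
                 paste(unique(taxon[!taxon %in% TAXA]), collapse = ", ")))
  key <- paste(taxon, df$symbol)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop(sprintf(
      "reference table %s: symbol duplicated within a taxon at line(s) %s",
      path, paste(d + 1L, collapse = ", ")))
  }
  stem <- trimws(df$stem)
  stem[!nzchar(stem)] <- NA_character_
  out <- data.frame(symbol = trimws(df$symbol),
                    full_name = df$name,
                    family_stem = stem,
                    taxon = taxon,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read gene models from GFF3 + genome FASTA
#'
#' Parses `gene` and `exon` features (exons attached to genes through their
#' `Parent` attribute), keeping GFF3 1-based inclusive coordinates
#' throughout. Optional GFF3 attributes `entrez_id` and `product` populate
#' the Entrez identifier and the predicted-product name used by the LOC
#' fallback rule.
#'
#' @param gff3_path Path to the GFF3 file.
#' @param fasta_path Path to the genome FASTA; sequence names must cover
#'   every chromosome referenced by a gene.
#' @param species Short species tag stored on every record.
#' @return A list of class `gene_models` with elements `genes` (data.frame
#'   with one row per gene, list-column `exons` of two-column start/end
#'   matrices) and `genome` (a [Biostrings::DNAStringSet]).
#' @export
read_gene_models <- function(gff3_path, fasta_path, species = "spur") {
  gr <- rtracklayer::import(gff3_path)
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  md <- S4Vectors::mcols(gr)
  is_gene <- as.character(md$type) == "gene"
  is_exon <- as.character(md$type) == "exon"
  genes_gr <- gr[is_gene]
  exons_gr <- gr[is_exon]
  gmd <- S4Vectors::mcols(genes_gr)

  gene_id <- as.character(gmd$ID)
  if (anyDuplicated(gene_id))
    stop("duplicate gene IDs in ", gff3_path)
  chrom <- as.character(GenomicRanges::seqnames(genes_gr))
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown))
    stop(sprintf("gene(s) reference sequence(s) absent from FASTA: %s",
                 paste(unknown, collapse = ", ")))
  start <- BiocGenerics::start(genes_gr)
  end <- BiocGenerics::end(genes_gr)
  over <- end > Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(over))
    stop(sprintf("gene span outside contig bounds: %s",
                 paste(gene_id[over], collapse = ", ")))

  entrez <- rep(NA_integer_, length(genes_gr))
  if (!is.null(gmd$entrez_id)) {
    ev <- suppressWarnings(as.integer(as.character(gmd$entrez_id)))
    entrez <- ev
  }
  product <- rep(NA_character_, length(genes_gr))
  if (!is.null(gmd$product)) product <- as.character(gmd$product)

  # attach exons through Parent
  emd <- S4Vectors::mcols(exons_gr)
  parent <- vapply(as.list(emd$Parent), function(p) as.character(p)[1L], "")
  ex_start <- BiocGenerics::start(exons_gr)
  ex_end <- BiocGenerics::end(exons_gr)
  exon_list <- lapply(seq_along(genes_gr), function(i) {
    sel <- which(parent == gene_id[i])
    if (!length(sel)) return(matrix(numeric(0), ncol = 2,
                                    dimnames = list(NULL, c("start", "end"))))
    m <- cbind(start = ex_start[sel], end = ex_end[sel])
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (any(m[, "start"] < start[i]) || any(m[, "end"] > end[i]))
      stop(sprintf("exon outside gene span for %s", gene_id[i]))
    if (nrow(m) > 1L && any(m[-1L, "start"] <= m[-nrow(m), "end"]))
      stop(sprintf("overlapping exons for %s", gene_id[i]))
    m
  })

  genes <- data.frame(species = species,
                      gene_id = gene_id,
                      entrez_id = entrez,
                      chrom = chrom,
                      start = start,
                      end = end,
                      strand = as.character(BiocGenerics::strand(genes_gr)),
                      product = product,
                      stringsAsFactors = FALSE)
  genes$exons <- exon_list
  ord <- order_c(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genes = genes, genome = genome), class = "gene_models")
}

#' Read BLAST-tabular similarity hits
#'
#' Canonical 12-column outfmt 6 order (`qseqid sseqid pident length ...`);
#' trailing extra columns are ignored, self-hits are dropped, and the full
#' gene-model sequence lengths are filled in from `gene_lengths`.
#'
#' @param path Path to the tabular file (no header).
#' @param gene_lengths Named numeric vector: gene_id -> full gene-model
#'   sequence length in bases (model plus flanks).
#' @return A data.frame of hits with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `q_len`, `s_len`.
#' @export
read_similarity_hits <- function(path, gene_lengths) {
  if (file.size(path) == 0L) return(empty_hits())
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty_hits())
  if (ncol(df) < 4L)
    stop(sprintf("similarity file %s: expected >= 4 tab-separated columns", path))
  hits <- data.frame(query_id = as.character(df[[1L]]),
                     subject_id = as.character(df[[2L]]),
                     pct_identity = as.numeric(df[[3L]]),
                     aln_length = as.numeric(df[[4L]]),
                     stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                     names(gene_lengths))
  if (length(unknown))
    stop(sprintf("similarity file %s names unknown gene(s): %s",
                 path, paste(sort_c(unknown), collapse = ", ")))
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop(sprintf("similarity file %s: pct_identity outside [0, 100]", path))
  hits$q_len <- as.numeric(gene_lengths[hits$query_id])
  hits$s_len <- as.numeric(gene_lengths[hits$subject_id])
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = numeric(0),
             q_len = numeric(0), s_len = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read the legacy-identifier table
#'
#' Tab-separated with header columns `gene_id`, `legacy_id`; one identifier
#' per row, oldest first, so the last row for a gene is its most recent
#' previous symbol.
#'
#' @param path Path to the table.
#' @return data.frame with columns `gene_id`, `legacy_id` in file order.
#' @export
read_legacy_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("gene_id", "legacy_id"), names(df))
  if (length(missing))
    stop(sprintf("legacy table %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  df[, c("gene_id", "legacy_id")]
}

#' Read the curator override table
#'
#' Tab-separated with header columns `gene_id`, `forced_symbol`,
#' `forced_name`, `note`. A forced symbol must already be in normalized
#' form (curators write machine-readable symbols directly).
#'
#' @param path Path to the table.
#' @return data.frame of overrides.
#' @export
read_overrides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("gene_id", "forced_symbol", "forced_name"),
                     names(df))
  if (length(missing))
    stop(sprintf("override table %s: missing column(s) %s", path,
                 paste(missing, collapse = ", ")))
  if (is.null(df$note)) df$note <- ""
  bad <- vapply(df$forced_symbol,
                function(s) !identical(normalize_symbol(s), s), logical(1))
  if (any(bad))
    stop(sprintf("override table %s: forced_symbol not in normalized form: %s",
                 path, paste(df$forced_symbol[bad], collapse = ", ")))
  df[, c("gene_id", "forced_symbol", "forced_name", "note")]
}

empty_overrides <- function() {
  data.frame(gene_id = character(0), forced_symbol = character(0),
             forced_name = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

assignment_columns <- c("species", "gene_id", "symbol", "full_name",
                        "rule_fired", "chosen_ortholog", "support_count",
                        "pseudodup_cluster", "suffix", "synonyms")

#' Write the assignment table
#'
#' Tab-separated, one row per gene, sorted by species then gene_id so
#' reruns are byte-identical. Symbol uniqueness within each species is
#' re-checked here as a last line of defense. Synonyms are semicolon-joined.
#'
#' @param path Output path.
#' @param assignments An assignments data.frame as produced by
#'   [assign_identifiers()].
#' @export
write_assignments <- function(path, assignments) {
  a <- assignments
  key <- paste(a$species, a$symbol)
  if (anyDuplicated(key))
    stop("duplicate symbol within a species: ",
         paste(unique(a$symbol[duplicated(key)]), collapse = ", "))
  a <- a[order_c(a$species, a$gene_id), , drop = FALSE]
  out <- data.frame(
    species = a$species,
    gene_id = a$gene_id,
    symbol = a$symbol,
    full_name = a$full_name,
    rule_fired = a$rule_fired,
    chosen_ortholog = ifelse(is.na(a$chosen_ortholog), "", a$chosen_ortholog),
    support_count = ifelse(is.na(a$support_count), "",
                           as.character(a$support_count)),
    pseudodup_cluster = ifelse(is.na(a$pseudodup_cluster), "",
                               a$pseudodup_cluster),
    suffix = ifelse(is.na(a$suffix), "", a$suffix),
    synonyms = vapply(a$synonyms, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read an assignment table back (round-trip of [write_assignments()])
#' @param path Path to the file.
#' @return assignments data.frame with the synonym list-column restored.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(assignment_columns, names(df))
  if (length(miss))
    stop(sprintf("assignment table %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  syn <- strsplit(df$synonyms, ";", fixed = TRUE)
  syn <- lapply(syn, function(s) s[nzchar(s)])
  out <- data.frame(gene_id = df$gene_id, species = df$species,
                    symbol = df$symbol, full_name = df$full_name,
                    rule_fired = df$rule_fired,
                    chosen_ortholog = ifelse(nzchar(df$chosen_ortholog),
                                             df$chosen_ortholog, NA_character_),
                    support_count = ifelse(nzchar(df$support_count),
                                           suppressWarnings(as.integer(df$support_count)),
                                           NA_integer_),
                    pseudodup_cluster = ifelse(nzchar(df$pseudodup_cluster),
                                               df$pseudodup_cluster, NA_character_),
                    suffix = ifelse(nzchar(df$suffix), df$suffix, NA_character_),
                    stringsAsFactors = FALSE)
  out$synonyms <- syn
  out
}

#' Write the synonym table
#'
#' Maps every historical identifier (and auto-generated alternate form) to
#' the gene's current symbol, so searches by legacy name keep resolving.
#'
#' @param path Output path.
#' @param assignments assignments data.frame.
#' @export
write_synonym_table <- function(path, assignments) {
  rows <- do.call(rbind, lapply(seq_len(nrow(assignments)), function(i) {
    syn <- assignments$synonyms[[i]]
    if (!length(syn)) return(NULL)
    data.frame(synonym = syn,
               species = assignments$species[i],
               gene_id = assignments$gene_id[i],
               current_symbol = assignments$symbol[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(synonym = character(0), species = character(0),
                       gene_id = character(0), current_symbol = character(0))
  rows <- rows[order_c(rows$species, rows$gene_id, rows$synonym), , drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
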