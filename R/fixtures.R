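# Deterministic synthetic-cohort generator. Every pipeline branch (one:one,
# each one:many tie-break, many:one, many:many, pseudoduplicates,
# vertebrate-only, invertebrate-only, orphan) is planted with a known
# expected symbol, rule and category, so end-to-end tests can demand 100%
# recovery without downloading anything. All randomness flows from one
# seed; reruns are byte-identical.

#' Cohort specification for the synthetic generator
#'
#' Counts are genes (or groups, where noted) per branch, per species.
#' Defaults give a small but complete cohort touching every branch.
#'
#' @param n_one_one Genes with a single human ortholog.
#' @param n_one_many_support One:many genes resolved by the most-tools rule.
#' @param n_one_many_stem One:many genes resolved to a family stem.
#' @param n_one_many_curator One:many genes resolved by a curator override.
#' @param n_one_many_alpha One:many genes resolved alphanumerically.
#' @param n_many_one Many:one groups; `many_one_size` genes each.
#' @param many_one_size Paralogs per many:one group.
#' @param n_many_many Many:many groups; `many_many_size` genes each.
#' @param many_many_size Paralogs per many:many group.
#' @param n_pseudodup Pseudoduplicate clusters (pairs) with a human ortholog.
#' @param n_vertebrate_one_one Genes whose only one:one ortholog is a
#'   non-human vertebrate gene.
#' @param n_invertebrate_only Genes with only invertebrate orthologs.
#' @param n_orphan Genes with no ortholog call at all.
#' @param n_noise Spurious gene-reference pairs reported by fewer than
#'   `min_tools` tools (must not affect any assignment).
#' @param n_species Number of echinoderm species (1 or 2). With 2 species
#'   every branch is planted in each species and `n_shared_paralog`
#'   many:one groups are additionally shared across species with
#'   supported cross-species links, so suffix inheritance is exercised.
#' @param n_shared_paralog Cross-species shared many:one groups.
#' @param tools Tool-name panel.
#' @param gene_len_range Range of gene-model lengths (bases).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_one_one = 5L, n_one_many_support = 2L,
                        n_one_many_stem = 2L, n_one_many_curator = 2L,
                        n_one_many_alpha = 2L,
                        n_many_one = 2L, many_one_size = 3L,
                        n_many_many = 1L, many_many_size = 3L,
                        n_pseudodup = 1L,
                        n_vertebrate_one_one = 2L,
                        n_invertebrate_only = 2L,
                        n_orphan = 2L, n_noise = 3L,
                        n_species = 1L, n_shared_paralog = 0L,
                        tools = c("inparanoid", "proteinortho", "swiftortho",
                                  "fastortho", "oma", "orthofinder"),
                        gene_len_range = c(400L, 1200L)) {
  spec <- as.list(environment())
  stopifnot(n_species %in% c(1L, 2L), length(tools) >= 1L)
  structure(spec, class = "cohort_spec")
}

# sample one element of a vector, immune to R's sample(n, 1) scalar pitfall
pick1 <- function(v) v[sample.int(length(v), 1L)]

# draw a tool subset of exactly `k` distinct tools
draw_tools <- function(tools, k) {
  if (k > length(tools))
    stop(sprintf("infeasible spec: %d tools requested from a panel of %d",
                 k, length(tools)))
  sort_c(sample(tools, k))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param seed Integer seed; the same seed always regenerates identical
#'   objects and (with `out_dir`) byte-identical files.
#' @param spec A [cohort_spec()].
#' @param config A [nomenclature_config()]; supported pairs are planted
#'   with at least `config$min_tools` tools, noise pairs with fewer.
#' @param out_dir Optional directory; when given, tool tables,
#'   reference/legacy/override tables, GFF3 + FASTA gene models, a
#'   similarity-hit table and the planted truth are written there.
#' @return List with `genes`, `calls`, `reference`, `overrides`, `legacy`,
#'   `hits`, `genome`, `truth` (data.frame of per-gene expected symbol,
#'   rule, category, cluster, suffix), and `files` (paths, if written).
#' @export
generate_cohort <- function(seed, spec = cohort_spec(),
                            config = nomenclature_config(),
                            out_dir = NULL) {
  if (spec$n_species == 1L && spec$n_shared_paralog > 0L)
    stop("n_shared_paralog requires n_species = 2")
  min_agree <- config$min_tools
  if (min_agree > length(spec$tools))
    stop(sprintf("infeasible spec: min_tools %d exceeds tool panel size %d",
                 min_agree, length(spec$tools)))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  # sorted species order matches downstream processing order, so planted
  # cluster ids line up with the pipeline's sorted cluster labels
  species <- sort_c(c("spur", "pmin")[seq_len(spec$n_species)])
  flank <- config$flank_bp

  ref_rows <- list()
  call_rows <- list()
  legacy_rows <- list()
  override_rows <- list()
  truth_rows <- list()
  gene_rows <- list()
  hit_rows <- list()
  counter <- 0L

  add_ref <- function(symbol, name, stem, taxon) {
    ref_rows[[length(ref_rows) + 1L]] <<- data.frame(
      symbol = symbol, full_name = name, family_stem = stem, taxon = taxon,
      stringsAsFactors = FALSE)
  }
  add_calls <- function(query, subject, taxon, k) {
    for (tl in draw_tools(spec$tools, k))
      call_rows[[length(call_rows) + 1L]] <<- data.frame(
        tool = tl, query_id = query, subject_id = subject,
        subject_taxon = taxon, stringsAsFactors = FALSE)
  }
  new_gene <- function(sp) {
    counter <<- counter + 1L
    gid <- sprintf("%s-g%05d", sp, counter)
    len <- pick1(seq(spec$gene_len_range[1L], spec$gene_len_range[2L]))
    g <- list(species = sp, gene_id = gid, entrez_id = 100000L + counter,
              len = len, strand = pick1(c("+", "-")),
              product = sprintf("hypothetical protein %05d", counter))
    gene_rows[[length(gene_rows) + 1L]] <<- g
    if (counter %% 3L == 0L)
      legacy_rows[[length(legacy_rows) + 1L]] <<- data.frame(
        gene_id = gid, legacy_id = sprintf("Sp-Leg%05d", counter),
        stringsAsFactors = FALSE)
    g
  }
  add_truth <- function(g, symbol, rule, category,
                        cluster = NA_character_, suffix = NA_character_) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      gene_id = g$gene_id, species = g$species,
      expected_symbol = symbol, expected_rule = rule,
      expected_category = category, expected_cluster = cluster,
      expected_suffix = suffix, stringsAsFactors = FALSE)
  }
  supp <- function() pick1(seq(min_agree, length(spec$tools)))

  unit <- 0L  # per-branch reference-symbol uniquifier
  cluster_no <- 0L
  shared_done <- FALSE

  for (sp in species) {
    # one:one
    for (i in seq_len(spec$n_one_one)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      sym <- sprintf("OOG%03d", unit)
      add_ref(sym, sprintf("one to one gene %03d", unit), "", "human")
      add_calls(g$gene_id, sym, "human", supp())
      add_truth(g, normalize_symbol(sym), "one_one", "human_one_one")
    }
    # one:many resolved by support
    for (i in seq_len(spec$n_one_many_support)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      win <- sprintf("OMW%03dA", unit)
      lose <- sprintf("OMW%03dB", unit)
      if (min_agree + 1L > length(spec$tools))
        stop("infeasible spec: the most-tools branch needs min_tools + 1 tools")
      w <- pick1(seq(min_agree + 1L, length(spec$tools)))
      add_ref(win, sprintf("winner gene %03d", unit), "", "human")
      add_ref(lose, sprintf("runner up gene %03d", unit), "", "human")
      add_calls(g$gene_id, win, "human", w)
      add_calls(g$gene_id, lose, "human",
                pick1(seq(min_agree, w - 1L)))
      add_truth(g, normalize_symbol(win), "one_many_support", "unnameable")
    }
    # one:many resolved to the family stem
    for (i in seq_len(spec$n_one_many_stem)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      stem <- sprintf("stm%03d", unit)
      t <- supp()
      for (letter in c("A", "B", "C")) {
        sym <- sprintf("STM%03d%s", unit, letter)
        add_ref(sym, sprintf("stem family %03d member %s", unit, letter),
                stem, "human")
        add_calls(g$gene_id, sym, "human", t)
      }
      add_truth(g, stem, "one_many_stem", "unnameable")
    }
    # one:many resolved by curator override
    for (i in seq_len(spec$n_one_many_curator)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      a <- sprintf("CURA%03d", unit)
      b <- sprintf("CURB%03d", unit)
      t <- supp()
      add_ref(a, sprintf("curated tie %03d a", unit), "", "human")
      add_ref(b, sprintf("curated tie %03d b", unit), "", "human")
      add_calls(g$gene_id, a, "human", t)
      add_calls(g$gene_id, b, "human", t)
      forced <- sprintf("cur%03dx", unit)
      override_rows[[length(override_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, forced_symbol = forced,
        forced_name = sprintf("curated gene %03d", unit),
        note = "fixture override", stringsAsFactors = FALSE)
      add_truth(g, forced, "one_many_curator", "unnameable")
    }
    # one:many resolved alphanumerically
    for (i in seq_len(spec$n_one_many_alpha)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      syms <- sprintf("AL%s%03d", sample(c("PA", "QB", "RC"), 2L), unit)
      t <- supp()
      for (sym in syms) {
        add_ref(sym, sprintf("alpha tie gene %s", sym), "", "human")
        add_calls(g$gene_id, sym, "human", t)
      }
      norm <- vapply(syms, normalize_symbol, "")
      add_truth(g, sort_c(norm)[1L], "one_many_alpha", "unnameable")
    }
    # many:one paralog groups
    for (i in seq_len(spec$n_many_one)) {
      unit <- unit + 1L
      sym <- sprintf("MOG%03d", unit)
      add_ref(sym, sprintf("expanded family %03d", unit), "", "human")
      for (k in seq_len(spec$many_one_size)) {
        g <- new_gene(sp)
        add_calls(g$gene_id, sym, "human", supp())
        add_truth(g, sprintf("%s.%d", normalize_symbol(sym), k),
                  "paralog_suffix", "unnameable",
                  suffix = as.character(k))
      }
    }
    # many:many paralog groups (base resolved through the one:many rules)
    for (i in seq_len(spec$n_many_many)) {
      unit <- unit + 1L
      wa <- sprintf("MMA%03d", unit)
      wb <- sprintf("MMB%03d", unit)
      add_ref(wa, sprintf("expanded pair %03d a", unit), "", "human")
      add_ref(wb, sprintf("expanded pair %03d b", unit), "", "human")
      hi <- length(spec$tools)
      lo <- min_agree
      if (hi <= lo) hi <- lo + 1L  # infeasible guard hit earlier
      for (k in seq_len(spec$many_many_size)) {
        g <- new_gene(sp)
        add_calls(g$gene_id, wa, "human", hi)
        add_calls(g$gene_id, wb, "human", lo)
        add_truth(g, sprintf("%s.%d", normalize_symbol(wa), k),
                  "paralog_suffix", "unnameable",
                  suffix = as.character(k))
      }
    }
    # pseudoduplicate pairs sharing one human ortholog
    for (i in seq_len(spec$n_pseudodup)) {
      unit <- unit + 1L
      cluster_no <- cluster_no + 1L
      sym <- sprintf("PDG%03d", unit)
      add_ref(sym, sprintf("pseudoduplicated gene %03d", unit), "", "human")
      ga <- new_gene(sp)
      gb <- new_gene(sp)
      gb$len <- ga$len
      gene_rows[[length(gene_rows)]] <- gb  # keep equal model lengths
      add_calls(ga$gene_id, sym, "human", supp())
      add_calls(gb$gene_id, sym, "human", supp())
      wlen <- ga$len + 2L * flank
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = ga$gene_id, subject_id = gb$gene_id,
        pct_identity = 98, aln_length = wlen, q_len = wlen, s_len = wlen,
        stringsAsFactors = FALSE)
      cid <- sprintf("pd%04d", cluster_no)
      base <- normalize_symbol(sym)
      add_truth(ga, sprintf("%s.a", base), "pseudodup_suffix",
                "unnameable", cluster = cid, suffix = "a")
      add_truth(gb, sprintf("%s.b", base), "pseudodup_suffix",
                "unnameable", cluster = cid, suffix = "b")
    }
    # one:one vertebrate (non-human) orthologs: LOC fallback, own category
    for (i in seq_len(spec$n_vertebrate_one_one)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      sym <- sprintf("VRT%03d", unit)
      add_ref(sym, sprintf("vertebrate gene %03d", unit), "",
              "other_vertebrate")
      add_calls(g$gene_id, sym, "other_vertebrate", supp())
      add_truth(g, sprintf("loc%d", g$entrez_id), "loc_fallback",
                "vertebrate_one_one")
    }
    # invertebrate-only orthologs: LOC fallback
    for (i in seq_len(spec$n_invertebrate_only)) {
      unit <- unit + 1L
      g <- new_gene(sp)
      sym <- sprintf("INV%03d", unit)
      add_ref(sym, sprintf("invertebrate gene %03d", unit), "",
              "invertebrate")
      add_calls(g$gene_id, sym, "invertebrate", supp())
      add_truth(g, sprintf("loc%d", g$entrez_id), "loc_fallback",
                "invertebrate_only")
    }
    # orphans: no calls at all
    for (i in seq_len(spec$n_orphan)) {
      g <- new_gene(sp)
      add_truth(g, sprintf("loc%d", g$entrez_id), "loc_fallback",
                "unnameable")
    }
  }

  # shared many:one groups across the two species, with cross-links
  if (spec$n_shared_paralog > 0L) {
    for (i in seq_len(spec$n_shared_paralog)) {
      unit <- unit + 1L
      sym <- sprintf("SHP%03d", unit)
      add_ref(sym, sprintf("shared family %03d", unit), "", "human")
      base <- normalize_symbol(sym)
      a_genes <- list()
      for (k in seq_len(spec$many_one_size)) {
        g <- new_gene("pmin")  # pmin sorts before spur: assigned first
        a_genes[[k]] <- g
        add_calls(g$gene_id, sym, "human", supp())
        add_truth(g, sprintf("%s.%d", base, k), "paralog_suffix",
                  "unnameable", suffix = as.character(k))
      }
      perm <- sample(seq_len(spec$many_one_size))
      for (k in seq_len(spec$many_one_size)) {
        g <- new_gene("spur")
        add_calls(g$gene_id, sym, "human", supp())
        partner <- a_genes[[perm[k]]]
        add_calls(g$gene_id, partner$gene_id, "invertebrate", min_agree)
        add_truth(g, sprintf("%s.%d", base, perm[k]), "paralog_suffix",
                  "unnameable", suffix = as.character(perm[k]))
      }
    }
  }

  # noise pairs: reported by fewer than min_tools tools, so never supported
  if (spec$n_noise > 0L && min_agree > 1L && length(gene_rows)) {
    for (i in seq_len(spec$n_noise)) {
      unit <- unit + 1L
      sym <- sprintf("NSE%03d", unit)
      add_ref(sym, sprintf("noise gene %03d", unit), "", "human")
      q <- gene_rows[[sample.int(length(gene_rows), 1L)]]$gene_id
      add_calls(q, sym, "human", pick1(seq_len(min_agree - 1L)))
    }
  }

  # lay genes on one contig per species and synthesize the genome
  genes <- do.call(rbind, lapply(gene_rows, function(g)
    data.frame(species = g$species, gene_id = g$gene_id,
               entrez_id = g$entrez_id, len = g$len, strand = g$strand,
               product = g$product, stringsAsFactors = FALSE)))
  genes$chrom <- sprintf("%s_scaf1", genes$species)
  genes$start <- NA_integer_
  genes$end <- NA_integer_
  contig_seqs <- list()
  for (sp in species) {
    idx <- which(genes$species == sp)
    cursor <- flank + 101L
    for (j in idx) {
      genes$start[j] <- cursor
      genes$end[j] <- cursor + genes$len[j] - 1L
      cursor <- genes$end[j] + 2L * flank + 201L
    }
    contig_len <- cursor
    contig_seqs[[sprintf("%s_scaf1", sp)]] <- paste(
      sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
      collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(contig_seqs))
  # 1-3 exons per gene: distinct sorted breakpoints give non-overlapping
  # intervals inside the span
  genes$exons <- lapply(seq_len(nrow(genes)), function(j) {
    len <- genes$len[j]
    nex <- sample(1:3, 1L)
    pts <- sort(sample(seq_len(len), 2L * nex))
    m <- matrix(pts, ncol = 2L, byrow = TRUE)
    cbind(start = genes$start[j] + m[, 1L] - 1L,
          end = genes$start[j] + m[, 2L] - 1L)
  })

  reference <- do.call(rbind, ref_rows)
  calls <- do.call(rbind, call_rows)
  calls <- calls[order_c(calls$tool, calls$query_id, calls$subject_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  overrides <- if (length(override_rows)) do.call(rbind, override_rows)
  else empty_overrides()
  legacy <- if (length(legacy_rows)) do.call(rbind, legacy_rows)
  else data.frame(gene_id = character(0), legacy_id = character(0))
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else empty_hits()
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order_c(truth$species, truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  genes <- genes[, c("species", "gene_id", "entrez_id", "chrom", "start",
                     "end", "strand", "product", "exons")]

  out <- list(genes = genes, genome = genome, calls = calls,
              reference = reference, overrides = overrides,
              legacy = legacy, hits = hits, truth = truth,
              spec = spec, seed = as.integer(seed))
  if (!is.null(out_dir)) out$files <- write_cohort(out, out_dir)
  out
}

# serialize a generated cohort as the external formats the readers consume
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "tools"), recursive = TRUE,
             showWarnings = FALSE)
  files <- list()
  for (tl in sort_c(unique(cohort$spec$tools))) {
    tc <- cohort$calls[cohort$calls$tool == tl, , drop = FALSE]
    tab <- data.frame(query = tc$query_id, subject = tc$subject_id,
                      taxon = tc$subject_taxon, stringsAsFactors = FALSE)
    p <- file.path(out_dir, "tools", paste0(tl, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    files$tools[[tl]] <- p
  }
  p <- file.path(out_dir, "reference.tsv")
  ref <- cohort$reference
  utils::write.table(
    data.frame(symbol = ref$symbol, name = ref$full_name,
               stem = ref$family_stem, taxon = ref$taxon),
    p, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  files$reference <- p
  p <- file.path(out_dir, "legacy.tsv")
  utils::write.table(cohort$legacy, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  files$legacy <- p
  p <- file.path(out_dir, "overrides.tsv")
  utils::write.table(cohort$overrides, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  files$overrides <- p
  p <- file.path(out_dir, "hits.tsv")
  h <- cohort$hits
  if (nrow(h)) {
    blast6 <- data.frame(h$query_id, h$subject_id, h$pct_identity,
                         h$aln_length, 0L, 0L, 1L, h$aln_length, 1L,
                         h$aln_length, 0, 0)
    utils::write.table(blast6, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
  } else {
    writeLines(character(0), p)
  }
  files$hits <- p
  files$gff3 <- file.path(out_dir, "genes.gff3")
  files$fasta <- file.path(out_dir, "genome.fa")
  write_gene_models(cohort$genes, cohort$genome, files$gff3, files$fasta)
  p <- file.path(out_dir, "truth.tsv")
  utils::write.table(cohort$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  files$truth <- p
  files
}

#' Write gene models as GFF3 + FASTA
#'
#' @param genes Genes data.frame (with the `exons` list-column).
#' @param genome A [Biostrings::DNAStringSet].
#' @param gff3_path,fasta_path Output paths.
#' @export
write_gene_models <- function(genes, genome, gff3_path, fasta_path) {
  lines <- c("##gff-version 3")
  for (nm in names(genome))
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", nm,
                              Biostrings::width(genome[nm])))
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, ]
    lines <- c(lines, sprintf(
      "%s\techinoname\tgene\t%d\t%d\t.\t%s\t.\tID=%s;entrez_id=%d;product=%s",
      g$chrom, g$start, g$end, g$strand, g$gene_id, g$entrez_id, g$product))
    ex <- g$exons[[1L]]
    for (k in seq_len(nrow(ex)))
      lines <- c(lines, sprintf(
        "%s\techinoname\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$chrom, ex[k, "start"], ex[k, "end"], g$strand, g$gene_id, k,
        g$gene_id))
  }
  writeLines(lines, gff3_path)
  Biostrings::writeXStringSet(genome, fasta_path, width = 80L)
  invisible(gff3_path)
}

#' Generate pseudoduplicate allele sequences with known divergence
#'
#' Each cluster is one source gene model plus diverged copies made by
#' substituting bases at the given per-site rate over the full window
#' (model plus flanks). Copies are planted on the contig so that
#' flank-extraction reproduces each copy's window exactly, and similarity
#' hits are emitted from the realized pairwise identity (alignment length
#' = window length, so coverage is 100%).
#'
#' @param seed Integer seed.
#' @param n_clusters Number of allele clusters.
#' @param divergence Per-site substitution rate, in `[0, 0.5]`; recycled
#'   across clusters, so a sweep can be planted in one call.
#' @param flank_bp Flank size in bases.
#' @param cluster_size Copies per cluster (including the source).
#' @param gene_len Gene-model length in bases.
#' @param out_dir Optional output directory (GFF3, FASTA, hits, truth).
#' @return List with `genes`, `genome`, `hits`, `truth` (per copy: realized
#'   identity to the source and whether the 90/90 rule puts it in-cluster),
#'   and `windows` (named character vector of each gene's true window).
#' @export
generate_pseudodup_sequences <- function(seed, n_clusters = 5L,
                                         divergence = 0.02,
                                         flank_bp = 1000L,
                                         cluster_size = 2L,
                                         gene_len = 1500L,
                                         out_dir = NULL) {
  stopifnot(all(divergence >= 0), all(divergence <= 0.5), cluster_size >= 2L)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))
  div <- rep_len(divergence, n_clusters)
  bases <- c("A", "C", "G", "T")
  wlen <- gene_len + 2L * flank_bp
  spacer <- 100L

  gene_rows <- list()
  hit_rows <- list()
  truth_rows <- list()
  window_rows <- list()
  contigs <- list()
  gno <- 0L
  for (ci in seq_len(n_clusters)) {
    contig <- sprintf("pd_scaf%03d", ci)
    src <- sample(bases, wlen, replace = TRUE)
    windows <- list(src)
    for (k in seq(2L, cluster_size)) {
      w <- src
      mut <- which(stats::runif(wlen) < div[ci])
      if (length(mut))
        w[mut] <- vapply(w[mut], function(b)
          sample(setdiff(bases, b), 1L), "")
      windows[[k]] <- w
    }
    segs <- character(0)
    for (k in seq_len(cluster_size)) {
      gno <- gno + 1L
      offset <- (k - 1L) * (wlen + spacer)
      gene_rows[[gno]] <- data.frame(
        species = "spur",
        gene_id = sprintf("pdfix-g%04d", gno),
        entrez_id = 500000L + gno, chrom = contig,
        start = offset + flank_bp + 1L,
        end = offset + flank_bp + gene_len,
        strand = "+",
        product = sprintf("allele copy %d of cluster %d", k, ci),
        stringsAsFactors = FALSE)
      segs <- c(segs, paste(windows[[k]], collapse = ""),
                paste(sample(bases, spacer, replace = TRUE),
                      collapse = ""))
    }
    contigs[[contig]] <- paste(segs, collapse = "")
    ids <- vapply(gene_rows[seq(gno - cluster_size + 1L, gno)],
                  function(g) g$gene_id, "")
    pidm <- matrix(100, cluster_size, cluster_size)
    for (a in seq_len(cluster_size - 1L)) {
      for (b in seq(a + 1L, cluster_size)) {
        pid <- 100 * sum(windows[[a]] == windows[[b]]) / wlen
        pidm[a, b] <- pidm[b, a] <- pid
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          query_id = ids[a], subject_id = ids[b],
          pct_identity = pid, aln_length = wlen,
          q_len = wlen, s_len = wlen, stringsAsFactors = FALSE)
      }
    }
    # coverage is 100% by construction, so the 90/90 rule reduces to the
    # realized identity; a copy is in-cluster iff it passes with >= 1 other
    pass <- pidm >= 90
    diag(pass) <- FALSE
    for (k in seq_len(cluster_size)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        gene_id = ids[k], cluster_index = ci, copy_index = k,
        divergence = div[ci], identity_to_source = pidm[1L, k],
        in_cluster = any(pass[k, ]),
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(cluster_size))
      window_rows[[length(window_rows) + 1L]] <-
        stats::setNames(paste(windows[[k]], collapse = ""), ids[k])
  }
  genes <- do.call(rbind, gene_rows)
  genes$exons <- lapply(seq_len(nrow(genes)), function(j)
    cbind(start = genes$start[j], end = genes$end[j]))
  genome <- Biostrings::DNAStringSet(unlist(contigs))
  hits <- do.call(rbind, hit_rows)
  truth <- do.call(rbind, truth_rows)
  window_seqs <- unlist(window_rows)

  out <- list(genes = genes, genome = genome, hits = hits, truth = truth,
              windows = window_seqs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    gff3 <- file.path(out_dir, "pd_genes.gff3")
    fasta <- file.path(out_dir, "pd_genome.fa")
    write_gene_models(genes, genome, gff3, fasta)
    hp <- file.path(out_dir, "pd_hits.tsv")
    blast6 <- data.frame(hits$query_id, hits$subject_id,
                         round(hits$pct_identity, 3), hits$aln_length,
                         0L, 0L, 1L, hits$aln_length, 1L, hits$aln_length,
                         0, 0)
    utils::write.table(blast6, hp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, eol = "\n")
    tp <- file.path(out_dir, "pd_truth.tsv")
    utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    out$files <- list(gff3 = gff3, fasta = fasta, hits = hp, truth = tp)
  }
  out
}
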