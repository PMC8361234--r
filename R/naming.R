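# The naming cascade: orthology groups, pseudoduplicate clusters, the
# reference table and curator overrides in; one Assignment per gene out.
# Symbols are lower case and machine readable: Greek letters become single
# Latin letters, trailing Roman numerals become Arabic digits, and the only
# separators allowed are "." (suffixes) and "-".

# Greek transliteration, HGNC-style single Latin letters
.greek_char <- c(
  "α" = "a", "β" = "b", "γ" = "g", "δ" = "d",
  "ε" = "e", "ζ" = "z", "η" = "h", "θ" = "t",
  "ι" = "i", "κ" = "k", "λ" = "l", "μ" = "m",
  "ν" = "n", "ξ" = "x", "ο" = "o", "π" = "p",
  "ρ" = "r", "σ" = "s", "ς" = "s", "τ" = "t",
  "υ" = "u", "φ" = "f", "χ" = "c", "ψ" = "y",
  "ω" = "w",
  "Α" = "a", "Β" = "b", "Γ" = "g", "Δ" = "d",
  "Ε" = "e", "Ζ" = "z", "Η" = "h", "Θ" = "t",
  "Ι" = "i", "Κ" = "k", "Λ" = "l", "Μ" = "m",
  "Ν" = "n", "Ξ" = "x", "Ο" = "o", "Π" = "p",
  "Ρ" = "r", "Σ" = "s", "Τ" = "t", "Υ" = "u",
  "Φ" = "f", "Χ" = "c", "Ψ" = "y", "Ω" = "w")

.greek_word <- c(alpha = "a", beta = "b", gamma = "g", delta = "d",
                 epsilon = "e", zeta = "z", eta = "h", theta = "t",
                 iota = "i", kappa = "k", lambda = "l", mu = "m", nu = "n",
                 xi = "x", omicron = "o", pi = "p", rho = "r", sigma = "s",
                 tau = "t", upsilon = "u", phi = "f", chi = "c", psi = "y",
                 omega = "w")

# single-character maps collapse to one chartr() call
.greek_from <- paste(names(.greek_char), collapse = "")
.greek_to <- paste(.greek_char, collapse = "")

# canonical subtractive Roman numerals for 1..20
.roman_table <- local({
  v <- as.character(utils::as.roman(1:20))
  stats::setNames(1:20, v)
})

#' Convert a canonical Roman-numeral token to an integer
#'
#' Only canonical subtractive forms for 1-20 convert ("IV", not "IIII");
#' anything else is a no-conversion, returned as `NA`. Case-insensitive.
#'
#' @param token Character vector of tokens.
#' @return Integer vector; `NA` where the token is not a canonical numeral.
#' @export
roman_to_arabic <- function(token) {
  v <- .roman_table[toupper(token)]
  as.integer(unname(v))
}

#' Normalize a raw identifier into a machine-readable gene symbol
#'
#' Lowercases, transliterates Greek letters to single Latin letters, maps
#' whitespace and disallowed characters to "-" (collapsing runs), converts
#' a trailing standalone Roman-numeral token (I-XX) to Arabic digits and a
#' trailing standalone spelled-out Greek-letter token to its single letter
#' (both joined to the preceding token without a separator), and strips
#' leading/trailing separators. Idempotent: normalizing a normalized symbol
#' is a no-op. "." is preserved so suffixes survive normalization.
#'
#' @param raw Non-empty character scalar.
#' @return The normalized symbol.
#' @export
normalize_symbol <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(trimws(raw))) stop("cannot normalize an empty identifier")
  x <- chartr(.greek_from, .greek_to, raw)
  x <- tolower(x)
  x <- gsub("[^a-z0-9.-]+", "-", x)
  x <- gsub("-{2,}", "-", x)
  x <- gsub("\\.{2,}", ".", x)
  x <- gsub("^[-.]+|[-.]+$", "", x)
  if (!nzchar(x))
    stop(sprintf("identifier %s normalizes to the empty string", dQuote(raw)))
  tokens <- strsplit(x, "-", fixed = TRUE)[[1L]]
  n <- length(tokens)
  if (n >= 2L) {
    last <- tokens[n]
    repl <- NULL
    if (last %in% names(.greek_word)) {
      repl <- unname(.greek_word[[last]])
    } else {
      ra <- roman_to_arabic(last)
      if (!is.na(ra)) repl <- as.character(ra)
    }
    if (!is.null(repl)) {
      x <- paste0(paste(tokens[-n], collapse = "-"), repl)
    }
  }
  x
}

# does a string satisfy the machine-readable symbol pattern?
is_valid_symbol <- function(x) {
  grepl("^[a-z0-9][a-z0-9.-]*$", x) & !grepl("[.-]$", x)
}

# family stem: reference-table stem when present, else the normalized
# symbol with trailing Arabic digits stripped
stem_of <- function(ref_row) {
  if (!is.na(ref_row$family_stem) && nzchar(ref_row$family_stem))
    return(normalize_symbol(ref_row$family_stem))
  s <- sub("[0-9]+$", "", normalize_symbol(ref_row$symbol))
  if (!nzchar(s)) normalize_symbol(ref_row$symbol) else s
}

#' Family stems of every human reference symbol
#'
#' Uses the table's `stem` column when present, else derives the stem by
#' stripping trailing Arabic digits from the normalized symbol.
#'
#' @param reference Reference gene data.frame.
#' @return Named character vector: human symbol -> normalized stem.
#' @export
reference_stems <- function(reference) {
  humans <- reference[reference$taxon == "human", , drop = FALSE]
  stats::setNames(
    vapply(seq_len(nrow(humans)), function(i)
      stem_of(humans[i, , drop = FALSE]), ""),
    humans$symbol)
}

ref_row <- function(reference, symbol, taxon = "human") {
  i <- which(reference$symbol == symbol & reference$taxon == taxon)
  if (!length(i))
    stop(sprintf("reference symbol %s (taxon %s) missing from table",
                 symbol, taxon))
  reference[i[1L], , drop = FALSE]
}

new_assignment <- function(gene_id, species, symbol, full_name, rule_fired,
                           chosen_ortholog = NA_character_,
                           support_count = NA_integer_,
                           pseudodup_cluster = NA_character_,
                           suffix = NA_character_,
                           synonyms = character(0),
                           legacy_ids = character(0)) {
  out <- data.frame(gene_id = gene_id, species = species, symbol = symbol,
                    full_name = full_name, rule_fired = rule_fired,
                    chosen_ortholog = chosen_ortholog,
                    support_count = as.integer(support_count),
                    pseudodup_cluster = pseudodup_cluster,
                    suffix = suffix, stringsAsFactors = FALSE)
  out$synonyms <- list(synonyms)
  out$legacy_ids <- list(legacy_ids)
  out
}

#' Assign the human identifier to a one:one gene
#'
#' The straightforward case: a single echinoderm gene orthologous to a
#' single human gene takes that gene's identifier (normalized symbol plus
#' the human full name).
#'
#' @param group A `one_one` orthology group.
#' @param reference Reference gene data.frame.
#' @return A one-row assignment data.frame.
#' @export
assign_one_to_one <- function(group, reference) {
  stopifnot(group$topology == "one_one")
  sym <- group$ref_members[1L]
  rr <- ref_row(reference, sym)
  new_assignment(gene_id = group$echino_members[1L],
                 species = NA_character_,
                 symbol = normalize_symbol(sym),
                 full_name = rr$full_name,
                 rule_fired = "one_one",
                 chosen_ortholog = sym,
                 support_count = max(group$edge_support$support_count))
}

#' Choose one ortholog for a one:many gene
#'
#' The tie-break cascade for a gene with several human co-orthologs:
#' \enumerate{
#' \item the candidate supported by the most tools, if unique
#'   (`one_many_support`);
#' \item on a tie, if all tied candidates share one family stem and no
#'   member of that family has a supported edge to a gene of another
#'   echinoderm species in the input, the stem itself becomes the symbol
#'   (`one_many_stem`);
#' \item a curator override for the gene, if present (`one_many_curator`);
#' \item otherwise the first tied candidate in byte order of normalized
#'   symbols (`one_many_alpha`).
#' }
#'
#' @param candidates data.frame with columns `symbol`, `support_count`
#'   (one row per human candidate).
#' @param reference Reference gene data.frame.
#' @param overrides Curator override data.frame ([read_overrides()]).
#' @param gene_id The echinoderm gene being named (override lookup key).
#' @param foreign_ref_symbols Reference symbols having a supported edge to
#'   a gene of *another* echinoderm species in the input (blocks the stem
#'   rule for their families).
#' @param human_stems Optional precomputed named vector human reference
#'   symbol -> family stem (see [reference_stems()]); computed on the fly
#'   when absent.
#' @return List with `symbol` (normalized), `full_name`, `rule`, `chosen`
#'   (the winning reference symbol, or the stem), `support_count`.
#' @export
choose_ortholog <- function(candidates, reference,
                            overrides = empty_overrides(),
                            gene_id = NA_character_,
                            foreign_ref_symbols = character(0),
                            human_stems = NULL) {
  stopifnot(nrow(candidates) >= 2L)
  mx <- max(candidates$support_count)
  tied <- candidates$symbol[candidates$support_count == mx]
  if (length(tied) == 1L) {
    rr <- ref_row(reference, tied)
    return(list(symbol = normalize_symbol(tied), full_name = rr$full_name,
                rule = "one_many_support", chosen = tied,
                support_count = mx))
  }
  tied <- sort_c(tied)
  if (is.null(human_stems)) human_stems <- reference_stems(reference)
  stems <- unname(human_stems[tied])
  if (length(unique(stems)) == 1L && nzchar(stems[1L])) {
    stem <- stems[1L]
    family <- names(human_stems)[human_stems == stem]
    if (!any(family %in% foreign_ref_symbols)) {
      return(list(symbol = stem,
                  full_name = sprintf("%s family", stem),
                  rule = "one_many_stem", chosen = stem,
                  support_count = mx))
    }
  }
  if (!is.na(gene_id) && gene_id %in% overrides$gene_id) {
    ov <- overrides[overrides$gene_id == gene_id, , drop = FALSE][1L, ]
    return(list(symbol = ov$forced_symbol, full_name = ov$forced_name,
                rule = "one_many_curator", chosen = ov$forced_symbol,
                support_count = mx))
  }
  norm <- vapply(tied, normalize_symbol, "")
  first <- tied[order_c(norm)][1L]
  rr <- ref_row(reference, first)
  list(symbol = normalize_symbol(first), full_name = rr$full_name,
       rule = "one_many_alpha", chosen = first, support_count = mx)
}

#' Letter-suffix the members of a pseudoduplicate cluster
#'
#' Members sorted by gene_id (case-insensitive, ties by byte order) receive
#' `base.a`, `base.b`, ... continuing `aa`, `ab` after `z`. The letters
#' carry no orthology meaning and are independent between species.
#'
#' @param members Character vector of cluster gene ids (>= 2).
#' @param base_symbol Normalized base symbol shared by the cluster.
#' @param base_name Full name of the base.
#' @param species Species tag.
#' @param cluster_id Identifier recorded in the `pseudodup_cluster` field.
#' @return Assignment data.frame, one row per member.
#' @export
assign_pseudodup_suffixes <- function(members, base_symbol, base_name,
                                      species = NA_character_,
                                      cluster_id = NA_character_) {
  if (length(members) < 2L)
    stop("a pseudoduplicate cluster needs >= 2 members")
  ord <- members[order_c(tolower(members), members)]
  do.call(rbind, lapply(seq_along(ord), function(i) {
    suf <- letter_suffix(i)
    new_assignment(gene_id = ord[i], species = species,
                   symbol = paste0(base_symbol, ".", suf),
                   full_name = sprintf("%s pseudoduplicate %s",
                                       base_name, suf),
                   rule_fired = "pseudodup_suffix",
                   chosen_ortholog = base_symbol,
                   pseudodup_cluster = cluster_id,
                   suffix = suf)
  }))
}

#' Number-suffix a set of echinoderm paralogs
#'
#' Members of a many:one (or resolved many:many) group receive `base.1`,
#' `base.2`, ... A member holding a supported one:one cross-species link to
#' an already-suffixed ortholog in another input species inherits that
#' suffix number; remaining members take the lowest unused numbers in
#' gene_id sort order. If two members claim the same inherited number both
#' fall back to fresh numbers (logged).
#'
#' @param members Character vector of paralog gene ids.
#' @param base_symbol Normalized base symbol (the resolved human ortholog
#'   or stem).
#' @param base_name Full name of the base.
#' @param chosen Reference symbol recorded as `chosen_ortholog`.
#' @param species Species tag.
#' @param inherited Named integer vector gene_id -> suffix number claimed
#'   through a cross-species link (may be empty).
#' @param support Named integer vector gene_id -> support count (optional).
#' @return Assignment data.frame, one row per member.
#' @export
assign_paralog_suffixes <- function(members, base_symbol, base_name,
                                    chosen = base_symbol,
                                    species = NA_character_,
                                    inherited = integer(0),
                                    support = integer(0)) {
  stopifnot(length(members) >= 1L)
  inherited <- inherited[names(inherited) %in% members]
  if (length(inherited)) {
    dup_num <- unique(inherited[duplicated(inherited)])
    if (length(dup_num)) {
      clash <- names(inherited)[inherited %in% dup_num]
      log_msg("suffix inheritance conflict for %s on base %s; using fresh numbers",
              paste(clash, collapse = ", "), base_symbol)
      inherited <- inherited[!names(inherited) %in% clash]
    }
  }
  nums <- stats::setNames(rep(NA_integer_, length(members)), members)
  nums[names(inherited)] <- inherited
  fresh <- sort_c(members[is.na(nums)])
  pool <- setdiff(seq_len(length(members) + length(inherited)),
                  unname(inherited))
  nums[fresh] <- pool[seq_along(fresh)]
  do.call(rbind, lapply(members[order_c(members)], function(m) {
    k <- nums[[m]]
    new_assignment(gene_id = m, species = species,
                   symbol = paste0(base_symbol, ".", k),
                   full_name = sprintf("%s paralog %d", base_name, k),
                   rule_fired = "paralog_suffix",
                   chosen_ortholog = chosen,
                   support_count = if (m %in% names(support))
                     support[[m]] else NA_integer_,
                   suffix = as.character(k))
  }))
}

#' LOC fallback identifier for genes without a qualifying ortholog
#'
#' Symbol is "loc" plus the Entrez ID (lowercased to satisfy the symbol
#' rules; the uppercase NCBI form is kept as a synonym), and the full name
#' is the annotation's predicted-product name.
#'
#' @param gene One gene row (needs `gene_id`, `species`, `entrez_id`,
#'   optionally `product`).
#' @return A one-row assignment data.frame.
#' @export
loc_fallback <- function(gene) {
  if (is.null(gene$entrez_id) || is.na(gene$entrez_id))
    stop(sprintf(
      "gene %s has no entrez_id; provide one via the GFF3 entrez_id attribute to enable LOC fallback",
      gene$gene_id))
  ez <- as.integer(gene$entrez_id)
  prod <- gene$product
  if (is.null(prod) || is.na(prod) || !nzchar(prod))
    prod <- "uncharacterized protein"
  new_assignment(gene_id = gene$gene_id,
                 species = gene$species %||% NA_character_,
                 symbol = paste0("loc", ez),
                 full_name = prod,
                 rule_fired = "loc_fallback",
                 synonyms = paste0("LOC", ez))
}

#' Render a symbol with its most recent previous symbol in parentheses
#'
#' @param assignment A one-row assignment data.frame.
#' @return `"current (previous)"` if a legacy symbol exists, else the
#'   current symbol alone.
#' @export
render_with_previous <- function(assignment) {
  legacy <- assignment$legacy_ids[[1L]]
  if (length(legacy) == 0L) return(assignment$symbol)
  sprintf("%s (%s)", assignment$symbol, legacy[length(legacy)])
}

#' Run the full naming cascade over a cohort
#'
#' Dispatch per gene, in this order: membership in a pseudoduplicate
#' cluster whose consensus human ortholog is resolvable gives a letter
#' suffix; otherwise the gene's human-stratum orthology-group topology
#' decides -- one:one takes the human identifier, one:many goes through
#' the tie-break cascade, many:one and many:many get numeric paralog
#' suffixes, and orphans (including genes whose only orthologs are
#' non-human, per current policy) fall back to LOC identifiers. Species
#' are processed in sorted order so later species can inherit paralog
#' suffix numbers over supported cross-species links. Species-wide symbol
#' uniqueness is enforced with deterministic numeric disambiguation.
#'
#' @param cohort List with elements `genes` (data.frame of all species'
#'   genes), `calls` (ortholog calls), `reference`, and optionally
#'   `overrides`, `clusters` (from [cluster_pseudoduplicates()]), `legacy`
#'   (from [read_legacy_table()]).
#' @param config A [nomenclature_config()].
#' @return Assignments data.frame, one row per input gene, sorted by
#'   species then gene_id.
#' @export
assign_identifiers <- function(cohort, config = nomenclature_config()) {
  genes <- cohort$genes
  reference <- cohort$reference
  overrides <- cohort$overrides %||% empty_overrides()
  clusters <- cohort$clusters %||% list()
  legacy <- cohort$legacy %||%
    data.frame(gene_id = character(0), legacy_id = character(0))

  hstems <- reference_stems(reference)
  edges <- tally_support(cohort$calls, config)
  sup <- edges[edges$supported, , drop = FALSE]
  species_of <- stats::setNames(genes$species, genes$gene_id)

  # cross-species echinoderm-echinoderm links: supported edges whose subject
  # is another input species' gene
  is_cross <- sup$subject_id %in% genes$gene_id &
    species_of[sup$query_id] != species_of[sup$subject_id]
  cross <- sup[!is.na(is_cross) & is_cross, , drop = FALSE]

  # reference symbols with supported edges from each species (stem-rule veto)
  ref_sup <- sup[sup$subject_taxon == "human" &
                   !(sup$subject_id %in% genes$gene_id), , drop = FALSE]

  all_species <- sort_c(unique(genes$species))
  assigned <- list()

  for (sp in all_species) {
    sp_genes <- genes[genes$species == sp, , drop = FALSE]
    sp_ids <- sp_genes$gene_id
    human_edges <- ref_sup[ref_sup$query_id %in% sp_ids, , drop = FALSE]
    groups <- classify_topology(human_edges, sp_ids)
    # symbols seen from species other than sp (blocks the stem rule)
    foreign_syms <- unique(ref_sup$subject_id[
      species_of[ref_sup$query_id] != sp])

    done <- character(0)
    sp_assign <- list()
    emit <- function(a) {
      a$species <- sp
      sp_assign[[length(sp_assign) + 1L]] <<- a
      done <<- c(done, a$gene_id)
    }

    # --- pseudoduplicate clusters first
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      members <- intersect(cl$members, sp_ids)
      if (length(members) < 2L) next
      cand_edges <- human_edges[human_edges$query_id %in% members, ,
                                drop = FALSE]
      if (nrow(cand_edges) == 0L) next  # no human ortholog: fall through
      agg <- stats::aggregate(support_count ~ subject_id, cand_edges, max)
      cand <- data.frame(symbol = agg$subject_id,
                         support_count = agg$support_count,
                         stringsAsFactors = FALSE)
      if (nrow(cand) == 1L) {
        rr <- ref_row(reference, cand$symbol)
        base <- list(symbol = normalize_symbol(cand$symbol),
                     full_name = rr$full_name, chosen = cand$symbol)
      } else {
        res <- choose_ortholog(cand, reference, overrides,
                               gene_id = sort_c(members)[1L],
                               foreign_ref_symbols = foreign_syms,
                               human_stems = hstems)
        base <- list(symbol = res$symbol, full_name = res$full_name,
                     chosen = res$chosen)
      }
      a <- assign_pseudodup_suffixes(members, base$symbol, base$full_name,
                                     species = sp,
                                     cluster_id = sprintf("pd%04d", ci))
      a$chosen_ortholog <- base$chosen
      for (k in seq_len(nrow(a))) emit(a[k, , drop = FALSE])
    }

    # paralog suffixes already assigned in earlier species, for inheritance
    prior <- if (length(assigned)) do.call(rbind, assigned) else NULL
    prior_suffix <- if (!is.null(prior)) {
      p <- prior[prior$rule_fired == "paralog_suffix", , drop = FALSE]
      stats::setNames(as.integer(p$suffix), p$gene_id)
    } else integer(0)
    prior_base <- if (!is.null(prior)) {
      p <- prior[prior$rule_fired == "paralog_suffix", , drop = FALSE]
      stats::setNames(sub("\\.[0-9]+$", "", p$symbol), p$gene_id)
    } else character(0)

    # --- topology dispatch
    for (grp in groups) {
      members <- setdiff(grp$echino_members, done)
      if (!length(members)) next
      if (grp$topology == "one_one") {
        a <- assign_one_to_one(grp, reference)
        emit(a)
      } else if (grp$topology == "one_many") {
        gid <- grp$echino_members[1L]
        es <- grp$edge_support
        cand <- data.frame(symbol = es$symbol,
                           support_count = es$support_count,
                           stringsAsFactors = FALSE)
        res <- choose_ortholog(cand, reference, overrides, gene_id = gid,
                               foreign_ref_symbols = foreign_syms,
                               human_stems = hstems)
        emit(new_assignment(gene_id = gid, species = sp,
                            symbol = res$symbol, full_name = res$full_name,
                            rule_fired = res$rule,
                            chosen_ortholog = res$chosen,
                            support_count = res$support_count))
      } else if (grp$topology %in% c("many_one", "many_many")) {
        es <- grp$edge_support
        if (grp$topology == "many_one") {
          sym <- grp$ref_members[1L]
          rr <- ref_row(reference, sym)
          base <- list(symbol = normalize_symbol(sym),
                       full_name = rr$full_name, chosen = sym)
        } else {
          agg <- stats::aggregate(support_count ~ symbol,
                                  stats::setNames(es[, c("symbol", "support_count")],
                                                  c("symbol", "support_count")),
                                  max)
          res <- choose_ortholog(
            data.frame(symbol = agg$symbol, support_count = agg$support_count,
                       stringsAsFactors = FALSE),
            reference, overrides, gene_id = sort_c(members)[1L],
            foreign_ref_symbols = foreign_syms, human_stems = hstems)
          base <- list(symbol = res$symbol, full_name = res$full_name,
                       chosen = res$chosen)
        }
        # suffix inheritance over supported one:one cross-species links
        inherited <- integer(0)
        if (nrow(cross)) {
          for (m in members) {
            link <- cross$subject_id[cross$query_id == m]
            if (length(link) != 1L) next
            if (link %in% names(prior_suffix) &&
                identical(prior_base[[link]], base$symbol)) {
              inherited[m] <- prior_suffix[[link]]
            }
          }
        }
        supv <- stats::setNames(
          vapply(members, function(m)
            max(es$support_count[es$gene_id == m]), integer(1)),
          members)
        a <- assign_paralog_suffixes(members, base$symbol, base$full_name,
                                     chosen = base$chosen, species = sp,
                                     inherited = inherited, support = supv)
        for (k in seq_len(nrow(a))) emit(a[k, , drop = FALSE])
      } else {
        # orphan in the human stratum: LOC fallback
        g <- sp_genes[sp_genes$gene_id == members[1L], , drop = FALSE]
        emit(loc_fallback(g))
      }
    }

    out <- do.call(rbind, sp_assign)
    missing <- setdiff(sp_ids, out$gene_id)
    if (length(missing))
      stop("unassigned gene(s): ", paste(missing, collapse = ", "))

    # species-wide uniqueness: deterministic numeric disambiguation
    out <- out[order_c(out$gene_id), , drop = FALSE]
    dup <- duplicated(out$symbol)
    if (any(dup)) {
      log_msg("symbol collision(s) in %s: %s; disambiguating numerically",
              sp, paste(unique(out$symbol[dup]), collapse = ", "))
      for (s in unique(out$symbol[dup])) {
        idx <- which(out$symbol == s)
        for (k in seq_along(idx)[-1L]) {
          cand <- paste0(s, "-", k)
          while (cand %in% out$symbol) {
            k <- k + 1L
            cand <- paste0(s, "-", k)
          }
          out$symbol[idx[k]] <- cand
        }
      }
    }
    assigned[[length(assigned) + 1L]] <- out
  }

  res <- do.call(rbind, assigned)
  # attach legacy synonyms; auto synonyms (LOC form) come first, legacy
  # identifiers after in chronological order, so the last synonym is the
  # most recent previous symbol
  for (i in seq_len(nrow(res))) {
    lg <- legacy$legacy_id[legacy$gene_id == res$gene_id[i]]
    if (length(lg)) {
      res$synonyms[[i]] <- c(res$synonyms[[i]], lg)
      res$legacy_ids[[i]] <- lg
    }
  }
  bad <- !is_valid_symbol(res$symbol)
  if (any(bad))
    stop("internal error: non-machine-readable symbol(s) emitted: ",
         paste(res$symbol[bad], collapse = ", "))
  res <- res[order_c(res$species, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
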