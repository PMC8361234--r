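# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths and the libraries it leans on (igraph), so a
# green comparison is meaningful.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# brute-force distinct-tool tally
oracle_tally <- function(calls) {
  keys <- unique(paste(calls$query_id, calls$subject_id, sep = "\t"))
  out <- lapply(keys, function(k) {
    p <- strsplit(k, "\t", fixed = TRUE)[[1]]
    sel <- calls$query_id == p[1] & calls$subject_id == p[2]
    data.frame(query_id = p[1], subject_id = p[2],
               support_count = length(unique(calls$tool[sel])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# union-find connected components over an edge list of character vertices
oracle_components <- function(from, to) {
  verts <- unique(c(from, to))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(verts, find, "")
  split(verts, roots)
}

# breadth-first-search connected components (second independent route)
oracle_bfs_components <- function(from, to) {
  verts <- unique(c(from, to))
  adj <- lapply(stats::setNames(verts, verts), function(v)
    unique(c(to[from == v], from[to == v])))
  seen <- character(0)
  comps <- list()
  for (v in verts) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# additive-notation Roman numeral table for 1..20, written out by hand
oracle_roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                  "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
                  "XVIII", "XIX", "XX")

# half-up percentage by string long division: digits of 100*n/d computed
# in integer arithmetic, rounded half-up at `decimals` by inspecting the
# next digit and propagating the carry through the digit string
oracle_percent <- function(n, d, decimals) {
  num <- n * 100
  ip <- num %/% d
  rem <- num %% d
  digits <- integer(decimals + 1)
  for (i in seq_len(decimals + 1)) {
    rem <- rem * 10
    digits[i] <- rem %/% d
    rem <- rem %% d
  }
  if (digits[decimals + 1] >= 5) {
    # carry
    if (decimals == 0) {
      ip <- ip + 1
    } else {
      i <- decimals
      digits[i] <- digits[i] + 1
      while (i > 1 && digits[i] == 10) {
        digits[i] <- 0
        digits[i - 1] <- digits[i - 1] + 1
        i <- i - 1
      }
      if (digits[1] == 10) {
        digits[1] <- 0
        ip <- ip + 1
      }
    }
  }
  if (decimals == 0) return(sprintf("%d%%", ip))
  sprintf("%d.%s%%", ip, paste(digits[seq_len(decimals)], collapse = ""))
}

# direct re-statement of the one:many cascade, independent of the
# package's implementation details
oracle_cascade <- function(candidates, stems, override_symbol = NULL,
                           family_blocked = FALSE) {
  mx <- max(candidates$support_count)
  tied <- sort(candidates$symbol[candidates$support_count == mx],
               method = "radix")
  if (length(tied) == 1) return(list(symbol = tolower(tied),
                                     rule = "one_many_support"))
  st <- unique(stems[tied])
  if (length(st) == 1 && !family_blocked)
    return(list(symbol = st, rule = "one_many_stem"))
  if (!is.null(override_symbol))
    return(list(symbol = override_symbol, rule = "one_many_curator"))
  norm <- tolower(tied)
  list(symbol = sort(norm, method = "radix")[1], rule = "one_many_alpha")
}

# small helper to build call data.frames tersely
mk_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(tool = r[1], query_id = r[2], subject_id = r[3],
               subject_taxon = if (length(r) > 3) r[4] else "human",
               stringsAsFactors = FALSE)))
}

mk_reference <- function(symbols, names = paste("gene", symbols),
                         stems = NA_character_, taxon = "human") {
  data.frame(symbol = symbols, full_name = names,
             family_stem = rep_len(stems, length(symbols)),
             taxon = rep_len(taxon, length(symbols)),
             stringsAsFactors = FALSE)
}

# the branch-count spec used by the end-to-end acceptance cohorts
acceptance_spec <- function(n_species = 1L) {
  cohort_spec(n_one_one = 150L, n_one_many_support = 40L,
              n_one_many_stem = 30L, n_one_many_curator = 20L,
              n_one_many_alpha = 40L, n_many_one = 30L, n_many_many = 15L,
              n_pseudodup = 20L, n_vertebrate_one_one = 40L,
              n_invertebrate_only = 40L, n_orphan = 35L, n_noise = 20L,
              n_species = n_species,
              n_shared_paralog = if (n_species == 2L) 5L else 0L)
}

run_cohort <- function(co, config = nomenclature_config()) {
  clusters <- cluster_pseudoduplicates(co$hits, config)
  assign_identifiers(list(genes = co$genes, calls = co$calls,
                          reference = co$reference,
                          overrides = co$overrides,
                          clusters = clusters, legacy = co$legacy),
                     config)
}
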