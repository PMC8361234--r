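test_that("normalize_symbol handles Greek, Roman numerals and case", {
  expect_equal(normalize_symbol("TGFβ2"), "tgfb2")
  expect_equal(normalize_symbol("Pax VI"), "pax6")
  expect_equal(normalize_symbol("FOXA2"), "foxa2")
  expect_equal(normalize_symbol("Wnt-8"), "wnt-8")
  expect_equal(normalize_symbol("tgf alpha"), "tgfa")
  expect_equal(normalize_symbol("msp130 IV"), "msp1304")  # trailing token
  expect_equal(normalize_symbol("Delta/Notch"), "delta-notch")
  expect_equal(normalize_symbol("fgf8.1"), "fgf8.1")      # suffix survives
  expect_error(normalize_symbol("  "), "empty")
  expect_error(normalize_symbol("__"), "empty")
})

test_that("normalize_symbol is idempotent on a 500-case battery", {
  set.seed(3)
  greek <- c("α", "β", "γ", "Δ", "κ")
  pieces <- c(LETTERS, letters, as.character(0:9), greek,
              " ", "-", "_", "/", ".", "alpha", "beta", "IV", "XII", "ii")
  battery <- vapply(1:500, function(i)
    paste(sample(pieces, sample(2:8, 1), replace = TRUE), collapse = ""),
    character(1))
  battery <- battery[vapply(battery, function(x)
    !inherits(try(normalize_symbol(x), silent = TRUE), "try-error"),
    logical(1))]
  expect_gt(length(battery), 400)
  for (x in battery) {
    n1 <- normalize_symbol(x)
    expect_identical(normalize_symbol(n1), n1, info = x)
    expect_true(grepl("^[a-z0-9][a-z0-9.-]*$", n1), info = x)
  }
})

test_that("roman_to_arabic matches the hand-written additive table for 1-20", {
  for (i in 1:20) {
    expect_equal(roman_to_arabic(oracle_roman[i]), i, info = oracle_roman[i])
    expect_equal(roman_to_arabic(tolower(oracle_roman[i])), i)
  }
  expect_true(is.na(roman_to_arabic("IIII")))  # non-canonical
  expect_true(is.na(roman_to_arabic("XXI")))   # out of range
  expect_true(is.na(roman_to_arabic("abc")))
  # vectorized
  expect_equal(roman_to_arabic(c("IV", "zz", "X")), c(4L, NA, 10L))
})

test_that("one:one groups take the human identifier; legacy ids become synonyms", {
  ref <- mk_reference(c("FOXA2", "NODAL"),
                      names = c("forkhead box A2", "nodal growth factor"))
  grp <- list(echino_members = "g1", ref_members = "FOXA2",
              topology = "one_one",
              edge_support = data.frame(gene_id = "g1", symbol = "FOXA2",
                                        support_count = 4L))
  a <- assign_one_to_one(grp, ref)
  expect_equal(a$symbol, "foxa2")
  expect_equal(a$full_name, "forkhead box A2")
  expect_equal(a$rule_fired, "one_one")
  expect_equal(a$support_count, 4L)
  bad <- grp; bad$ref_members <- "MISSING"
  expect_error(assign_one_to_one(bad, ref), "missing from table")

  # through the full cascade, legacy ids surface as synonyms
  genes <- data.frame(species = "spur", gene_id = "g2", entrez_id = 1L,
                      chrom = "c", start = 1L, end = 10L, strand = "+",
                      product = "x", stringsAsFactors = FALSE)
  calls <- mk_calls(c("t1", "g2", "NODAL"), c("t2", "g2", "NODAL"),
                    c("t3", "g2", "NODAL"))
  a2 <- assign_identifiers(list(
    genes = genes, calls = calls, reference = ref,
    legacy = data.frame(gene_id = "g2", legacy_id = "Sp-Nodal")))
  expect_equal(a2$symbol, "nodal")
  expect_true("Sp-Nodal" %in% a2$synonyms[[1]])
  expect_equal(render_with_previous(a2[1, ]), "nodal (Sp-Nodal)")
})

test_that("the one:many cascade fires rules in order", {
  ref <- rbind(mk_reference(c("FGF8", "FGF17", "FGF18"), stems = "fgf"),
               mk_reference(c("BMP2", "WNT5")))
  cand <- function(syms, sup) data.frame(symbol = syms, support_count = sup,
                                         stringsAsFactors = FALSE)
  r <- choose_ortholog(cand(c("FGF8", "FGF17"), c(5L, 3L)), ref)
  expect_equal(r[c("symbol", "rule")], list(symbol = "fgf8",
                                            rule = "one_many_support"))
  r <- choose_ortholog(cand(c("FGF8", "FGF17", "FGF18"), c(4L, 4L, 4L)), ref)
  expect_equal(r[c("symbol", "rule")], list(symbol = "fgf",
                                            rule = "one_many_stem"))
  # a family member seen from another species blocks the stem rule
  r <- choose_ortholog(cand(c("FGF8", "FGF17", "FGF18"), c(4L, 4L, 4L)), ref,
                       foreign_ref_symbols = "FGF17")
  expect_equal(r$rule, "one_many_alpha")
  expect_equal(r$symbol, "fgf17")  # byte order: fgf17 < fgf18 < fgf8
  ov <- data.frame(gene_id = "g9", forced_symbol = "bmpx",
                   forced_name = "curated bmp", note = "")
  r <- choose_ortholog(cand(c("BMP2", "WNT5"), c(4L, 4L)), ref,
                       overrides = ov, gene_id = "g9")
  expect_equal(r[c("symbol", "rule")], list(symbol = "bmpx",
                                            rule = "one_many_curator"))
  r <- choose_ortholog(cand(c("BMP2", "WNT5"), c(4L, 4L)), ref)
  expect_equal(r[c("symbol", "rule")], list(symbol = "bmp2",
                                            rule = "one_many_alpha"))
})

test_that("the cascade matches a direct re-statement on 200 random groups", {
  set.seed(12)
  syms <- sprintf("RG%02d%s", rep(1:20, each = 3), c("A", "B", "C"))
  stems <- sprintf("rg%02d", rep(1:20, each = 3))
  ref <- mk_reference(syms, stems = NA)
  ref$family_stem <- stems
  stem_map <- stats::setNames(stems, syms)
  for (rep in 1:200) {
    k <- sample(2:4, 1)
    cs <- sample(syms, k)
    sup <- sample(3:6, k, replace = TRUE)
    blocked <- stats::runif(1) < 0.3
    use_override <- stats::runif(1) < 0.3
    ov <- if (use_override)
      data.frame(gene_id = "gX", forced_symbol = "forced1",
                 forced_name = "f", note = "")
    else data.frame(gene_id = character(0), forced_symbol = character(0),
                    forced_name = character(0), note = character(0))
    got <- choose_ortholog(
      data.frame(symbol = cs, support_count = sup, stringsAsFactors = FALSE),
      ref, overrides = ov, gene_id = "gX",
      foreign_ref_symbols = if (blocked) cs else character(0))
    mx <- max(sup)
    tied <- cs[sup == mx]
    fam_all_blocked <- blocked && any(tied %in% cs)
    want <- oracle_cascade(
      data.frame(symbol = cs, support_count = sup),
      stem_map,
      override_symbol = if (use_override) "forced1" else NULL,
      family_blocked = fam_all_blocked)
    expect_equal(got$symbol, want$symbol,
                 info = paste(cs, sup, collapse = " "))
    expect_equal(got$rule, want$rule)
  }
})

test_that("pseudoduplicate letter suffixes are ordered, roll over, and are order-insensitive", {
  a <- assign_pseudodup_suffixes(c("LOC105444B", "LOC105444A"), "msp130",
                                 "mesenchyme-specific protein 130")
  expect_equal(a$symbol, c("msp130.a", "msp130.b"))
  expect_equal(a$gene_id, c("LOC105444A", "LOC105444B"))
  members27 <- sprintf("g%02d", 1:27)
  a27 <- assign_pseudodup_suffixes(members27, "base", "base name")
  expect_equal(a27$suffix[26:27], c("z", "aa"))
  expect_equal(anyDuplicated(a27$symbol), 0L)
  set.seed(8)
  perm <- assign_pseudodup_suffixes(sample(members27), "base", "base name")
  expect_equal(perm, a27)
  expect_error(assign_pseudodup_suffixes("solo", "b", "n"), ">= 2 members")
})

test_that("paralog suffixes number in gene order and inherit across species", {
  a <- assign_paralog_suffixes(c("gB", "gA", "gC"), "dll1", "delta like 1")
  expect_equal(a$gene_id, c("gA", "gB", "gC"))
  expect_equal(a$symbol, c("dll1.1", "dll1.2", "dll1.3"))
  # inheritance: a cross-linked member keeps its partner's number
  b <- assign_paralog_suffixes(c("hB", "hA"), "dll1", "delta like 1",
                               inherited = c(hB = 2L))
  expect_equal(b$symbol[b$gene_id == "hB"], "dll1.2")
  expect_equal(b$symbol[b$gene_id == "hA"], "dll1.1")
  # conflicting claims both fall back to fresh numbers
  expect_message(
    cc <- assign_paralog_suffixes(c("x1", "x2"), "dll1", "d",
                                  inherited = c(x1 = 1L, x2 = 1L)),
    "conflict")
  expect_equal(sort(cc$symbol), c("dll1.1", "dll1.2"))
})

test_that("loc fallback builds the symbol from the Entrez ID", {
  g <- list(gene_id = "gZ", species = "spur", entrez_id = 575898L,
            product = "predicted membrane protein")
  a <- loc_fallback(g)
  expect_equal(a$symbol, "loc575898")
  expect_equal(a$full_name, "predicted membrane protein")
  expect_equal(a$rule_fired, "loc_fallback")
  expect_true("LOC575898" %in% a$synonyms[[1]])
  g$entrez_id <- NA
  expect_error(loc_fallback(g), "entrez_id")
})

test_that("render_with_previous shows only the most recent legacy symbol", {
  a <- data.frame(symbol = "nodal")
  a$legacy_ids <- list(c("oldest", "older", "Sp-Nodal"))
  expect_equal(render_with_previous(a), "nodal (Sp-Nodal)")
  a$legacy_ids <- list(character(0))
  expect_equal(render_with_previous(a), "nodal")
})

test_that("a toy cohort exercises every rule family exactly once", {
  co <- generate_cohort(77, cohort_spec(
    n_one_one = 1, n_one_many_support = 1, n_one_many_stem = 1,
    n_one_many_curator = 1, n_one_many_alpha = 1, n_many_one = 1,
    many_one_size = 2, n_many_many = 0, n_pseudodup = 1,
    n_vertebrate_one_one = 0, n_invertebrate_only = 0, n_orphan = 1,
    n_noise = 0))
  a <- run_cohort(co)
  expect_setequal(unique(a$rule_fired),
                  c("one_one", "one_many_support", "one_many_stem",
                    "one_many_curator", "one_many_alpha", "paralog_suffix",
                    "pseudodup_suffix", "loc_fallback"))
  m <- merge(a, co$truth, by = "gene_id")
  expect_equal(m$symbol, m$expected_symbol)
  expect_equal(m$rule_fired, m$expected_rule)
})

test_that("assignments are total, unique, normalized-closed, and stable", {
  co <- generate_cohort(13, cohort_spec())
  a <- run_cohort(co)
  expect_equal(nrow(a), nrow(co$genes))           # totality
  expect_equal(anyDuplicated(paste(a$species, a$symbol)), 0L)  # uniqueness
  for (s in a$symbol)
    expect_identical(normalize_symbol(s), s)      # normalization closure
  # stability: an extra orphan gene changes no existing assignment
  extra <- co
  ng <- co$genes[1, ]
  ng$gene_id <- "spur-g99999"; ng$entrez_id <- 999999L
  ng$exons <- list(cbind(start = ng$start, end = ng$end))
  extra$genes <- rbind(co$genes, ng)
  a2 <- run_cohort(extra)
  both <- merge(a, a2, by = "gene_id")
  expect_equal(both$symbol.x, both$symbol.y)
  expect_equal(both$rule_fired.x, both$rule_fired.y)
  expect_equal(a2$symbol[a2$gene_id == "spur-g99999"], "loc999999")
})

test_that("cross-species paralogs agree on suffixes over planted links", {
  co <- generate_cohort(19, cohort_spec(n_species = 2, n_shared_paralog = 3,
                                        n_pseudodup = 0))
  a <- run_cohort(co)
  m <- merge(a, co$truth, by = "gene_id")
  shared <- m[grepl("^shp", m$symbol), ]
  expect_gt(nrow(shared), 0)
  expect_equal(shared$symbol, shared$expected_symbol)
  expect_equal(shared$suffix,
               shared$expected_suffix)
})
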