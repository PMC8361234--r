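test_that("flank extraction arithmetic and boundary clipping", {
  genome <- Biostrings::DNAStringSet(c(contig1 = strrep("ACGT", 2500)))
  gene <- list(gene_id = "gA", chrom = "contig1", start = 2001L, end = 4000L)
  s <- extract_gene_model_sequence(gene, genome, 1000L)
  expect_equal(nchar(s), 4000L)
  expect_equal(attr(s, "start"), 1001L)
  expect_equal(attr(s, "end"), 5000L)
  expect_equal(as.character(s),
               as.character(Biostrings::subseq(genome[[1]], 1001, 5000)))

  gene2 <- list(gene_id = "gB", chrom = "contig1", start = 1L, end = 500L)
  expect_warning(s2 <- extract_gene_model_sequence(gene2, genome, 1000L),
                 "clipped")
  expect_equal(attr(s2, "start"), 1L)
  expect_equal(nchar(s2), 1500L)

  gene3 <- list(gene_id = "gC", chrom = "contig1", start = 9000L, end = 11000L)
  expect_error(extract_gene_model_sequence(gene3, genome, 0L),
               "outside contig")
})

test_that("extraction reproduces the planted allele windows exactly", {
  fix <- generate_pseudodup_sequences(31, n_clusters = 3, divergence = 0.03,
                                      flank_bp = 200, gene_len = 400)
  for (i in seq_len(nrow(fix$genes))) {
    g <- fix$genes[i, ]
    s <- extract_gene_model_sequence(g, fix$genome, 200L)
    expect_equal(as.character(s), unname(fix$windows[g$gene_id]),
                 info = g$gene_id)
  }
})

test_that("the 90/90 rule is inclusive at both boundaries", {
  cfg <- nomenclature_config()
  h <- function(pid, alen, ql, sl)
    data.frame(query_id = "A", subject_id = "B", pct_identity = pid,
               aln_length = alen, q_len = ql, s_len = sl)
  expect_true(hit_passes(h(90.0, 900, 1000, 800), cfg))   # both at 90 exactly
  expect_false(hit_passes(h(95.0, 700, 1000, 800), cfg))  # 70% of the longer
  expect_false(hit_passes(h(89.999, 1000, 1000, 800), cfg))
  expect_true(hit_passes(h(100, 720, 800, 700), cfg))     # 90% of 800
  expect_error(hit_passes(h(90, 1200, 1000, 800), cfg), "malformed")
})

test_that("hit_passes agrees with direct re-evaluation on 10000 random hits", {
  set.seed(17)
  n <- 10000
  ql <- sample(200:5000, n, replace = TRUE)
  sl <- sample(200:5000, n, replace = TRUE)
  longer <- pmax(ql, sl)
  hits <- data.frame(
    query_id = "A", subject_id = "B",
    pct_identity = round(stats::runif(n, 80, 100), 2),
    aln_length = floor(stats::runif(n, 0.5, 1) * longer),
    q_len = ql, s_len = sl)
  got <- hit_passes(hits)
  want <- hits$pct_identity >= 90 &
    100 * hits$aln_length / pmax(hits$q_len, hits$s_len) >= 90
  expect_identical(got, want)
})

test_that("clustering chains passing pairs and drops singletons", {
  mk <- function(q, s, pid = 95) data.frame(
    query_id = q, subject_id = s, pct_identity = pid, aln_length = 1000,
    q_len = 1000, s_len = 1000, stringsAsFactors = FALSE)
  cl <- cluster_pseudoduplicates(rbind(mk("A", "B"), mk("B", "C")))
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members, c("A", "B", "C"))
  expect_equal(cluster_pseudoduplicates(mk("A", "B", pid = 50)), list())
})

test_that("a pair passes when either orientation passes; best HSP is used", {
  ab_good <- data.frame(query_id = "A", subject_id = "B",
                        pct_identity = 95, aln_length = 950,
                        q_len = 1000, s_len = 1000)
  ba_bad <- data.frame(query_id = "B", subject_id = "A",
                       pct_identity = 50, aln_length = 400,
                       q_len = 1000, s_len = 1000)
  cl <- cluster_pseudoduplicates(rbind(ba_bad, ab_good))
  expect_equal(length(cl), 1L)
  # two HSPs for one ordered pair: the longer one decides (and fails here)
  two_hsp <- rbind(
    data.frame(query_id = "A", subject_id = "B", pct_identity = 99,
               aln_length = 300, q_len = 1000, s_len = 1000),
    data.frame(query_id = "A", subject_id = "B", pct_identity = 85,
               aln_length = 950, q_len = 1000, s_len = 1000))
  expect_equal(cluster_pseudoduplicates(two_hsp), list())
})

test_that("clusters equal a BFS oracle on random graphs", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(10:100, 1)
    m <- sample(5:120, 1)
    ids <- sprintf("n%03d", 1:n)
    pass <- stats::runif(m) < 0.6
    hits <- data.frame(
      query_id = sample(ids, m, replace = TRUE),
      subject_id = sample(ids, m, replace = TRUE),
      pct_identity = ifelse(pass, 95, 50),
      aln_length = 950, q_len = 1000, s_len = 1000,
      stringsAsFactors = FALSE)
    hits <- hits[hits$query_id != hits$subject_id, ]
    hits <- hits[!duplicated(hits[, c("query_id", "subject_id")]), ]
    got <- lapply(cluster_pseudoduplicates(hits), `[[`, "members")
    pp <- hits[hits$pct_identity >= 90, ]
    want <- oracle_bfs_components(pp$query_id, pp$subject_id)
    want <- Filter(function(x) length(x) >= 2, want)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("clusters are symmetric under query/subject swap and monotone in thresholds", {
  set.seed(5)
  ids <- sprintf("n%02d", 1:30)
  hits <- data.frame(
    query_id = sample(ids, 60, replace = TRUE),
    subject_id = sample(ids, 60, replace = TRUE),
    pct_identity = round(stats::runif(60, 85, 100), 1),
    aln_length = sample(850:1000, 60, replace = TRUE),
    q_len = 1000, s_len = 1000, stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, ]
  key <- function(cl) sort(vapply(cl, function(x)
    paste(x$members, collapse = ","), ""))
  swapped <- hits
  names(swapped)[1:2] <- c("subject_id", "query_id")
  expect_equal(key(cluster_pseudoduplicates(hits)),
               key(cluster_pseudoduplicates(swapped)))
  loose <- cluster_pseudoduplicates(hits, nomenclature_config())
  strict <- cluster_pseudoduplicates(
    hits, nomenclature_config(identity_threshold = 95,
                              coverage_threshold = 95))
  in_loose <- unlist(lapply(loose, `[[`, "members"))
  in_strict <- unlist(lapply(strict, `[[`, "members"))
  expect_true(all(in_strict %in% in_loose))
  for (s in strict) {
    container <- Filter(function(l) all(s$members %in% l$members), loose)
    expect_equal(length(container), 1L)
  }
})

test_that("planted divergence crosses the 90/90 boundary near d = 0.10", {
  close_pair <- generate_pseudodup_sequences(41, n_clusters = 4,
                                             divergence = 0.02,
                                             flank_bp = 100, gene_len = 600)
  far_pair <- generate_pseudodup_sequences(43, n_clusters = 4,
                                           divergence = 0.15,
                                           flank_bp = 100, gene_len = 600)
  expect_true(all(close_pair$truth$in_cluster))
  expect_false(any(far_pair$truth$in_cluster))
  # realized identity tracks 1 - d (substitution-only divergence)
  expect_equal(mean(close_pair$hits$pct_identity), 98, tolerance = 0.01)
  expect_equal(mean(far_pair$hits$pct_identity), 85, tolerance = 0.01)
  # clustering of the emitted hits reproduces the planted labels
  for (fix in list(close_pair, far_pair)) {
    cl <- cluster_pseudoduplicates(fix$hits)
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members %||% character(0),
                    fix$truth$gene_id[fix$truth$in_cluster])
  }
  # sweep through the boundary: decisions flip where realized identity
  # crosses 90, i.e. divergence ~0.10 up to binomial noise
  sweep <- generate_pseudodup_sequences(47, n_clusters = 12,
                                        divergence = seq(0.05, 0.15,
                                                         length.out = 12),
                                        flank_bp = 100, gene_len = 600)
  t <- sweep$truth[sweep$truth$copy_index == 2, ]
  expect_true(all(t$in_cluster[t$divergence <= 0.07]))
  expect_false(any(t$in_cluster[t$divergence >= 0.13]))
  expect_equal(t$in_cluster, t$identity_to_source >= 90)
})

test_that("the internal aligner reproduces planted identities on tiny fixtures", {
  fix <- generate_pseudodup_sequences(53, n_clusters = 2, divergence = 0.03,
                                      flank_bp = 50, gene_len = 300)
  seqs <- stats::setNames(
    vapply(seq_len(nrow(fix$genes)), function(i) as.character(
      extract_gene_model_sequence(fix$genes[i, ], fix$genome, 50L)),
      character(1)),
    fix$genes$gene_id)
  hits <- compute_similarity_hits(seqs)
  # within-cluster pairs are found at close to the planted identity
  for (i in seq_len(nrow(fix$hits))) {
    planted <- fix$hits[i, ]
    got <- hits[(hits$query_id == planted$query_id &
                   hits$subject_id == planted$subject_id) |
                  (hits$query_id == planted$subject_id &
                     hits$subject_id == planted$query_id), ]
    expect_equal(nrow(got), 1L)
    expect_equal(got$pct_identity, planted$pct_identity, tolerance = 1)
  }
})
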