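# Cohort-level category statistics: how many genes are nameable, and
# through which kind of orthology. Percentages use half-up rounding
# computed in exact integer arithmetic, since published tables mix 0-, 1-
# and 2-decimal precision and half-even float rounding can disagree at the
# printed digit.

#' Format a percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` and rounds half-up at
#' `decimals` places using integer arithmetic (no float ties), e.g.
#' 964/8066 at 0 dp is "12%".
#'
#' @param numerator,denominator Non-negative numbers; denominator > 0.
#' @param decimals Number of decimal places (>= 0).
#' @return Character scalar ending in "%".
#' @export
format_percentage <- function(numerator, denominator, decimals = 2L) {
  if (numerator < 0 || denominator <= 0 || decimals < 0)
    stop("format_percentage: numerator >= 0, denominator > 0, decimals >= 0 required")
  v <- percent_half_up(numerator, denominator, decimals)
  d <- as.integer(decimals)
  scaled <- round(v * 10^d)
  ip <- scaled %/% 10^d
  if (d == 0L) return(sprintf("%d%%", as.integer(ip)))
  fp <- scaled %% 10^d
  sprintf("%d.%0*d%%", as.integer(ip), d, as.integer(fp))
}

# half-up rounded percentage as a number, exact for integer inputs:
# round(a/b + 1/2) computed as floor((2a + b) / (2b)) in integer arithmetic
percent_half_up <- function(numerator, denominator, decimals) {
  d <- as.integer(decimals)
  # scale non-integer inputs to integers (1e-6 precision) so the integer
  # half-up formula stays exact
  s <- 10^6
  a <- round(numerator * s) * 100 * 10^d
  b <- round(denominator * s)
  floor((2 * a + b) / (2 * b)) / 10^d
}

#' Compute cohort category statistics
#'
#' @param categories Named character vector gene_id -> category, as from
#'   [categorize_genes()] (complete over the genes considered nameable;
#'   `unnameable` entries may be present or absent).
#' @param n_total Total number of protein-coding genes in the genome
#'   (denominator for the "share of total" columns).
#' @return A `category_stats` list: counts plus a `percentages` data.frame
#'   with raw fractions and 0/1/2-dp half-up renderings of each category's
#'   share of nameable genes and of all protein-coding genes.
#' @export
compute_category_stats <- function(categories, n_total) {
  if (n_total == 0) stop("n_total must be > 0")
  n_h <- sum(categories == "human_one_one")
  n_v <- sum(categories == "vertebrate_one_one")
  n_i <- sum(categories == "invertebrate_only")
  n_nameable <- sum(categories != "unnameable")
  if (n_nameable > n_total)
    stop("more nameable genes than protein-coding genes")
  counts <- c(human_one_one = n_h, vertebrate_one_one = n_v,
              invertebrate_only = n_i)
  pct <- do.call(rbind, lapply(names(counts), function(cat) {
    n <- counts[[cat]]
    data.frame(
      category = cat,
      count = n,
      frac_of_nameable = if (n_nameable > 0) n / n_nameable else 0,
      frac_of_total = n / n_total,
      of_nameable_0dp = format_percentage(n, max(n_nameable, 1), 0L),
      of_nameable_1dp = format_percentage(n, max(n_nameable, 1), 1L),
      of_nameable_2dp = format_percentage(n, max(n_nameable, 1), 2L),
      of_total_0dp = format_percentage(n, n_total, 0L),
      of_total_1dp = format_percentage(n, n_total, 1L),
      of_total_2dp = format_percentage(n, n_total, 2L),
      stringsAsFactors = FALSE)
  }))
  structure(list(n_total_protein_coding = as.integer(n_total),
                 n_nameable = as.integer(n_nameable),
                 n_human_one_one = as.integer(n_h),
                 n_vertebrate_one_one = as.integer(n_v),
                 n_invertebrate_only = as.integer(n_i),
                 percentages = pct),
            class = "category_stats")
}

#' @export
print.category_stats <- function(x, ...) {
  cat(sprintf("protein-coding genes: %d\n", x$n_total_protein_coding))
  cat(sprintf("nameable genes:       %d (%s of total)\n", x$n_nameable,
              format_percentage(x$n_nameable, x$n_total_protein_coding, 1L)))
  p <- x$percentages
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-20s %6d  %s of nameable, %s of total\n",
                p$category[i], p$count[i],
                p$of_nameable_2dp[i], p$of_total_2dp[i]))
  }
  invisible(x)
}

#' Write the category-statistics table
#' @param stats A `category_stats` object.
#' @param path Output path (tab-separated).
#' @export
write_category_stats <- function(stats, path) {
  utils::write.table(stats$percentages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
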