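#' Pipeline configuration
#'
#' Bundles every tunable threshold of the nomenclature pipeline. Defaults are
#' the published operating point: an orthologous relationship counts when
#' three or more distinct tools support it, and two gene models are
#' pseudoduplicate candidates when they match at >= 90% identity along
#' >= 90% of the longer model's length, the models being taken with 1 kb of
#' flanking sequence on each side.
#'
#' @param min_tools Minimum number of distinct orthology tools that must
#'   report a gene pair for the edge to be consensus-supported (inclusive).
#' @param identity_threshold Percent identity threshold for the
#'   pseudoduplicate rule, inclusive.
#' @param coverage_threshold Percent of the longer sequence's length that the
#'   alignment must span, inclusive.
#' @param flank_bp Bases of genomic flank added up- and downstream of each
#'   gene model before similarity comparison.
#' @param rng_seed Integer seed for any randomized step (fixture generation).
#' @return An object of class `nomenclature_config`.
#' @export
nomenclature_config <- function(min_tools = 3L,
                                identity_threshold = 90,
                                coverage_threshold = 90,
                                flank_bp = 1000L,
                                rng_seed = 1L) {
  min_tools <- as.integer(min_tools)
  flank_bp <- as.integer(flank_bp)
  if (is.na(min_tools) || min_tools < 1L)
    stop("min_tools must be an integer >= 1")
  if (identity_threshold <= 0 || coverage_threshold <= 0)
    stop("identity_threshold and coverage_threshold must be > 0")
  if (flank_bp < 0L) stop("flank_bp must be >= 0")
  structure(
    list(min_tools = min_tools,
         identity_threshold = as.numeric(identity_threshold),
         coverage_threshold = as.numeric(coverage_threshold),
         flank_bp = flank_bp,
         rng_seed = as.integer(rng_seed)),
    class = "nomenclature_config"
  )
}

#' @export
print.nomenclature_config <- function(x, ...) {
  cat("nomenclature_config:\n")
  cat(sprintf("  min_tools          %d\n", x$min_tools))
  cat(sprintf("  identity_threshold %.1f%%\n", x$identity_threshold))
  cat(sprintf("  coverage_threshold %.1f%%\n", x$coverage_threshold))
  cat(sprintf("  flank_bp           %d\n", x$flank_bp))
  cat(sprintf("  rng_seed           %d\n", x$rng_seed))
  invisible(x)
}

#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Unknown keys are an error so typos never silently fall back to defaults.
#'
#' @param path Path to the config file.
#' @return A `nomenclature_config`.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- c("min_tools", "identity_threshold", "coverage_threshold",
             "flank_bp", "rng_seed")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- stats::setNames(as.list(as.numeric(vals)), keys)
  do.call(nomenclature_config, args)
}
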