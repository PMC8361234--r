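#' @keywords internal
"_PACKAGE"

# closed taxon vocabulary used throughout the package
TAXA <- c("human", "other_vertebrate", "invertebrate", "non_animal")

# radix sort: locale-independent byte order, so every ordering decision in
# the package is reproducible across platforms
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

log_msg <- function(fmt, ...) {
  message(sprintf(paste0("[echinoname] ", fmt), ...))
}

# bijective base-26 letter index: 1 -> "a", 26 -> "z", 27 -> "aa", 28 -> "ab"
letter_suffix <- function(i) {
  vapply(as.integer(i), function(n) {
    stopifnot(n >= 1L)
    out <- character(0)
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      out <- c(letters[r + 1L], out)
      n <- (n - 1L) %/% 26L
    }
    paste(out, collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
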