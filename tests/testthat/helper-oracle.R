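# Independent brute-force oracle for the two-element motif scan:
# exhaustively enumerates every (element1, element2) placement pair and
# returns the leftmost feasible one.  Written against the motif contract
# only; shares no code with match_pattern().

bf_element_at <- function(chars, start, element) {
  for (j in seq_along(element)) {
    allowed <- element[[j]]
    if (!is.null(allowed) && !(chars[start + j - 1] %in% allowed)) {
      return(FALSE)
    }
  }
  TRUE
}

bf_match <- function(residues, pattern) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  k1 <- length(pattern$element1)
  k2 <- length(pattern$element2)
  if (n < k1 + k2) return(NULL)
  for (i in seq_len(n - k1 + 1)) {
    if (!bf_element_at(chars, i, pattern$element1)) next
    j0 <- i + k1 + pattern$min_spacer
    if (j0 > n - k2 + 1) next
    for (j in j0:(n - k2 + 1)) {
      if (bf_element_at(chars, j, pattern$element2)) return(c(i, j))
    }
  }
  NULL
}

# Cysteine-enriched random amino-acid strings so motifs actually occur.
random_aa <- function(n, max_len = 60, p_c = 0.2) {
  alphabet <- c(thermoproxy::YVIWREL_SET, "A", "C", "D", "G", "H", "K",
                "M", "N", "P", "Q", "S", "T", "F", "X", "B", "Z")
  w <- rep(1, length(alphabet))
  w[alphabet == "C"] <- p_c * length(alphabet)
  vapply(seq_len(n), function(i) {
    len <- sample(8:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE, prob = w), collapse = "")
  }, character(1))
}
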