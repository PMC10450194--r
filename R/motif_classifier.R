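## The metal-binding-site grammar.  Each of the nine ribosomal proteins has
## a two-element motif (a zinc ribbon or iron-sulfur site): element 1 and
## element 2 each hold exactly two metal-coordinating residues separated by
## wildcards, and the elements occur in order, separated by a spacer of
## arbitrary (>= min_spacer) residues, without overlapping.
##
## Pattern strings use the field's notation: "CxxC-CxxC" means
## (C)(any)(any)(C) then a spacer then (C)(any)(any)(C).  'x'/'X' is a
## wildcard; '[CDE]' is an allowed-residue set.  Elements are internally
## lists with one entry per position: a character vector of allowed
## residues, or NULL for a wildcard.

#' Parse a motif pattern string
#'
#' @param pattern_string e.g. `"CxxC-CxxH"` or `"CxxC-Cxx[CDE]"`; exactly
#'   two elements separated by `-`; `x`/`X` is a wildcard, `[...]` an
#'   allowed set.
#' @param protein Protein name the pattern belongs to.
#' @param min_spacer Minimum number of residues between the two elements
#'   (default 0); the elements must occur in order and must not overlap.
#' @return An object of class `motif_pattern`.
#' @export
parse_motif <- function(pattern_string, protein = NA_character_,
                        min_spacer = 0L) {
  parts <- strsplit(pattern_string, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("pattern must have exactly two '-'-separated elements: ",
         pattern_string)
  }
  parse_element <- function(s) {
    out <- list()
    chars <- strsplit(s, "")[[1]]
    i <- 1
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "[") {
        j <- which(chars == "]" & seq_along(chars) > i)[1]
        if (is.na(j)) stop("unterminated '[' in pattern: ", s)
        out[[length(out) + 1]] <- chars[(i + 1):(j - 1)]
        i <- j + 1
      } else if (ch %in% c("x", "X")) {
        out[length(out) + 1] <- list(NULL)
        i <- i + 1
      } else {
        out[[length(out) + 1]] <- ch
        i <- i + 1
      }
    }
    first_last <- c(1L, length(out))
    if (any(vapply(out[first_last], is.null, logical(1)))) {
      stop("element must begin and end with a constrained position: ", s)
    }
    out
  }
  e1 <- parse_element(parts[1])
  e2 <- parse_element(parts[2])
  n_constrained <- sum(!vapply(c(e1, e2), is.null, logical(1)))
  structure(list(protein = protein, element1 = e1, element2 = e2,
                 min_spacer = as.integer(min_spacer),
                 pattern_string = pattern_string,
                 n_constrained = n_constrained),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern", x$pattern_string,
      if (!is.na(x$protein)) paste0("(", x$protein, ")"), "\n")
  invisible(x)
}

## All start positions (1-based) where `element` matches the character
## vector `chars`.  Constrained positions match only their allowed set;
## wildcards match any letter (including ambiguity codes).
element_starts <- function(chars, element) {
  n <- length(chars)
  k <- length(element)
  if (n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    allowed <- element[[j]]
    if (is.null(allowed)) next
    ok <- ok & chars[seq.int(j, j + n - k)] %in% allowed
  }
  which(ok)
}

#' Scan a sequence for a two-element motif pattern
#'
#' Finds the leftmost pair of in-order, non-overlapping occurrences of
#' element 1 followed by element 2 ("leftmost" = smallest element-1 start
#' among feasible pairs, then smallest element-2 start).  Wildcard
#' positions match any letter including ambiguity codes; constrained
#' positions match only their allowed residues, so a reported 'X' never
#' satisfies a constrained position.
#'
#' @param residues Gap-free uppercase amino-acid string.
#' @param pattern A [parse_motif()] object.
#' @return Integer vector `c(element1_start, element2_start)` (1-based), or
#'   `NULL` if the pattern does not occur.
#' @export
match_pattern <- function(residues, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (is.na(residues) || nchar(residues) == 0) return(NULL)
  chars <- strsplit(residues, "")[[1]]
  s1 <- element_starts(chars, pattern$element1)
  if (length(s1) == 0) return(NULL)
  s2 <- element_starts(chars, pattern$element2)
  if (length(s2) == 0) return(NULL)
  k1 <- length(pattern$element1)
  for (i in s1) {
    j <- s2[s2 >= i + k1 + pattern$min_spacer]
    if (length(j) > 0) return(c(i, j[1]))
  }
  NULL
}

#' The packaged classification scheme for the nine metal-binding proteins
#'
#' Reads the motif table shipped with the package: (CXXC)-(CXXC) for uL24,
#' bL28, bL31, bL32 and uS14; (CXXC)-(CXXH) for bS18 and bL36;
#' (CXXC)-(CXXXXC) for uS4; and (CXXC)-(CXX\[C, D or E\]) for bL33, carried
#' as three explicit variants (CCCC, CCCD, CCCE).  Eight proteins bind
#' Zn2+; uS4 binds an iron-sulfur cluster.
#'
#' @param path Optional path to an alternative scheme TSV with columns
#'   `protein`, `pattern`, `metal`, `variant`.
#' @return An object of class `classification_scheme`: list with `patterns`
#'   (named list of [parse_motif()] lists per protein) and `metal` (named
#'   character vector).
#' @export
default_scheme <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "motif_scheme.tsv", package = "thermoproxy",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "pattern", "metal", "variant") %in% names(tab)))
  proteins <- unique(tab$protein)
  if (!setequal(proteins, METAL_PROTEINS)) {
    stop("scheme must cover exactly the nine proteins ",
         paste(METAL_PROTEINS, collapse = ", "))
  }
  patterns <- lapply(proteins, function(p) {
    rows <- tab[tab$protein == p, , drop = FALSE]
    pats <- lapply(seq_len(nrow(rows)), function(i) {
      m <- parse_motif(rows$pattern[i], protein = p)
      m$variant <- rows$variant[i]
      m
    })
    names(pats) <- rows$variant
    pats
  })
  names(patterns) <- proteins
  metal <- vapply(proteins, function(p) tab$metal[tab$protein == p][1],
                  character(1))
  bad <- vapply(unlist(patterns, recursive = FALSE),
                function(m) m$n_constrained != 4L, logical(1))
  if (any(bad)) stop("every pattern must carry exactly 4 constrained positions")
  structure(list(patterns = patterns, metal = metal),
            class = "classification_scheme")
}

#' @export
print.classification_scheme <- function(x, ...) {
  cat("classification_scheme:", length(x$patterns), "proteins\n")
  for (p in names(x$patterns)) {
    cat(sprintf("  %-5s %-12s %s\n", p,
                paste(vapply(x$patterns[[p]], `[[`, character(1),
                             "pattern_string"), collapse = " | "),
                x$metal[[p]]))
  }
  invisible(x)
}

#' Does a sequence match any pattern of its protein?
#' @param residues Amino-acid string.
#' @param scheme A [default_scheme()].
#' @param protein Protein name.
#' @return TRUE if any variant pattern matches.
#' @export
matches_any_pattern <- function(residues, scheme, protein) {
  pats <- scheme$patterns[[protein]]
  if (is.null(pats)) stop("unknown protein: ", protein)
  for (p in pats) if (!is.null(match_pattern(residues, p))) return(TRUE)
  FALSE
}

#' Call the C+/C-/both isoform status for one species x one protein
#'
#' All records matching a pattern gives `only_cplus`; none matching gives
#' `only_cminus`; a mixture gives `both` (one metal-binding and one
#' metal-free paralog).
#'
#' @param records Sequence data.frame: one species, one protein, >= 1 row.
#' @param scheme A [default_scheme()].
#' @return data.frame `species_id`, `protein`, `call`, `n_sequences`.
#' @export
classify_protein_isoform <- function(records, scheme) {
  if (nrow(records) == 0) stop("classify_protein_isoform: zero records")
  protein <- unique(records$molecule)
  species <- unique(records$species_id)
  if (length(protein) != 1 || length(species) != 1) {
    stop("records must belong to a single species and protein")
  }
  hits <- vapply(records$residues, matches_any_pattern, logical(1),
                 scheme = scheme, protein = protein, USE.NAMES = FALSE)
  call <- if (all(hits)) "only_cplus" else if (!any(hits)) "only_cminus" else "both"
  data.frame(species_id = species, protein = protein, call = call,
             n_sequences = nrow(records))
}

#' Classify every species x protein combination in a record table
#'
#' @param records Sequence data.frame covering any number of species and
#'   proteins (molecule names must be scheme proteins).
#' @param scheme A [default_scheme()].
#' @return data.frame of isoform calls, one row per species x protein with
#'   data, ordered by species then protein.
#' @export
classify_isoforms <- function(records, scheme) {
  records <- records[records$molecule %in% names(scheme$patterns), ,
                     drop = FALSE]
  if (nrow(records) == 0) stop("no records of scheme proteins")
  key <- interaction(records$species_id, records$molecule, drop = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, classify_protein_isoform,
                               scheme = scheme))
  out <- out[order(out$species_id, out$protein, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count C+ proteins in one species
#'
#' Species encoding both isoforms count as C+ (the metal-binding copy is
#' the physiologically expressed one).  Proteins without sequence data are
#' excluded from the count and reported via a warning, not treated as C-.
#'
#' @param calls Isoform-call data.frame of a single species (at most one
#'   row per protein).
#' @param scheme A [default_scheme()] (names the expected proteins).
#' @return Integer in \[0, 9\]; attribute `missing_proteins` lists proteins
#'   without data.
#' @export
species_cplus_count <- function(calls, scheme = default_scheme()) {
  if (anyDuplicated(calls$protein)) {
    stop("duplicate protein calls for one species")
  }
  missing <- setdiff(names(scheme$patterns), calls$protein)
  if (length(missing) > 0) {
    warning("no sequence data for protein(s): ",
            paste(missing, collapse = ", "))
  }
  n <- sum(calls$call %in% c("only_cplus", "both"))
  attr(n, "missing_proteins") <- missing
  n
}

#' Per-species C+ counts for a full call table
#'
#' @param calls Isoform-call data.frame over many species.
#' @return data.frame `species_id`, `cplus_count`, `n_proteins_with_data`.
#' @export
cplus_count_table <- function(calls) {
  agg <- stats::aggregate(
    cbind(cplus = calls$call %in% c("only_cplus", "both"), one = 1L),
    by = list(species_id = calls$species_id), FUN = sum)
  data.frame(species_id = agg$species_id,
             cplus_count = as.integer(agg$cplus),
             n_proteins_with_data = as.integer(agg$one))
}

#' Type a bL33 sequence as CCCC, CCCD or CCCE
#'
#' bL33 occurs in three apparent metal-binding forms in which the fourth
#' coordinating residue is cysteine, aspartate or glutamate.  Patterns are
#' tested in the order CCCC, CCCD, CCCE and the first match wins: the
#' all-cysteine form is the canonical, experimentally characterised one.
#'
#' @param residues Gap-free amino-acid string.
#' @return One of `"CCCC"`, `"CCCD"`, `"CCCE"`, `"none"`.
#' @export
classify_bl33_variant <- function(residues) {
  for (v in c("CCCC", "CCCD", "CCCE")) {
    if (!is.null(match_pattern(residues, bl33_patterns[[v]]))) return(v)
  }
  "none"
}

bl33_patterns <- list(
  CCCC = parse_motif("CxxC-CxxC", "bL33"),
  CCCD = parse_motif("CxxC-CxxD", "bL33"),
  CCCE = parse_motif("CxxC-CxxE", "bL33")
)

#' Count metal-coordinating residues over a protein subset
#'
#' Sums the constrained (non-wildcard) positions of each protein's
#' canonical pattern; bL33 is counted once through its CCCC variant.  Over
#' all nine proteins the scheme defines 36 coordinating residues; the pair
#' bL36 + bL32 alone contributes 8.
#'
#' @param scheme A [default_scheme()].
#' @param proteins Subset of scheme proteins (default: all nine).
#' @return Integer.
#' @export
coordinating_residue_count <- function(scheme, proteins = names(scheme$patterns)) {
  unknown <- setdiff(proteins, names(scheme$patterns))
  if (length(unknown) > 0) {
    stop("unknown protein name(s): ", paste(unknown, collapse = ", "))
  }
  sum(vapply(proteins, function(p) {
    scheme$patterns[[p]][[1]]$n_constrained
  }, integer(1)))
}
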