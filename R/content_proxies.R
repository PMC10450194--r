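## Sequence-composition proxies: GC and U content of the 16S rRNA (whole
## molecule or restricted to helical segments of a reference structure)
## and the YVIWREL amino-acid content of a protein set.  All values are
## fractions in [0, 1]; percentages are a formatting concern only.
## Denominators count unambiguous bases (A/C/G/U) only: N and gaps are
## excluded from numerator and denominator alike.

base_counts <- function(residues) {
  chars <- strsplit(gsub("T", "U", toupper(residues), fixed = TRUE), "")[[1]]
  c(A = sum(chars == "A"), C = sum(chars == "C"),
    G = sum(chars == "G"), U = sum(chars == "U"))
}

#' GC content of a nucleotide sequence
#'
#' (#G + #C) / (#A + #C + #G + #U).  T is read as U; N and any other
#' character are excluded from both numerator and denominator.
#'
#' @param residues Nucleotide string.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(residues) {
  n <- base_counts(residues)
  total <- sum(n)
  if (total == 0) stop("no unambiguous bases in sequence")
  unname((n["G"] + n["C"]) / total)
}

#' U content of a nucleotide sequence
#'
#' #U / (#A + #C + #G + #U), with the same denominator convention as
#' [gc_content()].
#'
#' @inheritParams gc_content
#' @return Fraction in \[0, 1\].
#' @export
u_content <- function(residues) {
  n <- base_counts(residues)
  total <- sum(n)
  if (total == 0) stop("no unambiguous bases in sequence")
  unname(n["U"] / total)
}

#' Read a helix coordinate table
#'
#' @param path TSV with header `start end name`; 1-based inclusive
#'   positions in ungapped reference coordinates.
#' @param reference_record_id Id of the reference row the coordinates
#'   refer to.
#' @return An object of class `helix_set`: list with
#'   `reference_record_id` and `intervals` (data.frame `start`, `end`,
#'   `name`).
#' @export
read_helix_table <- function(path, reference_record_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end") %in% names(tab)))
  if (!"name" %in% names(tab)) tab$name <- paste0("h", seq_len(nrow(tab)))
  helix_set(reference_record_id, tab)
}

#' Construct a helix coordinate set
#'
#' @param reference_record_id Reference row id.
#' @param intervals data.frame `start`, `end` (1-based inclusive, ungapped
#'   reference coordinates); must be sorted and non-overlapping.
#' @return A `helix_set`.
#' @export
helix_set <- function(reference_record_id, intervals) {
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  if (nrow(intervals) > 0) {
    if (any(intervals$end < intervals$start)) {
      stop("helix interval with end < start")
    }
    if (nrow(intervals) > 1 &&
        any(intervals$start[-1] <= intervals$end[-nrow(intervals)])) {
      stop("helix intervals overlap")
    }
  }
  rownames(intervals) <- NULL
  structure(list(reference_record_id = reference_record_id,
                 intervals = intervals),
            class = "helix_set")
}

#' Alignment columns covered by reference helices
#'
#' Maps each helix interval (in ungapped reference coordinates) onto
#' alignment columns through the reference row.  Columns where the
#' reference carries a gap are never included.
#'
#' @param aligned An [aligned_set()] containing the reference row.
#' @param helices A [helix_set()].
#' @return Sorted integer vector of alignment columns (1-based).
#' @export
helical_column_mask <- function(aligned, helices) {
  i <- match(helices$reference_record_id, aligned$rows$record_id)
  if (is.na(i)) {
    stop("reference row not found: ", helices$reference_record_id)
  }
  if (nrow(helices$intervals) == 0) return(integer(0))
  chars <- strsplit(aligned$rows$aligned[i], "")[[1]]
  ungapped_cols <- which(chars != "-")
  if (any(helices$intervals$end > length(ungapped_cols))) {
    stop("helix interval beyond ungapped reference length (",
         length(ungapped_cols), ")")
  }
  pos <- unlist(mapply(seq.int, helices$intervals$start,
                       helices$intervals$end, SIMPLIFY = FALSE))
  sort(ungapped_cols[pos])
}

#' GC content of an aligned row over masked columns
#'
#' @param aligned_row A single gapped row (character string).
#' @param mask Alignment columns (1-based), e.g. from
#'   [helical_column_mask()]; must be non-empty.
#' @return Fraction in \[0, 1\], computed over the row's non-gap bases at
#'   the masked columns; errors if the row is entirely gapped there.
#' @export
helical_gc <- function(aligned_row, mask) {
  if (length(mask) == 0) stop("empty helical mask")
  chars <- strsplit(aligned_row, "")[[1]]
  sub <- chars[mask]
  sub <- sub[sub != "-"]
  if (length(sub) == 0) stop("row entirely gapped at helical mask")
  gc_content(paste(sub, collapse = ""))
}

#' Per-species helical GC table for an alignment
#'
#' Applies [helical_gc()] to every row of the alignment except the
#' reference; rows entirely gapped at the mask are skipped and reported.
#'
#' @param aligned An [aligned_set()].
#' @param helices A [helix_set()].
#' @return data.frame `species_id`, `proxy_name` ("gc_helical"), `value`,
#'   `n_residues_used`; attribute `skipped` lists unusable rows.
#' @export
helical_gc_table <- function(aligned, helices) {
  mask <- helical_column_mask(aligned, helices)
  rows <- aligned$rows[aligned$rows$record_id != helices$reference_record_id, ,
                       drop = FALSE]
  vals <- lapply(seq_len(nrow(rows)), function(i) {
    chars <- strsplit(rows$aligned[i], "")[[1]][mask]
    chars <- chars[chars != "-"]
    if (length(chars) == 0) return(NULL)
    n <- base_counts(paste(chars, collapse = ""))
    if (sum(n) == 0) return(NULL)
    data.frame(species_id = rows$species_id[i], proxy_name = "gc_helical",
               value = unname((n["G"] + n["C"]) / sum(n)),
               n_residues_used = sum(n))
  })
  skipped <- rows$record_id[vapply(vals, is.null, logical(1))]
  if (length(skipped) > 0) {
    warning("row(s) entirely gapped at helical mask skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, vals)
  attr(out, "skipped") <- skipped
  out
}

#' YVIWREL content of a species' protein set
#'
#' Cumulative count of Y, V, I, W, R, E and L residues across all supplied
#' protein sequences, divided by the total residue count of those
#' sequences.  The caller restricts the records to the designated set
#' (ribosomal proteins or a minimal gene set); all retained records of a
#' species contribute.
#'
#' @param residues Character vector of amino-acid sequences (>= 1).
#' @return Fraction in \[0, 1\].
#' @export
yviwrel_content <- function(residues) {
  if (length(residues) == 0 || all(!nzchar(residues))) {
    stop("yviwrel_content: empty protein set")
  }
  chars <- unlist(strsplit(toupper(residues), ""))
  sum(chars %in% YVIWREL_SET) / length(chars)
}

#' Per-species content-proxy table
#'
#' Convenience wrapper producing the long-format proxy table used by the
#' comparison stage.
#'
#' @param records Sequence data.frame.
#' @param proxy One of `"gc_full"`, `"u_content"`, `"yviwrel"`.
#' @return data.frame `species_id`, `proxy_name`, `value`,
#'   `n_residues_used`.
#' @export
content_proxy_table <- function(records,
                                proxy = c("gc_full", "u_content", "yviwrel")) {
  proxy <- match.arg(proxy)
  parts <- split(records, records$species_id)
  out <- lapply(names(parts), function(sp) {
    res <- parts[[sp]]$residues
    val <- switch(proxy,
      gc_full = gc_content(paste(res, collapse = "")),
      u_content = u_content(paste(res, collapse = "")),
      yviwrel = yviwrel_content(res))
    n_used <- if (proxy == "yviwrel") sum(nchar(res))
              else sum(base_counts(paste(res, collapse = "")))
    data.frame(species_id = sp, proxy_name = proxy, value = val,
               n_residues_used = n_used)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
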