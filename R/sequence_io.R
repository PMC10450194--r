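## Sequence, alignment and annotation I/O plus the quality filters applied
## before any proxy is computed.  Sequences travel as plain data.frames
## (one row per record); alignments as the small S3 container `aligned_set`.

#' Read a species annotation table
#'
#' The annotation TSV carries one row per sequence record and joins records
#' to species, molecules and optimal growth temperatures.  Expected header:
#' `record_id species_id molecule phylum ogt_celsius` with an optional
#' logical `plasmid` column (plasmid-encoded genes cannot be recognised
#' from sequence alone, so their removal is delegated to this table).
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data.frame with one row per record. OGT values must lie in
#'   \[-20, 130\] degrees Celsius.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("record_id", "species_id", "molecule")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$record_id)) {
    stop("duplicate record_id in annotation table: ",
         paste(unique(ann$record_id[duplicated(ann$record_id)]), collapse = ", "))
  }
  if ("ogt_celsius" %in% names(ann)) {
    bad <- !is.na(ann$ogt_celsius) &
      (ann$ogt_celsius < -20 | ann$ogt_celsius > 130)
    if (any(bad)) {
      stop("ogt_celsius outside [-20, 130] for: ",
           paste(ann$record_id[bad], collapse = ", "))
    }
  }
  ann
}

#' Extract the per-species annotation from a per-record table
#'
#' @param annotations A per-record annotation data.frame
#'   (see [read_annotation_table()]).
#' @return data.frame with columns `species_id`, `phylum`, `ogt_celsius`,
#'   one row per species.
#' @export
species_annotations <- function(annotations) {
  cols <- intersect(c("species_id", "phylum", "ogt_celsius"), names(annotations))
  sp <- unique(annotations[cols])
  if (anyDuplicated(sp$species_id)) {
    stop("inconsistent phylum/OGT annotation within a species: ",
         paste(unique(sp$species_id[duplicated(sp$species_id)]), collapse = ", "))
  }
  rownames(sp) <- NULL
  sp
}

#' Read sequences from FASTA and join them to their annotations
#'
#' Headers are truncated at the first whitespace to obtain the record id.
#' Residues are uppercased; for nucleotide molecules T is normalised to U.
#' Records absent from the annotation table are dropped with a message and
#' listed in the `dropped` attribute of the result.
#'
#' @param path FASTA file.
#' @param annotations Per-record annotation data.frame; must map
#'   `record_id` to `species_id` and `molecule`.
#' @return data.frame with columns `record_id`, `species_id`, `molecule`,
#'   `residues`, `source_tag`, plus any annotation columns such as
#'   `ogt_celsius`; attribute `dropped` holds unmatched record ids.
#' @export
read_fasta <- function(path, annotations) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  res <- toupper(as.character(set))
  hit <- match(ids, annotations$record_id)
  dropped <- ids[is.na(hit)]
  if (length(dropped) > 0) {
    message(length(dropped), " record(s) without annotation dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  keep <- !is.na(hit)
  out <- annotations[hit[keep], , drop = FALSE]
  out$record_id <- ids[keep]
  out$residues <- unname(res[keep])
  if (!"source_tag" %in% names(out)) out$source_tag <- ""
  nt <- is_nucleotide_molecule(out$molecule)
  out$residues[nt] <- gsub("T", "U", out$residues[nt], fixed = TRUE)
  validate_alphabets(out)
  rownames(out) <- NULL
  front <- c("record_id", "species_id", "molecule", "residues", "source_tag")
  out <- out[c(front, setdiff(names(out), front))]
  attr(out, "dropped") <- dropped
  out
}

validate_alphabets <- function(records) {
  nt <- is_nucleotide_molecule(records$molecule)
  ok_nt <- paste0("^[", paste(NT_LETTERS, collapse = ""), "]+$")
  ok_aa <- paste0("^[", paste(c(AA_STANDARD, AA_AMBIGUOUS), collapse = ""), "]+$")
  bad <- (nt & !grepl(ok_nt, records$residues)) |
    (!nt & !grepl(ok_aa, records$residues)) |
    !nzchar(records$residues)
  if (any(bad)) {
    stop("record(s) with empty or out-of-alphabet residues: ",
         paste(records$record_id[bad], collapse = ", "))
  }
  invisible(records)
}

#' Write sequence records to FASTA
#'
#' @param records Sequence data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$residues,
                                                records$record_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct an aligned sequence set
#'
#' @param record_id,species_id Character vectors.
#' @param aligned Character vector of equal-length gapped rows
#'   ('-' for gaps; '.' is normalised to '-').
#' @param width Column count; required only for an empty set.
#' @return An object of class `aligned_set`: a list with elements `rows`
#'   (data.frame `record_id`, `species_id`, `aligned`) and `width`.
#' @export
aligned_set <- function(record_id, species_id, aligned, width = NULL) {
  aligned <- gsub(".", "-", toupper(aligned), fixed = TRUE)
  w <- unique(nchar(aligned))
  if (length(aligned) == 0) {
    if (is.null(width)) stop("alignment has no rows")
    w <- as.integer(width)
  }
  if (length(w) != 1) stop("aligned rows differ in length: ",
                           paste(w, collapse = ", "))
  if (anyDuplicated(record_id)) stop("duplicate record_id in alignment")
  structure(list(
    rows = data.frame(record_id = record_id, species_id = species_id,
                      aligned = aligned, stringsAsFactors = FALSE),
    width = w
  ), class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", nrow(x$rows), "rows x", x$width, "columns\n")
  invisible(x)
}

#' Read an aligned FASTA into an `aligned_set`
#'
#' @inheritParams read_fasta
#' @return An [aligned_set()].
#' @export
read_aligned_fasta <- function(path, annotations) {
  if (!file.exists(path)) stop("aligned FASTA not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty alignment file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  hit <- match(ids, annotations$record_id)
  if (anyNA(hit)) {
    message(sum(is.na(hit)), " aligned record(s) without annotation dropped")
  }
  keep <- !is.na(hit)
  aligned_set(ids[keep], annotations$species_id[hit[keep]],
              toupper(as.character(set))[keep])
}

#' Remove gaps from an aligned row
#' @param aligned Gapped character vector.
#' @return Ungapped character vector.
#' @export
degap <- function(aligned) gsub("-", "", aligned, fixed = TRUE)

#' Remove truncated sequences
#'
#' Drops records whose length is at least `fraction` shorter than the mean
#' length of the input set, i.e. length <= (1 - fraction) * mean.  The mean
#' is computed once over the original input, not iteratively.
#'
#' @param records Sequence data.frame of a single molecule.
#' @param fraction Truncation fraction in (0, 1); default 0.25.
#' @return list with `records` (survivors, unchanged) and `removed`
#'   (data.frame `record_id`, `length`, `cutoff`).
#' @export
filter_truncated <- function(records, fraction = 0.25) {
  if (nrow(records) == 0) stop("filter_truncated: empty input")
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  if (length(unique(records$molecule)) != 1) {
    stop("filter_truncated expects records of a single molecule")
  }
  len <- nchar(records$residues)
  cutoff <- (1 - fraction) * mean(len)
  drop <- len <= cutoff
  list(
    records = records[!drop, , drop = FALSE],
    removed = data.frame(record_id = records$record_id[drop],
                         length = len[drop],
                         cutoff = rep(cutoff, sum(drop)))
  )
}

#' Keep one sequence record per species
#'
#' When a species carries several records of the same molecule (e.g. the
#' rRNA operons rrnA, rrnB, ...), the record with the lexicographically
#' smallest `record_id` is kept, which selects rrnA-style ids and is fully
#' deterministic (C-locale ordering).
#'
#' @param records Sequence data.frame of a single molecule.
#' @return Deduplicated data.frame, one row per `species_id`.
#' @export
dedup_one_per_species <- function(records) {
  if (nrow(records) == 0) return(records)
  o <- order(records$species_id, records$record_id, method = "radix")
  records <- records[o, , drop = FALSE]
  out <- records[!duplicated(records$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map ungapped reference positions to alignment columns
#'
#' @param aligned An [aligned_set()].
#' @param reference_record_id Row providing the coordinate system.
#' @param positions 1-based positions in the ungapped reference.
#' @return Integer alignment columns (1-based).
#' @export
map_reference_columns <- function(aligned, reference_record_id, positions) {
  i <- match(reference_record_id, aligned$rows$record_id)
  if (is.na(i)) stop("reference row not found: ", reference_record_id)
  chars <- strsplit(aligned$rows$aligned[i], "")[[1]]
  ungapped_cols <- which(chars != "-")
  if (any(positions < 1 | positions > length(ungapped_cols))) {
    stop("reference position beyond ungapped reference length (",
         length(ungapped_cols), ")")
  }
  ungapped_cols[positions]
}

#' Remove rows lacking the decoding-site residues
#'
#' Emulates the removal of seemingly truncated 16S rRNA sequences that lack
#' the decoding-site adenosines (A1492/A1493 in E. coli numbering).  The
#' reference positions are mapped to alignment columns; a row is removed if
#' it carries a gap at either column, or (in strict mode) any base other
#' than A.
#'
#' @param aligned An [aligned_set()].
#' @param reference_record_id Reference row id.
#' @param reference_positions 1-based ungapped reference positions,
#'   default `c(1492, 1493)`.
#' @param strict If TRUE additionally require the base to be 'A'.
#' @return list with `aligned` (filtered [aligned_set()]) and `removed`
#'   (data.frame of removed rows and the offending characters).
#' @export
filter_decoding_site <- function(aligned, reference_record_id,
                                 reference_positions = c(1492, 1493),
                                 strict = FALSE) {
  cols <- map_reference_columns(aligned, reference_record_id,
                                reference_positions)
  chars <- lapply(strsplit(aligned$rows$aligned, ""), `[`, cols)
  bad <- vapply(chars, function(x) {
    any(x == "-") || (strict && any(x != "A"))
  }, logical(1))
  list(
    aligned = aligned_set(aligned$rows$record_id[!bad],
                          aligned$rows$species_id[!bad],
                          aligned$rows$aligned[!bad],
                          width = aligned$width),
    removed = data.frame(
      record_id = aligned$rows$record_id[bad],
      found = vapply(chars[bad], paste, character(1), collapse = "")
    )
  )
}
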