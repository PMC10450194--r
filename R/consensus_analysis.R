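## Comparison of cold-adapted vs heat-adapted consensus sequences.  For
## each alignment column a per-class profile (consensus residue and its
## conservation among non-gap rows) is computed; two search strategies
## then flag temperature-associated residues:
##   identity_switch    - highly conserved in BOTH classes but with a
##                        different consensus residue (e.g. F in the cold
##                        class replaced by Y in the hot class);
##   conservation_shift - conserved (>= threshold) in exactly one class
##                        (e.g. <40% in cold rows, 100% in hot rows).

#' Split an alignment into cold- and heat-adapted classes
#'
#' Class membership uses strict inequalities: cold rows have OGT below
#' `cold_max`, hot rows above `hot_min`; species exactly at a boundary and
#' all intermediate species are excluded.
#'
#' @param aligned An [aligned_set()].
#' @param annotations Per-species annotation data.frame with `species_id`
#'   and `ogt_celsius`.
#' @param cold_max Upper OGT bound of the cold class (default 20).
#' @param hot_min Lower OGT bound of the hot class (default 60).
#' @param min_class_size Below this row count a class triggers a warning
#'   that its consensus is unreliable (default 5).
#' @return list with `cold` and `hot` [aligned_set()]s.
#' @export
split_alignment_by_ogt <- function(aligned, annotations, cold_max = 20,
                                   hot_min = 60, min_class_size = 5) {
  if (cold_max >= hot_min) stop("cold_max must be below hot_min")
  ogt <- annotations$ogt_celsius[match(aligned$rows$species_id,
                                       annotations$species_id)]
  if (anyNA(ogt)) {
    stop("unannotated species in alignment: ",
         paste(unique(aligned$rows$species_id[is.na(ogt)]), collapse = ", "))
  }
  pick <- function(idx, label) {
    if (length(idx) == 0) stop("empty temperature class: ", label)
    if (length(idx) < min_class_size) {
      warning(label, " class has only ", length(idx),
              " rows; consensus may be unreliable")
    }
    aligned_set(aligned$rows$record_id[idx], aligned$rows$species_id[idx],
                aligned$rows$aligned[idx])
  }
  list(cold = pick(which(ogt < cold_max), "cold"),
       hot = pick(which(ogt > hot_min), "hot"))
}

#' Per-column consensus profiles of an alignment
#'
#' For every column the consensus residue is the most frequent non-gap
#' character (ties broken alphabetically and recorded in the `ties`
#' attribute); conservation is its frequency among non-gap rows only.
#'
#' @param aligned An [aligned_set()] with at least one row.
#' @return data.frame with one row per column: `column` (1-based),
#'   `consensus`, `conservation`, `gap_fraction`, `n_rows`, `n_nongap`.
#'   Fully gapped columns get `NA` consensus and conservation.
#' @export
column_profiles <- function(aligned) {
  if (nrow(aligned$rows) == 0) stop("column_profiles: empty alignment")
  mat <- do.call(rbind, strsplit(aligned$rows$aligned, ""))
  n <- nrow(mat)
  ties <- integer(0)
  prof <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    nongap <- col[col != "-"]
    if (length(nongap) == 0) {
      return(data.frame(column = j, consensus = NA_character_,
                        conservation = NA_real_, gap_fraction = 1,
                        n_rows = n, n_nongap = 0L))
    }
    counts <- table(nongap)
    top <- counts[counts == max(counts)]
    if (length(top) > 1) ties <<- c(ties, j)
    consensus <- sort(names(top))[1]
    data.frame(column = j, consensus = consensus,
               conservation = as.numeric(max(counts)) / length(nongap),
               gap_fraction = 1 - length(nongap) / n,
               n_rows = n, n_nongap = length(nongap))
  })
  out <- do.call(rbind, prof)
  attr(out, "ties") <- ties
  out
}

#' Find temperature-associated alignment columns
#'
#' Compares the cold- and hot-class profiles column by column and reports
#' the union of the two search strategies (identity switches and
#' conservation shifts).  Columns with more than `max_gap_fraction` gaps in
#' either class are skipped as unreliable and listed in the
#' `skipped_columns` attribute.  The two categories are mutually exclusive
#' by construction.
#'
#' @param cold_profiles,hot_profiles [column_profiles()] outputs with equal
#'   column counts.
#' @param threshold Conservation threshold (default 0.60).
#' @param max_gap_fraction Gap tolerance per class (default 0.5).
#' @return data.frame `column`, `category`, `cold_consensus`,
#'   `cold_conservation`, `hot_consensus`, `hot_conservation`, `direction`
#'   (`gain-in-heat`/`loss-in-heat` for shifts, `NA` for switches).
#' @export
find_temperature_associated_sites <- function(cold_profiles, hot_profiles,
                                              threshold = 0.60,
                                              max_gap_fraction = 0.5) {
  if (nrow(cold_profiles) != nrow(hot_profiles)) {
    stop("column-count mismatch between classes: ", nrow(cold_profiles),
         " vs ", nrow(hot_profiles))
  }
  if (!(threshold > 0.5 && threshold <= 1)) {
    stop("conservation threshold must lie in (0.5, 1]")
  }
  skip <- cold_profiles$gap_fraction > max_gap_fraction |
    hot_profiles$gap_fraction > max_gap_fraction |
    is.na(cold_profiles$conservation) | is.na(hot_profiles$conservation)
  cold_hi <- !skip & cold_profiles$conservation >= threshold
  hot_hi <- !skip & hot_profiles$conservation >= threshold
  switch_ <- cold_hi & hot_hi &
    cold_profiles$consensus != hot_profiles$consensus
  shift <- xor(cold_hi, hot_hi)
  idx <- which(switch_ | shift)
  out <- data.frame(
    column = cold_profiles$column[idx],
    category = ifelse(switch_[idx], "identity_switch", "conservation_shift"),
    cold_consensus = cold_profiles$consensus[idx],
    cold_conservation = cold_profiles$conservation[idx],
    hot_consensus = hot_profiles$consensus[idx],
    hot_conservation = hot_profiles$conservation[idx],
    direction = ifelse(switch_[idx], NA_character_,
                       ifelse(hot_hi[idx], "gain-in-heat", "loss-in-heat"))
  )
  rownames(out) <- NULL
  attr(out, "skipped_columns") <- cold_profiles$column[skip]
  out
}
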