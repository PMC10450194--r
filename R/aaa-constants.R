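## Alphabets used for validation throughout the package.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "Z", "X", "U", "O")
NT_LETTERS <- c("A", "C", "G", "U", "N")

#' The seven-residue thermophily set
#'
#' The amino acids whose summed fraction in a protein set correlates with
#' optimal growth temperature.  The set is written YVIWREL or IVYWREL in
#' the literature; both orderings denote the same residues.
#'
#' @format Character vector of length 7.
#' @export
YVIWREL_SET <- c("Y", "V", "I", "W", "R", "E", "L")

#' The nine metal-binding ribosomal proteins
#'
#' Ribosomal proteins whose smallest members coordinate Zn2+ ions (eight
#' proteins) or an iron-sulfur cluster (uS4) in thermophiles, ordered by
#' increasing occupancy midpoint used by the synthetic generator
#' (smallest protein first).
#'
#' @format Character vector of length 9.
#' @export
METAL_PROTEINS <- c("bL36", "bL33", "bL32", "uS14", "bL31", "bL28", "bS18",
                    "uS4", "uL24")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_nucleotide_molecule <- function(molecule) {
  grepl("16S|23S|5S|18S|rRNA|RNA", molecule)
}
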