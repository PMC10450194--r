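# Small in-code fixtures shared across test files.

mk_records <- function(record_id, species_id, molecule, residues) {
  data.frame(record_id = record_id, species_id = species_id,
             molecule = molecule, residues = residues, source_tag = "")
}

mk_species <- function(species_id, ogt, phylum = "PhylumT") {
  data.frame(species_id = species_id, phylum = phylum, ogt_celsius = ogt)
}

write_tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

mk_record_annotations <- function(record_id, species_id, molecule,
                                  ogt = 37) {
  data.frame(record_id = record_id, species_id = species_id,
             molecule = molecule, phylum = "PhylumT",
             ogt_celsius = rep(ogt, length.out = length(record_id)),
             plasmid = FALSE)
}
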