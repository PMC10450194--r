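## Seeded synthetic data emulating the study conditions: species annotated
## with uniformly drawn OGTs; per-protein metal-motif occupancy rising
## with OGT along a logistic curve (midpoints ordered by protein size);
## 16S rRNA whose GC rises and U falls with OGT; proteomes whose YVIWREL
## content rises with OGT; occasional C+/C- paralog pairs; and planted
## outlier species.  One seed drives every stage (each stage derives a
## fixed offset from it), so two runs with the same config are identical.

#' Configuration of the synthetic-data generator
#'
#' Defaults encode the emulated study conditions: 500 species with OGT
#' uniform on (1, 90) degrees Celsius so all nine decade bins populate;
#' logistic motif occupancy with midpoints 30..55 degrees in protein-size
#' order (bL36 lowest, uL24 highest) and steepness 0.05 per degree.  The
#' steepness/midpoint span is calibrated to the generator's contract that
#' per-bin only-C+ fractions rise detectably at a few dozen species per
#' bin: steeper curves saturate early and leave several top bins
#' separated by less than one binomial standard error, so their sampled
#' fractions permute at random.  16S GC = 0.50 + 0.0015 OGT (sd
#' 0.01) and U = 0.22 - 0.0008 OGT (sd 0.008) over 1500 nt; YVIWREL =
#' 0.40 + 0.0008 OGT (sd 0.005); 5% of species carry a C+/C- paralog
#' pair.
#'
#' @param n_species Number of species (>= 1).
#' @param ogt_range OGT range in degrees Celsius, drawn uniformly.
#' @param seed Integer master seed; stage s uses `seed + s`.
#' @param occupancy_midpoint Named numeric: OGT at which each protein is
#'   C+ in half the species.
#' @param occupancy_steepness Logistic steepness per degree Celsius; `Inf`
#'   gives a hard threshold at the midpoint.
#' @param protein_lengths Named integer: generated sequence length per
#'   protein.
#' @param gc_intercept,gc_slope,gc_noise_sd Linear model of 16S GC on OGT.
#' @param u_intercept,u_slope,u_noise_sd Linear model of 16S U on OGT
#'   (negative slope by default).
#' @param rrna_length Length of generated 16S sequences (nt).
#' @param yviwrel_intercept,yviwrel_slope,yviwrel_noise_sd Linear model of
#'   proteome YVIWREL content on OGT.
#' @param proteome_n_records,proteome_record_length Records per species
#'   and residues per record in the YVIWREL set.
#' @param paralog_prob Probability that a species emits both a C+ and a
#'   C- copy of a protein.
#' @param outlier_spec Optional data.frame describing planted outliers;
#'   see [plant_outliers()].
#' @param max_rejection Attempts allowed when rejection-sampling a
#'   pattern-free backbone.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 500,
                       ogt_range = c(1, 90),
                       seed = 1,
                       occupancy_midpoint = stats::setNames(
                         seq(30, 55, length.out = 9), METAL_PROTEINS),
                       occupancy_steepness = 0.05,
                       protein_lengths = c(bL36 = 37, bL33 = 55, bL32 = 57,
                                           uS14 = 61, bL31 = 70, bL28 = 78,
                                           bS18 = 75, uS4 = 205, uL24 = 104),
                       gc_intercept = 0.50, gc_slope = 0.0015,
                       gc_noise_sd = 0.01,
                       u_intercept = 0.22, u_slope = -0.0008,
                       u_noise_sd = 0.008,
                       rrna_length = 1500,
                       yviwrel_intercept = 0.40, yviwrel_slope = 0.0008,
                       yviwrel_noise_sd = 0.005,
                       proteome_n_records = 3,
                       proteome_record_length = 150,
                       paralog_prob = 0.05,
                       outlier_spec = NULL,
                       max_rejection = 1000) {
  if (n_species < 1) stop("n_species must be >= 1")
  if (length(ogt_range) != 2 || ogt_range[1] >= ogt_range[2]) {
    stop("invalid ogt_range")
  }
  if (paralog_prob < 0 || paralog_prob > 1) stop("paralog_prob not in [0,1]")
  if (!setequal(names(occupancy_midpoint), METAL_PROTEINS)) {
    stop("occupancy_midpoint must name exactly the nine scheme proteins")
  }
  structure(as.list(environment()), class = "sim_config")
}

clip01 <- function(x, lo = 0.05, hi = 0.95) pmin(hi, pmax(lo, x))

occupancy_prob <- function(ogt, midpoint, steepness) {
  if (is.infinite(steepness)) {
    return(ifelse(ogt > midpoint, 1, ifelse(ogt < midpoint, 0, 0.5)))
  }
  stats::plogis((ogt - midpoint) * steepness)
}

#' Simulate annotated species
#'
#' OGTs drawn uniformly over `ogt_range`; synthetic phyla ("Phylum01"..
#' "Phylum08") assigned round-robin.
#'
#' @param config A [sim_config()].
#' @return data.frame `species_id`, `phylum`, `ogt_celsius`.
#' @export
simulate_species <- function(config) {
  set.seed(config$seed + 0L)
  n <- config$n_species
  data.frame(
    species_id = sprintf("SP%04d", seq_len(n)),
    phylum = paste0("Phylum", sprintf("%02d", (seq_len(n) - 1) %% 8 + 1)),
    ogt_celsius = stats::runif(n, config$ogt_range[1], config$ogt_range[2])
  )
}

## Random backbone without cysteine: embedding a motif into it can never
## create a second, unintended motif variant (all patterns require C).
cplus_backbone_alphabet <- setdiff(AA_STANDARD, "C")

embed_motif <- function(len, pattern) {
  k1 <- length(pattern$element1)
  k2 <- length(pattern$element2)
  if (len < k1 + k2) stop("protein length too short for its motif")
  chars <- sample(cplus_backbone_alphabet, len, replace = TRUE)
  start1 <- sample.int(len - k1 - k2 + 1L, 1)
  max_spacer <- len - (start1 + k1 - 1L) - k2
  spacer <- sample.int(max_spacer + 1L, 1) - 1L
  start2 <- start1 + k1 + spacer
  place <- function(start, element) {
    for (j in seq_along(element)) {
      allowed <- element[[j]]
      if (!is.null(allowed)) {
        chars[start + j - 1L] <<- allowed[sample.int(length(allowed), 1)]
      }
    }
  }
  place(start1, pattern$element1)
  place(start2, pattern$element2)
  paste(chars, collapse = "")
}

pattern_free_backbone <- function(len, patterns, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    s <- paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
    hit <- FALSE
    for (p in patterns) {
      if (!is.null(match_pattern(s, p))) { hit <- TRUE; break }
    }
    if (!hit) return(s)
  }
  stop("could not sample a pattern-free backbone after ", max_attempts,
       " attempts")
}

#' Simulate ribosomal-protein sequences with planted motif occupancy
#'
#' For each species and protein, the species is C+ with probability
#' logistic((OGT - midpoint) * steepness).  A C+ sequence is a random
#' cysteine-free backbone with the protein's motif embedded in order and
#' without overlap (for bL33 the CCCC/CCCD/CCCE variant is drawn with
#' probabilities 0.8/0.12/0.08); a C- sequence is rejection-sampled
#' against all patterns of the protein, guaranteeing label purity.  With
#' probability `paralog_prob` both copies are emitted and the true call
#' is `both`.
#'
#' @param annotations Species table from [simulate_species()].
#' @param scheme A [default_scheme()].
#' @param config A [sim_config()].
#' @return list with `records` (sequence data.frame) and `truth`
#'   (data.frame `species_id`, `protein`, `call_truth`, `variant_truth`).
#' @export
simulate_protein_sequences <- function(annotations, scheme, config) {
  set.seed(config$seed + 1L)
  proteins <- METAL_PROTEINS
  recs <- vector("list", nrow(annotations) * length(proteins))
  truth <- vector("list", length(recs))
  k <- 0L
  for (i in seq_len(nrow(annotations))) {
    sp <- annotations$species_id[i]
    ogt <- annotations$ogt_celsius[i]
    for (prot in proteins) {
      k <- k + 1L
      p <- occupancy_prob(ogt, config$occupancy_midpoint[[prot]],
                          config$occupancy_steepness)
      len <- config$protein_lengths[[prot]]
      paralog <- stats::runif(1) < config$paralog_prob
      emit <- make_protein_copies(sp, prot, len, p, paralog, scheme, config)
      recs[[k]] <- emit$records
      truth[[k]] <- emit$truth
    }
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
}

make_protein_copies <- function(sp, prot, len, p, paralog, scheme, config) {
  pats <- scheme$patterns[[prot]]
  draw_cplus <- function() {
    if (prot == "bL33") {
      v <- sample(c("CCCC", "CCCD", "CCCE"), 1,
                  prob = c(0.80, 0.12, 0.08))
      list(seq = embed_motif(len, pats[[v]]), variant = v)
    } else {
      list(seq = embed_motif(len, pats[[1]]), variant = "canonical")
    }
  }
  draw_cminus <- function() {
    list(seq = pattern_free_backbone(len, pats, config$max_rejection),
         variant = "none")
  }
  if (paralog) {
    plus <- draw_cplus()
    minus <- draw_cminus()
    records <- data.frame(
      record_id = paste0(sp, "_", prot, "_", 1:2),
      species_id = sp, molecule = prot,
      residues = c(plus$seq, minus$seq), source_tag = c("cplus", "cminus"))
    truth <- data.frame(species_id = sp, protein = prot,
                        call_truth = "both", variant_truth = plus$variant)
  } else {
    is_plus <- stats::runif(1) < p
    copy <- if (is_plus) draw_cplus() else draw_cminus()
    records <- data.frame(
      record_id = paste0(sp, "_", prot, "_1"),
      species_id = sp, molecule = prot, residues = copy$seq,
      source_tag = if (is_plus) "cplus" else "cminus")
    truth <- data.frame(
      species_id = sp, protein = prot,
      call_truth = if (is_plus) "only_cplus" else "only_cminus",
      variant_truth = copy$variant)
  }
  list(records = records, truth = truth)
}

#' Default helix coordinate table for a synthetic reference
#'
#' Regularly spaced 30-nt "helices" every 50 nt, covering about 60% of
#' the reference; a synthetic stand-in for a real secondary-structure
#' table, adequate because the generator's composition model is uniform
#' along the molecule.
#'
#' @param length Reference length (default 1500).
#' @param reference_record_id Reference row id.
#' @return A [helix_set()].
#' @export
default_helix_table <- function(length = 1500,
                                reference_record_id = "REF_16S") {
  starts <- seq(11, length - 40, by = 50)
  helix_set(reference_record_id,
            data.frame(start = starts, end = starts + 29,
                       name = paste0("h", seq_along(starts))))
}

sample_rrna_seq <- function(len, gc, u) {
  probs <- c(A = 1 - gc - u, C = gc / 2, G = gc / 2, U = u)
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

#' Simulate a gap-free 16S rRNA alignment with composition trends
#'
#' Per species, the expected GC is `gc_intercept + gc_slope * OGT` and the
#' expected U is `u_intercept + u_slope * OGT` (normal noise on each,
#' means clipped to \[0.05, 0.95\]); bases are drawn i.i.d. per position,
#' so all rows have equal length and the "alignment" is gap-free.  A
#' reference row (id `REF_16S`, composition at the intercepts) is
#' prepended to carry the helix coordinate system, and the decoding-site
#' positions 1492/1493 are set to 'A' in every row when the molecule is
#' long enough.
#'
#' @param annotations Species table.
#' @param config A [sim_config()].
#' @param helices Optional [helix_set()]; defaults to
#'   [default_helix_table()] for the configured length.
#' @return list with `aligned` ([aligned_set()]), `reference_record_id`,
#'   `helices`, and `truth` (data.frame of the per-species target GC/U).
#' @export
simulate_rrna <- function(annotations, config, helices = NULL) {
  set.seed(config$seed + 2L)
  len <- config$rrna_length
  if (is.null(helices)) helices <- default_helix_table(len, "REF_16S")
  if (max(helices$intervals$end) > len) {
    stop("helix table exceeds generated reference length")
  }
  gc <- clip01(config$gc_intercept + config$gc_slope *
                 annotations$ogt_celsius +
                 stats::rnorm(nrow(annotations), 0, config$gc_noise_sd))
  u <- clip01(config$u_intercept + config$u_slope *
                annotations$ogt_celsius +
                stats::rnorm(nrow(annotations), 0, config$u_noise_sd))
  if (any(gc + u > 1)) stop("infeasible GC/U combination (sum > 1)")
  ref <- sample_rrna_seq(len, clip01(config$gc_intercept),
                         clip01(config$u_intercept))
  rows <- vapply(seq_len(nrow(annotations)), function(i) {
    sample_rrna_seq(len, gc[i], u[i])
  }, character(1))
  fix_a <- function(s) {
    if (len >= 1493) {
      substr(s, 1492, 1493) <- "AA"
    }
    s
  }
  rows <- vapply(rows, fix_a, character(1), USE.NAMES = FALSE)
  ref <- fix_a(ref)
  aligned <- aligned_set(
    record_id = c("REF_16S", paste0(annotations$species_id, "_16S")),
    species_id = c("REF", annotations$species_id),
    aligned = c(ref, rows))
  list(aligned = aligned, reference_record_id = "REF_16S",
       helices = helices,
       truth = data.frame(species_id = annotations$species_id,
                          gc_target = gc, u_target = u))
}

## 13 filler residues disjoint from the YVIWREL set.
yviwrel_filler <- setdiff(AA_STANDARD, YVIWREL_SET)

#' Simulate proteome records with a planted YVIWREL trend
#'
#' Per species, `proteome_n_records` records of fixed length whose
#' residues fall in the YVIWREL set with probability
#' `yviwrel_intercept + yviwrel_slope * OGT` (plus clipped normal noise)
#' and in a disjoint 13-letter filler set otherwise.
#'
#' @param annotations Species table.
#' @param config A [sim_config()].
#' @return list with `records` (sequence data.frame, molecule "MGS") and
#'   `truth` (per-species target fraction).
#' @export
simulate_proteome_content <- function(annotations, config) {
  set.seed(config$seed + 3L)
  q <- clip01(config$yviwrel_intercept + config$yviwrel_slope *
                annotations$ogt_celsius +
                stats::rnorm(nrow(annotations), 0, config$yviwrel_noise_sd))
  len <- config$proteome_record_length
  m <- config$proteome_n_records
  recs <- lapply(seq_len(nrow(annotations)), function(i) {
    seqs <- vapply(seq_len(m), function(j) {
      in_set <- stats::runif(len) < q[i]
      chars <- ifelse(in_set,
                      sample(YVIWREL_SET, len, replace = TRUE),
                      sample(yviwrel_filler, len, replace = TRUE))
      paste(chars, collapse = "")
    }, character(1))
    data.frame(record_id = paste0(annotations$species_id[i], "_MGS", seq_len(m)),
               species_id = annotations$species_id[i], molecule = "MGS",
               residues = seqs, source_tag = "proteome")
  })
  list(records = do.call(rbind, recs),
       truth = data.frame(species_id = annotations$species_id,
                          yviwrel_target = q))
}

#' Plant outlier species into a simulated dataset
#'
#' Rebuilds designated species with a forced C+ protein count (their
#' protein sequences are regenerated: the first `forced_cplus_count`
#' proteins in midpoint order become C+, the rest C-, no paralogs) and/or
#' offsets their composition targets (regenerating the 16S or proteome
#' records with a shifted mean).  Ground truth is recorded in
#' `dataset$planted_outliers`.
#'
#' @param dataset Output of [simulate_dataset()] (or the same structure).
#' @param outlier_spec data.frame with `species_index` and any of
#'   `forced_cplus_count` (0..9), `gc_offset`, `yviwrel_offset`.
#' @return The modified dataset.
#' @export
plant_outliers <- function(dataset, outlier_spec) {
  if (is.null(outlier_spec) || nrow(outlier_spec) == 0) return(dataset)
  config <- dataset$config
  scheme <- default_scheme()
  set.seed(config$seed + 4L)
  ann <- dataset$annotations
  if (any(outlier_spec$species_index < 1 |
          outlier_spec$species_index > nrow(ann))) {
    stop("outlier species_index out of range")
  }
  planted <- list()
  for (r in seq_len(nrow(outlier_spec))) {
    i <- outlier_spec$species_index[r]
    sp <- ann$species_id[i]
    forced <- outlier_spec$forced_cplus_count[r] %||% NA
    if (!is.null(outlier_spec$forced_cplus_count) && !is.na(forced)) {
      stopifnot(forced >= 0, forced <= 9)
      plus_set <- METAL_PROTEINS[seq_len(forced)]
      keep <- dataset$proteins$records$species_id != sp
      keep_t <- dataset$proteins$truth$species_id != sp
      new <- lapply(METAL_PROTEINS, function(prot) {
        make_protein_copies(sp, prot, config$protein_lengths[[prot]],
                            p = as.numeric(prot %in% plus_set),
                            paralog = FALSE, scheme = scheme,
                            config = config)
      })
      dataset$proteins$records <- rbind(
        dataset$proteins$records[keep, , drop = FALSE],
        do.call(rbind, lapply(new, `[[`, "records")))
      dataset$proteins$truth <- rbind(
        dataset$proteins$truth[keep_t, , drop = FALSE],
        do.call(rbind, lapply(new, `[[`, "truth")))
      planted[[length(planted) + 1]] <- data.frame(
        species_id = sp, kind = "forced_cplus_count", value = forced)
    }
    gc_off <- outlier_spec$gc_offset[r] %||% NA
    if (!is.null(outlier_spec$gc_offset) && !is.na(gc_off)) {
      tr <- dataset$rrna$truth
      j <- match(sp, tr$species_id)
      new_gc <- clip01(tr$gc_target[j] + gc_off)
      row_id <- paste0(sp, "_16S")
      k <- match(row_id, dataset$rrna$aligned$rows$record_id)
      dataset$rrna$aligned$rows$aligned[k] <-
        sample_rrna_seq(config$rrna_length, new_gc, tr$u_target[j])
      dataset$rrna$truth$gc_target[j] <- new_gc
      planted[[length(planted) + 1]] <- data.frame(
        species_id = sp, kind = "gc_offset", value = gc_off)
    }
    yv_off <- outlier_spec$yviwrel_offset[r] %||% NA
    if (!is.null(outlier_spec$yviwrel_offset) && !is.na(yv_off)) {
      tr <- dataset$proteome$truth
      j <- match(sp, tr$species_id)
      new_q <- clip01(tr$yviwrel_target[j] + yv_off)
      len <- config$proteome_record_length
      idx <- which(dataset$proteome$records$species_id == sp)
      for (k in idx) {
        in_set <- stats::runif(len) < new_q
        chars <- ifelse(in_set, sample(YVIWREL_SET, len, replace = TRUE),
                        sample(yviwrel_filler, len, replace = TRUE))
        dataset$proteome$records$residues[k] <- paste(chars, collapse = "")
      }
      dataset$proteome$truth$yviwrel_target[j] <- new_q
      planted[[length(planted) + 1]] <- data.frame(
        species_id = sp, kind = "yviwrel_offset", value = yv_off)
    }
  }
  dataset$planted_outliers <- do.call(rbind, planted)
  dataset
}

#' Simulate a complete dataset
#'
#' Runs every generator stage in a fixed order under one master seed:
#' species, protein sequences, 16S rRNA, proteome, planted outliers.
#'
#' @param config A [sim_config()].
#' @param scheme A [default_scheme()].
#' @return list with `config`, `annotations`, `proteins`
#'   (`records`/`truth`), `rrna` (`aligned`/`helices`/`truth`),
#'   `proteome` (`records`/`truth`) and optionally `planted_outliers`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             scheme = default_scheme()) {
  ann <- simulate_species(config)
  dataset <- list(
    config = config,
    annotations = ann,
    proteins = simulate_protein_sequences(ann, scheme, config),
    rrna = simulate_rrna(ann, config),
    proteome = simulate_proteome_content(ann, config)
  )
  if (!is.null(config$outlier_spec)) {
    dataset <- plant_outliers(dataset, config$outlier_spec)
  }
  dataset
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Produces the file layout consumed by [run_pipeline()]: `species.tsv`,
#' `records.tsv` (per-record annotations), `proteins.fasta`,
#' `rrna_aligned.fasta`, `proteome.fasta`, `helices.tsv`, and
#' `ground_truth.tsv`.
#'
#' @param dataset From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(dataset$annotations, "species.tsv")
  rec_ann <- function(records, species) {
    idx <- match(records$species_id, species$species_id)
    data.frame(record_id = records$record_id,
               species_id = records$species_id,
               molecule = records$molecule,
               phylum = species$phylum[idx],
               ogt_celsius = species$ogt_celsius[idx],
               plasmid = FALSE)
  }
  rrna_rows <- dataset$rrna$aligned$rows
  rrna_recs <- data.frame(record_id = rrna_rows$record_id,
                          species_id = rrna_rows$species_id,
                          molecule = "16S")
  sp_plus_ref <- rbind(dataset$annotations,
                       data.frame(species_id = "REF", phylum = "reference",
                                  ogt_celsius = NA))
  idx <- match(rrna_recs$species_id, sp_plus_ref$species_id)
  rrna_ann <- data.frame(rrna_recs,
                         phylum = sp_plus_ref$phylum[idx],
                         ogt_celsius = sp_plus_ref$ogt_celsius[idx],
                         plasmid = FALSE)
  all_ann <- rbind(rec_ann(dataset$proteins$records, dataset$annotations),
                   rrna_ann,
                   rec_ann(dataset$proteome$records, dataset$annotations))
  tsv(all_ann, "records.tsv")
  write_fasta(dataset$proteins$records, file.path(dir, "proteins.fasta"))
  write_fasta(data.frame(record_id = rrna_rows$record_id,
                         residues = rrna_rows$aligned),
              file.path(dir, "rrna_aligned.fasta"))
  write_fasta(dataset$proteome$records, file.path(dir, "proteome.fasta"))
  tsv(dataset$rrna$helices$intervals, "helices.tsv")
  tsv(dataset$proteins$truth, "ground_truth.tsv")
  invisible(dir)
}
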