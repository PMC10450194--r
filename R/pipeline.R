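## End-to-end analysis: quality control -> isoform classification ->
## consensus comparison -> content proxies -> proxy-vs-OGT comparison,
## with a machine-readable manifest.  Input is a directory in the layout
## written by write_dataset(); every threshold defaults to the study's
## printed value and is recorded in the manifest.

#' Pipeline configuration
#'
#' @param input_dir Directory holding `species.tsv`, `records.tsv`,
#'   `proteins.fasta`, `rrna_aligned.fasta`, `proteome.fasta`,
#'   `helices.tsv` (see [write_dataset()]).
#' @param out_dir Output directory for TSVs and the manifest.
#' @param truncation_fraction Truncated-sequence filter (default 0.25).
#' @param conservation_threshold Consensus threshold (default 0.60).
#' @param cold_max,hot_min Temperature-class bounds (defaults 20 / 60).
#' @param outlier_delta Minimum C+ count deviation (default 3).
#' @param top_n Extreme species per proxy at `t_extreme` (default 10).
#' @param t_extreme,t_tol Target temperature and matching tolerance for
#'   the extreme-species analysis (defaults 37 / 0.5).
#' @param strict_decoding Require 'A' (not merely non-gap) at the
#'   decoding-site columns (default FALSE).
#' @param reference_record_id Reference row of the rRNA alignment.
#' @param decoding_positions Ungapped reference positions of the decoding
#'   site (default c(1492, 1493)).
#' @param min_class_size Warning threshold for tiny consensus classes.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(input_dir, out_dir,
                            truncation_fraction = 0.25,
                            conservation_threshold = 0.60,
                            cold_max = 20, hot_min = 60,
                            outlier_delta = 3, top_n = 10,
                            t_extreme = 37, t_tol = 0.5,
                            strict_decoding = FALSE,
                            reference_record_id = "REF_16S",
                            decoding_positions = c(1492, 1493),
                            min_class_size = 5,
                            seed = 1) {
  stopifnot(truncation_fraction > 0, truncation_fraction < 1,
            conservation_threshold > 0.5, conservation_threshold <= 1,
            cold_max < hot_min, outlier_delta >= 1, top_n >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_msg <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: (1) QC - read sequences, drop truncated proteins, drop rRNA
#' rows lacking the decoding site, keep one rRNA per species; (2)
#' classify - isoform calls, per-species C+ counts, bL33 variants; (3)
#' consensus - cold/hot consensus comparison per protein; (4) content -
#' whole and helical 16S GC, U content, YVIWREL content; (5) compare -
#' per-bin curves, OLS fits on the species common to all proxies, phylum
#' means and both outlier analyses.  All tables are written to
#' `config$out_dir` together with `manifest.json` (effective thresholds,
#' per-stage record counts, package version).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every result table plus the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  need <- c("species.tsv", "records.tsv", "proteins.fasta",
            "rrna_aligned.fasta", "proteome.fasta", "helices.tsv")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing) > 0) {
    stop("missing input file(s): ",
         paste(file.path(ind, missing), collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  ## -- qc ------------------------------------------------------------
  stage_msg("qc", "reading inputs from ", ind)
  rec_ann <- run_stage("qc", read_annotation_table(file.path(ind, "records.tsv")))
  species <- run_stage("qc", utils::read.delim(file.path(ind, "species.tsv")))
  if ("plasmid" %in% names(rec_ann)) {
    rec_ann <- rec_ann[!isTRUE_vec(rec_ann$plasmid), , drop = FALSE]
  }
  prot <- run_stage("qc", read_fasta(file.path(ind, "proteins.fasta"), rec_ann))
  counts$proteins_read <- nrow(prot)
  kept <- lapply(split(prot, prot$molecule), function(p) {
    filter_truncated(p, config$truncation_fraction)$records
  })
  prot <- do.call(rbind, kept)
  rownames(prot) <- NULL
  counts$proteins_after_truncation <- nrow(prot)

  rrna <- run_stage("qc", read_aligned_fasta(file.path(ind, "rrna_aligned.fasta"),
                                             rec_ann))
  counts$rrna_read <- nrow(rrna$rows)
  dec <- run_stage("qc", filter_decoding_site(
    rrna, config$reference_record_id, config$decoding_positions,
    strict = config$strict_decoding))
  rrna <- dec$aligned
  counts$rrna_after_decoding_filter <- nrow(rrna$rows)
  ## one operon per species (reference row exempt)
  rows <- rrna$rows
  is_ref <- rows$record_id == config$reference_record_id
  dedup <- dedup_one_per_species(
    data.frame(record_id = rows$record_id[!is_ref],
               species_id = rows$species_id[!is_ref],
               molecule = "16S", residues = rows$aligned[!is_ref]))
  rrna <- aligned_set(c(rows$record_id[is_ref], dedup$record_id),
                      c(rows$species_id[is_ref], dedup$species_id),
                      c(rows$aligned[is_ref], dedup$residues))
  counts$rrna_after_dedup <- nrow(rrna$rows)

  proteome <- run_stage("qc", read_fasta(file.path(ind, "proteome.fasta"),
                                         rec_ann))
  counts$proteome_read <- nrow(proteome)
  helices <- run_stage("qc", read_helix_table(
    file.path(ind, "helices.tsv"), config$reference_record_id))

  ## -- classify ------------------------------------------------------
  stage_msg("classify", "calling isoforms for ",
            length(unique(prot$species_id)), " species")
  scheme <- default_scheme()
  calls <- run_stage("classify", classify_isoforms(prot, scheme))
  cnt <- cplus_count_table(calls)
  bl33 <- prot[prot$molecule == "bL33", , drop = FALSE]
  variants <- do.call(rbind, lapply(split(bl33, bl33$species_id), function(p) {
    v <- vapply(p$residues, classify_bl33_variant, character(1),
                USE.NAMES = FALSE)
    keep <- match(c("CCCC", "CCCD", "CCCE", "none"), v)
    data.frame(species_id = p$species_id[1],
               variant = v[keep[!is.na(keep)][1]])
  }))
  rownames(variants) <- NULL
  counts$isoform_calls <- nrow(calls)

  ## -- consensus -----------------------------------------------------
  stage_msg("consensus", "cold/hot consensus comparison per protein")
  consensus <- run_stage("consensus", {
    out <- lapply(sort(unique(prot$molecule)), function(p) {
      sub <- prot[prot$molecule == p, , drop = FALSE]
      if (length(unique(nchar(sub$residues))) != 1) return(NULL)
      al <- aligned_set(sub$record_id, sub$species_id, sub$residues)
      classes <- tryCatch(
        split_alignment_by_ogt(al, species, config$cold_max,
                               config$hot_min, config$min_class_size),
        error = function(e) NULL)
      if (is.null(classes)) return(NULL)
      sites <- find_temperature_associated_sites(
        column_profiles(classes$cold), column_profiles(classes$hot),
        config$conservation_threshold)
      if (nrow(sites) == 0) return(NULL)
      cbind(protein = p, sites)
    })
    do.call(rbind, out)
  })
  counts$consensus_sites <- if (is.null(consensus)) 0L else nrow(consensus)

  ## -- content -------------------------------------------------------
  stage_msg("content", "computing composition proxies")
  rrna_records <- {
    rows <- rrna$rows[rrna$rows$record_id != config$reference_record_id, ,
                      drop = FALSE]
    data.frame(record_id = rows$record_id, species_id = rows$species_id,
               molecule = "16S", residues = degap(rows$aligned))
  }
  gc_full <- run_stage("content", content_proxy_table(rrna_records, "gc_full"))
  u_tab <- content_proxy_table(rrna_records, "u_content")
  gc_hel <- run_stage("content", helical_gc_table(rrna, helices))
  yv <- run_stage("content", content_proxy_table(proteome, "yviwrel"))
  cplus_tab <- data.frame(species_id = cnt$species_id,
                          proxy_name = "cplus_count",
                          value = cnt$cplus_count,
                          n_residues_used = NA_integer_)
  proxies <- rbind(cplus_tab, gc_hel, gc_full, u_tab, yv)
  counts$proxy_rows <- nrow(proxies)

  ## -- compare -------------------------------------------------------
  stage_msg("compare", "fits, curves and outliers")
  curves <- do.call(rbind, lapply(split(calls, calls$protein),
                                  isoform_frequency_curves,
                                  annotations = species))
  rownames(curves) <- NULL
  bl33_bins <- bl33_variant_abundance(variants, species)
  common <- intersect_species(list(cplus_tab, gc_hel, u_tab, yv))
  fits <- lapply(common, function(tab) {
    ogt <- species$ogt_celsius[match(tab$species_id, species$species_id)]
    fit_linear_proxy(ogt, tab$value)
  })
  names(fits) <- vapply(common, function(t) t$proxy_name[1], character(1))
  fit_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(proxy_name = nm, slope = f$slope, intercept = f$intercept,
               pearson_r = f$pearson_r, n = f$n,
               residual_sd = f$residual_sd)
  }))
  cplus_out <- flag_cplus_outliers(cnt, species, config$outlier_delta)
  extremes <- do.call(rbind, lapply(
    list(gc_hel, gc_full, u_tab, yv), function(tab) {
      tryCatch(flag_extreme_at_temperature(tab, species, config$t_extreme,
                                           config$t_tol, config$top_n),
               error = function(e) NULL)
    }))
  phylum_means <- group_mean_cplus(cnt, species, by = "phylum")
  bin_means <- group_mean_cplus(cnt, species, by = "bin")
  counts$cplus_outliers <- nrow(cplus_out)

  ## -- write ---------------------------------------------------------
  outd <- config$out_dir
  tsv <- function(x, f) {
    if (is.null(x)) x <- data.frame()
    utils::write.table(x, file.path(outd, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(calls, "calls.tsv")
  tsv(cnt, "cplus_counts.tsv")
  tsv(variants, "bl33_variants.tsv")
  tsv(curves, "curves.tsv")
  tsv(bl33_bins, "bl33_bins.tsv")
  tsv(consensus, "consensus_sites.tsv")
  tsv(proxies, "proxies.tsv")
  tsv(fit_tab, "fit.tsv")
  tsv(cplus_out, "outliers_cplus.tsv")
  tsv(extremes, "outliers_extreme.tsv")
  tsv(phylum_means, "phylum_means.tsv")
  tsv(bin_means, "bin_means.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("thermoproxy")),
    config = unclass(config),
    counts = counts,
    proteins_classified = length(unique(calls$protein))
  )
  jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  stage_msg("done", "outputs in ", outd)
  invisible(list(calls = calls, counts = cnt, variants = variants,
                 curves = curves, bl33_bins = bl33_bins,
                 consensus = consensus, proxies = proxies, fits = fits,
                 fit_table = fit_tab, cplus_outliers = cplus_out,
                 extremes = extremes, phylum_means = phylum_means,
                 bin_means = bin_means, manifest = manifest))
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) x & !is.na(x)
  else x %in% c("TRUE", "true", "1", "yes")
}
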