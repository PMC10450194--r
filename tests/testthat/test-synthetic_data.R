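scheme <- default_scheme()

test_that("species simulation is deterministic and spans the OGT range", {
  cfg <- sim_config(n_species = 10, seed = 1)
  a <- simulate_species(cfg)
  b <- simulate_species(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_species = 200, ogt_range = c(5, 85), seed = 2)
  sp <- simulate_species(cfg2)
  expect_true(all(sp$ogt_celsius > 5 & sp$ogt_celsius < 85))
  big <- simulate_species(sim_config(n_species = 1000, seed = 3))
  expect_lt(abs(mean(big$ogt_celsius) - 45.5), 2)
  expect_error(sim_config(n_species = 5, ogt_range = c(50, 10)), "ogt_range")
})

test_that("emitted C+ sequences always match and C- sequences never do", {
  cfg <- sim_config(n_species = 60, seed = 21)
  ann <- simulate_species(cfg)
  sim <- simulate_protein_sequences(ann, scheme, cfg)
  for (i in seq_len(nrow(sim$records))) {
    rec <- sim$records[i, ]
    hit <- matches_any_pattern(rec$residues, scheme, rec$molecule)
    expect_equal(hit, rec$source_tag == "cplus",
                 label = rec$record_id)
  }
})

test_that("occupancy limits behave: infinite steepness and sure paralogs", {
  cfg <- sim_config(n_species = 20, seed = 22,
                    occupancy_steepness = Inf, paralog_prob = 0)
  ann <- simulate_species(cfg)
  sim <- simulate_protein_sequences(ann, scheme, cfg)
  mid <- cfg$occupancy_midpoint
  ogt <- ann$ogt_celsius[match(sim$truth$species_id, ann$species_id)]
  expect_true(all(
    sim$truth$call_truth == ifelse(ogt > mid[sim$truth$protein],
                                   "only_cplus", "only_cminus")))
  cfgp <- sim_config(n_species = 5, seed = 23, paralog_prob = 1)
  annp <- simulate_species(cfgp)
  simp <- simulate_protein_sequences(annp, scheme, cfgp)
  expect_true(all(simp$truth$call_truth == "both"))
})

test_that("simulated rRNA follows the configured composition trends", {
  cfg <- sim_config(n_species = 120, seed = 24, gc_noise_sd = 0,
                    u_noise_sd = 0)
  ann <- simulate_species(cfg)
  rr <- simulate_rrna(ann, cfg)
  expect_equal(nrow(rr$aligned$rows), 121)  # species + reference
  expect_false(any(grepl("-", rr$aligned$rows$aligned, fixed = TRUE)))
  gc_obs <- vapply(rr$aligned$rows$aligned[-1], gc_content, numeric(1),
                   USE.NAMES = FALSE)
  # binomial error at length 1500 is ~0.013; allow 4 sd
  expect_true(all(abs(gc_obs - rr$truth$gc_target) < 4 * 0.013))
  hot <- ann$ogt_celsius > 60
  cold <- ann$ogt_celsius < 30
  expect_gt(mean(gc_obs[hot]), mean(gc_obs[cold]))
  u_obs <- vapply(rr$aligned$rows$aligned[-1], u_content, numeric(1),
                  USE.NAMES = FALSE)
  expect_lt(mean(u_obs[hot]), mean(u_obs[cold]))
})

test_that("flat-GC configuration stays within binomial error of the intercept", {
  cfg <- sim_config(n_species = 40, seed = 25, gc_slope = 0,
                    gc_noise_sd = 0)
  ann <- simulate_species(cfg)
  rr <- simulate_rrna(ann, cfg)
  gc_obs <- vapply(rr$aligned$rows$aligned[-1], gc_content, numeric(1),
                   USE.NAMES = FALSE)
  expect_true(all(abs(gc_obs - 0.5) < 4 * sqrt(0.25 / 1500)))
})

test_that("infeasible GC/U combinations error", {
  cfg <- sim_config(n_species = 5, seed = 26, gc_intercept = 0.9,
                    u_intercept = 0.5, gc_noise_sd = 0, u_noise_sd = 0)
  ann <- simulate_species(cfg)
  expect_error(simulate_rrna(ann, cfg), "infeasible")
})

test_that("gap-free rRNA mask equals the raw helix intervals", {
  cfg <- sim_config(n_species = 10, seed = 27)
  rr <- simulate_rrna(simulate_species(cfg), cfg)
  mask <- helical_column_mask(rr$aligned, rr$helices)
  raw <- unlist(mapply(seq, rr$helices$intervals$start,
                       rr$helices$intervals$end, SIMPLIFY = FALSE))
  expect_equal(mask, sort(raw))
})

test_that("proteome generator hits its target YVIWREL fraction and slope", {
  cfg <- sim_config(n_species = 1, seed = 28, yviwrel_slope = 0,
                    yviwrel_intercept = 0.4, yviwrel_noise_sd = 0,
                    proteome_n_records = 10, proteome_record_length = 1000)
  ann <- simulate_species(cfg)
  pr <- simulate_proteome_content(ann, cfg)
  got <- yviwrel_content(pr$records$residues)
  expect_lt(abs(got - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))
  # intercept 1 limit: the mean is clipped to 0.95, the generator ceiling
  cfg1 <- sim_config(n_species = 2, seed = 29, yviwrel_intercept = 1,
                     yviwrel_slope = 0, yviwrel_noise_sd = 0,
                     proteome_n_records = 10, proteome_record_length = 1000)
  p1 <- simulate_proteome_content(simulate_species(cfg1), cfg1)
  got1 <- yviwrel_content(p1$records$residues)
  expect_lt(abs(got1 - 0.95), 4 * sqrt(0.95 * 0.05 / 20000))
})

test_that("fit on generated proteomes recovers the configured slope within 20%", {
  cfg <- sim_config(n_species = 500, seed = 30)
  ann <- simulate_species(cfg)
  pr <- simulate_proteome_content(ann, cfg)
  tab <- content_proxy_table(pr$records, "yviwrel")
  ogt <- ann$ogt_celsius[match(tab$species_id, ann$species_id)]
  fit <- fit_linear_proxy(ogt, tab$value)
  expect_lt(abs(fit$slope - cfg$yviwrel_slope) / cfg$yviwrel_slope, 0.2)
})

test_that("whole datasets are deterministic under one seed", {
  cfg <- sim_config(n_species = 25, seed = 31)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("planted outliers are rebuilt as specified and recovered downstream", {
  spec <- data.frame(species_index = c(3, 7), forced_cplus_count = c(8, 8))
  cfg <- sim_config(n_species = 80, seed = 32, ogt_range = c(1, 20),
                    outlier_spec = spec)
  d <- simulate_dataset(cfg)
  sp <- d$annotations$species_id[spec$species_index]
  calls <- classify_isoforms(
    d$proteins$records[d$proteins$records$species_id %in% sp, ], scheme)
  for (s in sp) {
    n <- suppressWarnings(species_cplus_count(calls[calls$species_id == s, ],
                                              scheme))
    expect_equal(as.integer(n), 8)
  }
  # end to end: the cold planted species surface as C+ outliers
  all_calls <- classify_isoforms(d$proteins$records, scheme)
  flagged <- flag_cplus_outliers(cplus_count_table(all_calls),
                                 d$annotations, delta = 3)
  expect_true(all(sp %in% flagged$species_id))
  expect_equal(d$planted_outliers$species_id, sp)
  # empty spec: identity
  cfg0 <- sim_config(n_species = 10, seed = 33)
  d0 <- simulate_dataset(cfg0)
  expect_identical(plant_outliers(d0, data.frame()), d0)
})
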