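test_that("decade bins are upper-inclusive and cover (0, 90]", {
  expect_equal(assign_bin(45), 5L)
  expect_equal(bin_label(assign_bin(45)), "41-50")
  expect_equal(bin_label(assign_bin(40)), "31-40")  # upper edge belongs below
  expect_equal(assign_bin(90), 9L)
  expect_equal(assign_bin(0.5), 1L)
  expect_error(assign_bin(0, "spX"), "spX")
  expect_error(assign_bin(91), "outside")
  expect_equal(bin_label(c(1, 9)), c("1-10", "81-90"))
})

test_that("isoform frequency curves give per-bin fractions summing to one", {
  calls <- data.frame(species_id = paste0("s", 1:5),
                      protein = "bL32",
                      call = c("only_cplus", "only_cplus", "only_cminus",
                               "both", "only_cplus"),
                      n_sequences = 1)
  ann <- mk_species(paste0("s", 1:5), c(5, 7, 8, 9, 55))
  cur <- isoform_frequency_curves(calls, ann)
  b1 <- cur[cur$bin == 1, ]
  expect_equal(b1$n_species, 4)
  expect_equal(b1$frac_only_cplus, 0.5)
  expect_equal(b1$frac_only_cminus, 0.25)
  expect_equal(b1$frac_both, 0.25)
  expect_equal(cur[cur$bin == 6, ]$frac_only_cplus, 1)
  sums <- cur$frac_only_cminus + cur$frac_only_cplus + cur$frac_both
  expect_equal(sums, rep(1, nrow(cur)))
  expect_equal(nrow(isoform_frequency_curves(calls[0, ], ann)), 0)
})

test_that("bL33 abundance shares exclude 'none' and sum to one per bin", {
  v <- data.frame(species_id = paste0("s", 1:6),
                  variant = c("CCCC", "CCCC", "CCCC", "CCCD", "none", "CCCE"))
  ann <- mk_species(paste0("s", 1:6), c(33, 34, 35, 36, 37, 55))
  ab <- bl33_variant_abundance(v, ann)
  b4 <- ab[ab$bin == 4, ]
  expect_equal(b4$n_species, 4)  # the 'none' species drops out
  expect_equal(b4$frac_cccc, 0.75)
  expect_equal(b4$frac_cccd, 0.25)
  expect_equal(ab[ab$bin == 6, ]$frac_ccce, 1)
  all_none <- bl33_variant_abundance(
    data.frame(species_id = "s1", variant = "none"), ann)
  expect_equal(nrow(all_none), 0)
})

test_that("OLS fit recovers exact lines and degenerate inputs", {
  x <- 1:10
  fit <- suppressWarnings(fit_linear_proxy(x, 0.1 * x + 45))
  expect_equal(fit$slope, 0.1)
  expect_equal(fit$intercept, 45)
  expect_equal(fit$pearson_r, 1)
  w <- capture_warnings(flat <- fit_linear_proxy(x, rep(2, 10)))
  expect_match(w, "zero variance", all = FALSE)
  expect_equal(flat$slope, 0)
  expect_equal(flat$pearson_r, 0)
  expect_error(fit_linear_proxy(rep(1, 5), 1:5), "zero variance in OGT")
  expect_error(fit_linear_proxy(1:2, 1:2), "at least 3")
})

test_that("Pearson r matches the covariance-formula oracle to 1e-12", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(30); y <- 0.3 * x + rnorm(30)
    fit <- fit_linear_proxy(x, y)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(fit$pearson_r, r_oracle, tolerance = 1e-12)
  }
})

test_that("prediction bands strictly contain confidence bands", {
  set.seed(12)
  x <- runif(40, 0, 90)
  fit <- fit_linear_proxy(x, 0.01 * x + rnorm(40, 0, 0.5))
  xx <- c(0, 25, 50, 90)
  ci <- fit$ci95(xx); pi <- fit$pi95(xx)
  expect_true(all(pi[, "lwr"] < ci[, "lwr"]))
  expect_true(all(pi[, "upr"] > ci[, "upr"]))
})

test_that("simulated fits recover the slope and PI coverage is nominal", {
  set.seed(13)
  x <- runif(500, 0, 90)
  y <- 0.1 * x + 45 + rnorm(500, 0, 2)
  fit <- fit_linear_proxy(x, y)
  expect_lt(abs(fit$slope - 0.1), 0.01)
  # empirical coverage of the 95% PI on fresh draws from the generator
  covered <- 0
  for (i in 1:1000) {
    xs <- runif(50, 0, 90)
    ys <- 0.1 * xs + 45 + rnorm(50, 0, 2)
    f <- fit_linear_proxy(xs, ys)
    x_new <- runif(1, 0, 90)
    y_new <- 0.1 * x_new + 45 + rnorm(1, 0, 2)
    b <- f$pi95(x_new)
    covered <- covered + (b[, "lwr"] <= y_new && y_new <= b[, "upr"])
  }
  expect_gte(covered / 1000, 0.93)
  expect_lte(covered / 1000, 0.97)
})

test_that("OGT estimation inverts the fit and bounds it by the PI band", {
  x <- seq(1, 90, length.out = 30)
  set.seed(14)
  fit <- fit_linear_proxy(x, 0.1 * x + 45 + rnorm(30, 0, 1))
  est <- estimate_ogt(fit, 50)
  expect_equal(est$estimate, (50 - fit$intercept) / fit$slope)
  expect_lt(est$lower, est$estimate)
  expect_gt(est$upper, est$estimate)
  # the PI indeed covers the value across the interval interior
  mid <- (est$lower + est$upper) / 2
  b <- fit$pi95(mid)
  expect_true(b[, "lwr"] <= 50 && 50 <= b[, "upr"])
  # noiseless fit collapses the interval to the point
  exact <- suppressWarnings(fit_linear_proxy(x, 0.1 * x + 45))
  e2 <- estimate_ogt(exact, 50)
  expect_equal(e2$lower, e2$estimate)
  expect_equal(e2$upper, e2$estimate)
  expect_error(estimate_ogt(suppressWarnings(
    fit_linear_proxy(x, rep(1, 30))), 1), "uninformative")
})

test_that("species intersection restricts all tables identically", {
  t1 <- data.frame(species_id = c("A", "B", "C"), value = 1:3)
  t2 <- data.frame(species_id = c("B", "C", "D"), value = 4:6)
  out <- intersect_species(list(t1, t2))
  expect_equal(out[[1]]$species_id, c("B", "C"))
  expect_equal(out[[2]]$species_id, c("B", "C"))
  expect_equal(out[[2]]$value, c(4, 5))
  same <- intersect_species(list(t1, t1))
  expect_equal(same[[1]], t1)
  four <- intersect_species(list(t1, t2,
                                 data.frame(species_id = c("X", "C", "B")),
                                 data.frame(species_id = c("B", "C"))))
  expect_true(all(vapply(four, nrow, integer(1)) == 2))
  expect_error(intersect_species(list(t1,
    data.frame(species_id = "Z"))), "no species shared")
})

test_that("C+ outlier flagging uses the bin mean including the candidate", {
  counts <- data.frame(species_id = paste0("s", 1:5),
                       cplus_count = c(8, 1, 1, 1, 1))
  ann <- mk_species(paste0("s", 1:5), rep(15, 5))
  out <- flag_cplus_outliers(counts, ann, delta = 3)
  expect_equal(out$species_id, "s1")
  expect_equal(out$group_mean, 2.4)
  expect_equal(out$deviation, 5.6)
  # below delta: not flagged
  near <- flag_cplus_outliers(data.frame(species_id = paste0("s", 1:5),
                                         cplus_count = c(3, 2, 2, 2, 1)),
                              ann, delta = 3)
  expect_equal(nrow(near), 0)
  # a lone species is its own mean and never flagged
  lone <- flag_cplus_outliers(data.frame(species_id = "solo",
                                         cplus_count = 9),
                              mk_species("solo", 85), delta = 3)
  expect_equal(nrow(lone), 0)
})

test_that("C+ outlier flagging is invariant to species order", {
  set.seed(15)
  counts <- data.frame(species_id = sprintf("s%02d", 1:40),
                       cplus_count = sample(0:9, 40, replace = TRUE))
  ann <- mk_species(counts$species_id, runif(40, 1, 90))
  a <- flag_cplus_outliers(counts, ann)
  perm <- sample(40)
  b <- flag_cplus_outliers(counts[perm, ], ann)
  expect_equal(a, b)
})

test_that("extremes at a target temperature rank by absolute deviation", {
  tab <- data.frame(species_id = sprintf("s%02d", 1:12),
                    value = c(rep(0.5, 10), 0.40, 0.62),
                    proxy_name = "gc_full")
  ann <- mk_species(tab$species_id, rep(37, 12))
  top <- flag_extreme_at_temperature(tab, ann, t = 37, top_n = 2)
  expect_setequal(top$species_id, c("s11", "s12"))
  expect_equal(top$species_id[1], "s12")  # |0.62-mean| > |0.40-mean|
  expect_equal(top$sign, c("above", "below"))
  # all-equal values: stable ordering by species id
  flat <- data.frame(species_id = c("b", "a", "c"), value = 1)
  all3 <- suppressWarnings(flag_extreme_at_temperature(
    flat, mk_species(c("b", "a", "c"), 37), top_n = 10))
  expect_equal(all3$species_id, c("a", "b", "c"))
  expect_warning(flag_extreme_at_temperature(
    flat, mk_species(c("b", "a", "c"), 37), top_n = 10), "returning all")
  # tolerance matches 37.4 but not 38
  ann2 <- mk_species(paste0("t", 1:3), c(37.4, 38, 37))
  tab2 <- data.frame(species_id = paste0("t", 1:3), value = 1:3)
  got <- suppressWarnings(flag_extreme_at_temperature(tab2, ann2, top_n = 5))
  expect_setequal(got$species_id, c("t1", "t3"))
})

test_that("group means aggregate per phylum and per bin", {
  counts <- data.frame(species_id = paste0("s", 1:3),
                       cplus_count = c(8, 9, 4))
  ann <- data.frame(species_id = paste0("s", 1:3),
                    phylum = c("P1", "P1", "P2"),
                    ogt_celsius = c(75, 85, 20))
  by_ph <- group_mean_cplus(counts, ann, by = "phylum")
  expect_equal(by_ph$mean_cplus_count[by_ph$group == "P1"], 8.5)
  expect_equal(by_ph$mean_cplus_count[by_ph$group == "P2"], 4)
  expect_equal(nrow(by_ph), 2)
  by_bin <- group_mean_cplus(counts, ann, by = "bin")
  expect_setequal(by_bin$group, c("71-80", "81-90", "11-20"))
})
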