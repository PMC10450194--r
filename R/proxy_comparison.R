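## Relating proxies to optimal growth temperature: decade bins, per-bin
## isoform frequency curves, bL33 variant abundance, OLS fits with 95%
## confidence/prediction bands, species-overlap reduction and the two
## outlier analyses (bin-wise C+ count deviation; extremes among species
## adapted to one temperature).

#' Assign optimal growth temperatures to decade bins
#'
#' Nine upper-inclusive bins partition (0, 90] degrees Celsius: bin i
#' covers (10(i-1), 10i], labelled "1-10" ... "81-90" (so 40 falls in
#' "31-40" and 90 in "81-90").
#'
#' @param ogt_celsius Numeric vector of OGTs.
#' @param species_id Optional ids used in error messages.
#' @return Integer bin indices (1..9).
#' @export
assign_bin <- function(ogt_celsius, species_id = NULL) {
  bad <- is.na(ogt_celsius) | ogt_celsius <= 0 | ogt_celsius > 90
  if (any(bad)) {
    who <- if (!is.null(species_id)) paste(species_id[bad], collapse = ", ")
           else paste(ogt_celsius[bad], collapse = ", ")
    stop("OGT outside (0, 90]: ", who)
  }
  as.integer(ceiling(ogt_celsius / 10))
}

#' Bin labels "1-10" ... "81-90"
#' @param index Bin indices from [assign_bin()].
#' @return Character labels.
#' @export
bin_label <- function(index) {
  if (length(index) == 0) return(character(0))
  paste0(10 * (index - 1) + 1, "-", 10 * index)
}

#' Per-bin isoform frequency curves for one protein
#'
#' Fractions of only-C-, only-C+ and both species per decade temperature
#' bin, among species with data; empty bins are omitted.  The three
#' fractions sum to 1 in every returned bin.
#'
#' @param calls Isoform-call data.frame of a single protein.
#' @param annotations Per-species annotations with `ogt_celsius`.
#' @return data.frame `bin`, `bin_label`, `protein`, `n_species`,
#'   `frac_only_cminus`, `frac_only_cplus`, `frac_both`.
#' @export
isoform_frequency_curves <- function(calls, annotations) {
  if (length(unique(calls$protein)) > 1) {
    stop("isoform_frequency_curves expects calls of a single protein")
  }
  if (nrow(calls) == 0) {
    return(data.frame(bin = integer(0), bin_label = character(0),
                      protein = character(0), n_species = integer(0),
                      frac_only_cminus = numeric(0),
                      frac_only_cplus = numeric(0), frac_both = numeric(0)))
  }
  ogt <- annotations$ogt_celsius[match(calls$species_id,
                                       annotations$species_id)]
  bins <- assign_bin(ogt, calls$species_id)
  out <- lapply(sort(unique(bins)), function(b) {
    cc <- calls$call[bins == b]
    data.frame(bin = b, bin_label = bin_label(b),
               protein = calls$protein[1], n_species = length(cc),
               frac_only_cminus = mean(cc == "only_cminus"),
               frac_only_cplus = mean(cc == "only_cplus"),
               frac_both = mean(cc == "both"))
  })
  do.call(rbind, out)
}

#' Per-bin relative abundance of bL33 variants
#'
#' Shares of the CCCC, CCCD and CCCE forms among variant-bearing species
#' in each bin; species typed `none` are excluded from the denominator and
#' bins with no variant-bearing species are omitted.
#'
#' @param variants data.frame `species_id`, `variant` from
#'   [classify_bl33_variant()].
#' @param annotations Per-species annotations.
#' @return data.frame `bin`, `bin_label`, `n_species`, `frac_cccc`,
#'   `frac_cccd`, `frac_ccce` (shares sum to 1 per bin).
#' @export
bl33_variant_abundance <- function(variants, annotations) {
  variants <- variants[variants$variant != "none", , drop = FALSE]
  if (nrow(variants) == 0) {
    return(data.frame(bin = integer(0), bin_label = character(0),
                      n_species = integer(0), frac_cccc = numeric(0),
                      frac_cccd = numeric(0), frac_ccce = numeric(0)))
  }
  ogt <- annotations$ogt_celsius[match(variants$species_id,
                                       annotations$species_id)]
  bins <- assign_bin(ogt, variants$species_id)
  out <- lapply(sort(unique(bins)), function(b) {
    v <- variants$variant[bins == b]
    data.frame(bin = b, bin_label = bin_label(b), n_species = length(v),
               frac_cccc = mean(v == "CCCC"), frac_cccd = mean(v == "CCCD"),
               frac_ccce = mean(v == "CCCE"))
  })
  do.call(rbind, out)
}

#' Ordinary least squares fit of a proxy on OGT
#'
#' Fits proxy ~ OGT, with Pearson's r of the pairs and t-based 95%
#' confidence (mean response) and prediction (new observation) bands.
#' When the proxy has zero variance the slope is 0 and r is defined as 0
#' with a warning.
#'
#' @param ogt Numeric vector of optimal growth temperatures (x).
#' @param value Numeric vector of proxy values (y), same length, n >= 3.
#' @return Object of class `proxy_fit`: list with `slope`, `intercept`,
#'   `pearson_r`, `n`, `residual_sd`, `model` (the underlying `lm`), and
#'   band functions `ci95(x)` / `pi95(x)` returning a two-column matrix
#'   (`lwr`, `upr`).
#' @export
fit_linear_proxy <- function(ogt, value) {
  if (length(ogt) != length(value)) stop("ogt and value lengths differ")
  if (length(ogt) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(ogt)) || !all(is.finite(value))) {
    stop("non-finite values in input pairs")
  }
  if (stats::var(ogt) == 0) stop("zero variance in OGT; fit undefined")
  df <- data.frame(ogt = ogt, value = value)
  model <- stats::lm(value ~ ogt, data = df)
  if (stats::var(value) == 0) {
    warning("proxy has zero variance; Pearson r defined as 0")
    r <- 0
  } else {
    r <- stats::cor(ogt, value)
  }
  band <- function(interval) {
    force(interval)
    function(x) {
      p <- stats::predict(model, newdata = data.frame(ogt = x),
                          interval = interval, level = 0.95)
      p[, c("lwr", "upr"), drop = FALSE]
    }
  }
  structure(list(
    slope = unname(stats::coef(model)[2]),
    intercept = unname(stats::coef(model)[1]),
    pearson_r = r,
    n = length(ogt),
    residual_sd = summary(model)$sigma,
    model = model,
    ci95 = band("confidence"),
    pi95 = band("prediction")
  ), class = "proxy_fit")
}

#' @export
print.proxy_fit <- function(x, digits = 4, ...) {
  cat(sprintf("proxy_fit: value = %.*g + %.*g * OGT  (n = %d)\n",
              digits, x$intercept, digits, x$slope, x$n))
  cat(sprintf("  Pearson r = %.*g, residual sd = %.*g\n",
              digits, x$pearson_r, digits, x$residual_sd))
  invisible(x)
}

#' Invert a proxy fit to estimate OGT from a proxy value
#'
#' Point estimate by inverting the trend line; the interval is the OGT
#' range over which the fit's 95% prediction band covers the observed
#' value (open-ended sides are reported as -Inf/Inf).  With a noiseless
#' fit the interval collapses to the point estimate.
#'
#' @param fit A [fit_linear_proxy()] object with non-zero slope.
#' @param value Observed proxy value.
#' @param search_halfwidth Half-width of the numeric search window around
#'   the point estimate, in degrees Celsius (default 300).
#' @return list with `estimate`, `lower`, `upper` (degrees Celsius).
#' @export
estimate_ogt <- function(fit, value, search_halfwidth = 300) {
  if (abs(fit$slope) < 1e-12) stop("proxy uninformative: slope is ~0")
  xhat <- (value - fit$intercept) / fit$slope
  if (fit$residual_sd < 1e-12) {
    return(list(estimate = xhat, lower = xhat, upper = xhat))
  }
  grid <- seq(xhat - search_halfwidth, xhat + search_halfwidth,
              length.out = 4001)
  band <- fit$pi95(grid)
  covered <- band[, "lwr"] <= value & value <= band[, "upr"]
  if (!any(covered)) {
    return(list(estimate = xhat, lower = NA_real_, upper = NA_real_))
  }
  lo <- grid[which(covered)[1]]
  hi <- grid[rev(which(covered))[1]]
  if (which(covered)[1] == 1) lo <- -Inf
  if (rev(which(covered))[1] == length(grid)) hi <- Inf
  list(estimate = xhat, lower = lo, upper = hi)
}

#' Restrict proxy tables to their common species
#'
#' So that every correlation is computed over an identical species set,
#' each table is reduced to the intersection of `species_id`s, ordered
#' identically (sorted) across tables.
#'
#' @param proxy_tables List of >= 2 data.frames with a `species_id`
#'   column.
#' @return List of data.frames, each containing exactly the common
#'   species in the same order.
#' @export
intersect_species <- function(proxy_tables) {
  if (length(proxy_tables) < 2) stop("need at least two proxy tables")
  common <- Reduce(intersect, lapply(proxy_tables, function(t) t$species_id))
  if (length(common) == 0) stop("no species shared by all proxy tables")
  common <- sort(common)
  lapply(proxy_tables, function(t) {
    out <- t[match(common, t$species_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Flag species with anomalous C+ protein counts
#'
#' A species is an outlier when its C+ count deviates from the mean count
#' of its decade temperature bin by at least `delta` proteins.  By default
#' the bin mean includes the candidate itself; `leave_one_out = TRUE`
#' excludes it.
#'
#' @param counts data.frame `species_id`, `cplus_count` (values in 0..9).
#' @param annotations Per-species annotations.
#' @param delta Minimum absolute deviation (default 3).
#' @param leave_one_out Exclude the candidate from its bin mean.
#' @return data.frame `species_id`, `criterion` ("cplus_delta"),
#'   `proxy_name`, `observed`, `group_mean`, `deviation`, `bin_label`.
#' @export
flag_cplus_outliers <- function(counts, annotations, delta = 3,
                                leave_one_out = FALSE) {
  stopifnot(all(counts$cplus_count >= 0 & counts$cplus_count <= 9))
  ogt <- annotations$ogt_celsius[match(counts$species_id,
                                       annotations$species_id)]
  bins <- assign_bin(ogt, counts$species_id)
  o <- order(counts$species_id, method = "radix")
  counts <- counts[o, , drop = FALSE]
  bins <- bins[o]
  bin_sum <- tapply(counts$cplus_count, bins, sum)
  bin_n <- tapply(counts$cplus_count, bins, length)
  key <- as.character(bins)
  if (leave_one_out) {
    gm <- ifelse(bin_n[key] > 1,
                 (bin_sum[key] - counts$cplus_count) / (bin_n[key] - 1),
                 NA_real_)
  } else {
    gm <- bin_sum[key] / bin_n[key]
  }
  dev <- counts$cplus_count - gm
  flag <- !is.na(dev) & abs(dev) >= delta
  out <- data.frame(species_id = counts$species_id[flag],
                    criterion = rep("cplus_delta", sum(flag)),
                    proxy_name = rep("cplus_count", sum(flag)),
                    observed = counts$cplus_count[flag],
                    group_mean = unname(gm[flag]),
                    deviation = unname(dev[flag]),
                    bin_label = bin_label(bins[flag]))
  rownames(out) <- NULL
  out
}

#' Most extreme proxy values among species adapted to one temperature
#'
#' Selects the `top_n` species whose proxy value deviates most (in
#' absolute terms) from the mean value of species adapted to temperature
#' `t` (matched with tolerance `tol`, since OGT tables mix e.g. 37 and
#' 37.0).  Ties are broken by `species_id` for determinism.
#'
#' @param proxy_table data.frame `species_id`, `value` and optionally
#'   `proxy_name`.
#' @param annotations Per-species annotations.
#' @param t Target temperature in degrees Celsius (default 37).
#' @param tol Matching tolerance (default 0.5).
#' @param top_n Number of species to report (default 10); if fewer
#'   species match, all are returned with a warning.
#' @return data.frame `species_id`, `criterion`
#'   ("extreme_at_temperature"), `proxy_name`, `observed`, `group_mean`,
#'   `deviation`, `sign` ("above"/"below").
#' @export
flag_extreme_at_temperature <- function(proxy_table, annotations, t = 37,
                                        tol = 0.5, top_n = 10) {
  ogt <- annotations$ogt_celsius[match(proxy_table$species_id,
                                       annotations$species_id)]
  grp <- proxy_table[!is.na(ogt) & abs(ogt - t) <= tol, , drop = FALSE]
  if (nrow(grp) == 0) stop("no species adapted to ", t, " degrees C")
  if (nrow(grp) < top_n) {
    warning("only ", nrow(grp), " species at ", t,
            " degrees C; returning all")
    top_n <- nrow(grp)
  }
  gm <- mean(grp$value)
  dev <- grp$value - gm
  o <- order(-abs(dev), grp$species_id, method = "radix")
  pick <- o[seq_len(top_n)]
  out <- data.frame(
    species_id = grp$species_id[pick],
    criterion = "extreme_at_temperature",
    proxy_name = if ("proxy_name" %in% names(grp)) grp$proxy_name[pick]
                 else NA_character_,
    observed = grp$value[pick],
    group_mean = gm,
    deviation = dev[pick],
    sign = ifelse(dev[pick] >= 0, "above", "below"))
  rownames(out) <- NULL
  out
}

#' Mean C+ count per phylum or per temperature bin
#'
#' @param counts data.frame `species_id`, `cplus_count`.
#' @param annotations Per-species annotations (with `phylum` and
#'   `ogt_celsius`).
#' @param by Grouping key: `"phylum"` or `"bin"`.
#' @return data.frame `group`, `mean_cplus_count`, `n_species`.
#' @export
group_mean_cplus <- function(counts, annotations, by = c("phylum", "bin")) {
  by <- match.arg(by)
  idx <- match(counts$species_id, annotations$species_id)
  if (anyNA(idx)) {
    stop("unannotated species: ",
         paste(counts$species_id[is.na(idx)], collapse = ", "))
  }
  key <- if (by == "phylum") annotations$phylum[idx]
         else bin_label(assign_bin(annotations$ogt_celsius[idx],
                                   counts$species_id))
  agg <- stats::aggregate(counts$cplus_count, by = list(group = key),
                          FUN = function(x) c(mean(x), length(x)))
  data.frame(group = agg$group, mean_cplus_count = agg$x[, 1],
             n_species = as.integer(agg$x[, 2]))
}
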