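#' Annual trade and redundancy series
#'
#' One row per calendar year present in the validated table, carrying the
#' filtering funnel and the redundancy total:
#'
#' * `gross_tonnes`: every validated tonne, including aquaculture, unknown
#'   method and re-exports.
#' * `total_tonnes`: the wild-capture trade scope (capture production, not
#'   re-exported, any taxonomic resolution) - the "Total" series of the
#'   funnel.
#' * `species_level_tonnes`: the subset of `total_tonnes` resolved to
#'   species level - the "Species" series, the denominator-eligible scope
#'   for redundancy.
#' * `redundant_tonnes`: twice the matched minimum summed over all pair x
#'   species cells that year.
#' * `redundant_share_of_total` and `redundant_share_of_species`: the two
#'   candidate shares (the appropriate denominator is analysis-dependent,
#'   so both are reported).
#'
#' The invariant `redundant <= species_level <= total <= gross` holds per
#' row.
#'
#' @param x validated trade records (a `trade_table` or records
#'   `data.table`), pre-filtering.
#' @param flows redundant flows from [compute_redundant_flows()]; when
#'   `NULL` they are computed from `x` via [apply_filters()].
#' @return `data.table` with one row per year.
#' @export
annual_series <- function(x, flows = NULL) {
  rec <- check_record_columns(records_of(x))
  if (is.null(flows)) flows <- compute_redundant_flows(apply_filters(rec))
  scope <- rec$production_method == "capture" & !rec$is_reexport
  per_year <- rec[, .(
    gross_tonnes = sum(tonnes),
    total_tonnes = sum(tonnes[scope[.I]]),
    species_level_tonnes = sum(tonnes[scope[.I] & taxon_rank == "species"])
  ), by = year]
  red <- flows[, .(redundant_tonnes = sum(redundant_tonnes)), by = year]
  out <- merge(per_year, red, by = "year", all.x = TRUE)
  out[is.na(redundant_tonnes), redundant_tonnes := 0]
  out[, redundant_share_of_total :=
        data.table::fifelse(total_tonnes > 0,
                            redundant_tonnes / total_tonnes, NA_real_)]
  out[, redundant_share_of_species :=
        data.table::fifelse(species_level_tonnes > 0,
                            redundant_tonnes / species_level_tonnes,
                            NA_real_)]
  out[order(year)][]
}

#' Signed percent change of a series between two years
#'
#' `100 * (v_to - v_from) / v_from` for one column of an annual series.
#'
#' @param series a `data.table` with a `year` column (e.g. from
#'   [annual_series()]), or a numeric vector named by year.
#' @param year_from,year_to the two years; both must be present.
#' @param field which column to compare when `series` is a table
#'   (default `"redundant_tonnes"`).
#' @return the signed percent change; errors if a year is absent, `NA_real_`
#'   with a warning if the baseline value is zero.
#' @export
percent_change <- function(series, year_from, year_to,
                           field = "redundant_tonnes") {
  if (is.data.frame(series)) {
    series <- data.table::as.data.table(series)
    if (!field %in% names(series)) {
      stop("field not found in series: ", field, call. = FALSE)
    }
    v <- setNames(series[[field]], series$year)
  } else {
    v <- series
  }
  pick <- function(yr) {
    i <- match(as.character(yr), names(v))
    if (is.na(i)) stop("year not present in series: ", yr, call. = FALSE)
    v[[i]]
  }
  v_from <- pick(year_from)
  v_to <- pick(year_to)
  if (!isTRUE(v_from != 0)) {
    warning("baseline value is zero; percent change undefined")
    return(NA_real_)
  }
  100 * (v_to - v_from) / v_from
}

#' Attribute redundant trade to countries
#'
#' Each redundant flow credits its matched minimum to *both* partners (their
#' redundant exports), so country totals sum exactly to the global redundant
#' tonnage: every `2 * min` splits as `min` to each side. Per country:
#'
#' * `redundant_export_tonnes`: sum of matched minima over all flows the
#'   country participates in.
#' * `total_export_tonnes`: the country's wild-capture non-re-export exports
#'   (pre species filter) - the default proportion denominator.
#' * `species_level_export_tonnes` and `species_level_fraction`: the
#'   species-resolved subset and its share of total exports.
#' * `redundancy_proportion`: redundant over the denominator selected by
#'   `proportion_basis`: `"exports"` (default) or `"trade"`
#'   (exports + imports).
#' * `n_redundant_species`: distinct species with a positive matched
#'   minimum for that country.
#'
#' @param flows output of [compute_redundant_flows()].
#' @param x the validated records the flows were derived from.
#' @param proportion_basis denominator for `redundancy_proportion`.
#' @return `data.table`, one row per country appearing in the wild-capture
#'   scope, sorted by decreasing redundant exports (ties broken by country
#'   code).
#' @export
country_attribution <- function(flows, x,
                                proportion_basis = c("exports", "trade")) {
  proportion_basis <- match.arg(proportion_basis)
  rec <- check_record_columns(records_of(x))
  scope <- rec[production_method == "capture" & is_reexport == FALSE]

  exp_tot <- scope[, .(total_export_tonnes = sum(tonnes)),
                   by = .(country = exporter)]
  exp_sp <- scope[taxon_rank == "species",
                  .(species_level_export_tonnes = sum(tonnes)),
                  by = .(country = exporter)]
  imp_tot <- scope[, .(total_import_tonnes = sum(tonnes)),
                   by = .(country = importer)]

  red <- rbind(
    flows[, .(country = country_a, species, matched_min)],
    flows[, .(country = country_b, species, matched_min)]
  )
  ## grouped sum kept as a single GForce expression so the accumulation
  ## order matches any other grouped sum over the same rows bit for bit
  red_by_country <- red[, .(redundant_export_tonnes = sum(matched_min)),
                        by = country]
  n_sp <- red[matched_min > 0,
              .(n_redundant_species = data.table::uniqueN(species)),
              by = country]
  red_by_country <- merge(red_by_country, n_sp, by = "country", all.x = TRUE)
  red_by_country[is.na(n_redundant_species), n_redundant_species := 0L]

  out <- Reduce(function(a, b) merge(a, b, by = "country", all = TRUE),
                list(exp_tot, exp_sp, imp_tot, red_by_country))
  num_cols <- setdiff(names(out), "country")
  for (col in num_cols) out[is.na(get(col)), (col) := 0]
  stray <- out[redundant_export_tonnes > 0 & total_export_tonnes == 0]
  if (nrow(stray)) {
    stop("internal error: country present in flows but absent from records: ",
         paste(stray$country, collapse = ", "))
  }
  out[, species_level_fraction :=
        data.table::fifelse(total_export_tonnes > 0,
                            species_level_export_tonnes / total_export_tonnes,
                            NA_real_)]
  out[, denominator_tonnes := if (proportion_basis == "exports") {
    total_export_tonnes
  } else {
    total_export_tonnes + total_import_tonnes
  }]
  out[, redundancy_proportion :=
        data.table::fifelse(denominator_tonnes > 0,
                            redundant_export_tonnes / denominator_tonnes,
                            NA_real_)]
  out[, denominator_tonnes := NULL]
  out[, n_redundant_species := as.integer(n_redundant_species)]
  out[order(-redundant_export_tonnes, country)][]
}

#' Rank trade partners by redundant volume and measure region overlap
#'
#' Sums redundant tonnage per canonical country pair across species and
#' years, computes each pair's share of the global total, joins continent
#' and subregion labels for both partners, and reports the fraction of
#' redundant trade occurring within the same continent / same subregion on
#' two bases: pair counts and tonnage.
#'
#' Pairs with a country missing from the region map get `NA` overlap flags,
#' are excluded from the overlap-fraction denominators, and trigger a
#' warning; they still carry their share of global redundancy.
#'
#' @param flows output of [compute_redundant_flows()].
#' @param region_map region lookup from [read_region_map()] (columns
#'   `country_iso3`, `continent`, `subregion`).
#' @return a list of class `pair_ranking`: `pairs` (a `data.table` sorted by
#'   decreasing redundant tonnage, ties broken by pair key) and `fractions`
#'   (named list with `same_continent_count`, `same_subregion_count`,
#'   `same_continent_tonnage`, `same_subregion_tonnage`, `n_pairs`,
#'   `n_pairs_with_regions`).
#' @export
pair_ranking <- function(flows, region_map) {
  pairs <- flows[, .(redundant_tonnes = sum(redundant_tonnes)),
                 by = .(country_a, country_b)]
  global <- sum(pairs$redundant_tonnes)
  pairs[, share_of_global :=
          if (global > 0) redundant_tonnes / global else NA_real_]

  rm <- data.table::as.data.table(region_map)
  lookup <- function(code, col) rm[[col]][match(code, rm$country_iso3)]
  pairs[, `:=`(
    continent_a = lookup(country_a, "continent"),
    continent_b = lookup(country_b, "continent"),
    subregion_a = lookup(country_a, "subregion"),
    subregion_b = lookup(country_b, "subregion")
  )]
  pairs[, same_continent := continent_a == continent_b]
  pairs[, same_subregion := subregion_a == subregion_b]
  unmapped <- pairs[is.na(same_continent),
                    unique(c(country_a[is.na(continent_a)],
                             country_b[is.na(continent_b)]))]
  if (length(unmapped)) {
    warning("countries missing from region map (pairs excluded from ",
            "overlap fractions): ", paste(sort(unmapped), collapse = ", "))
  }
  pairs[, c("continent_a", "continent_b", "subregion_a", "subregion_b") :=
          NULL]
  known <- pairs[!is.na(same_continent)]
  frac <- function(flag, weight = NULL) {
    if (nrow(known) == 0L) return(NA_real_)
    if (is.null(weight)) return(mean(known[[flag]]))
    w <- known[[weight]]
    if (sum(w) == 0) return(NA_real_)
    sum(w * known[[flag]]) / sum(w)
  }
  fractions <- list(
    same_continent_count = frac("same_continent"),
    same_subregion_count = frac("same_subregion"),
    same_continent_tonnage = frac("same_continent", "redundant_tonnes"),
    same_subregion_tonnage = frac("same_subregion", "redundant_tonnes"),
    n_pairs = nrow(pairs),
    n_pairs_with_regions = nrow(known)
  )
  structure(list(
    pairs = pairs[order(-redundant_tonnes, country_a, country_b)][],
    fractions = fractions
  ), class = "pair_ranking")
}

#' @export
print.pair_ranking <- function(x, ...) {
  cat(sprintf("Redundant trade partners: %d pairs (%d with region labels)\n",
              x$fractions$n_pairs, x$fractions$n_pairs_with_regions))
  cat(sprintf("  same continent: %.1f%% of pairs, %.1f%% of tonnage\n",
              100 * x$fractions$same_continent_count,
              100 * x$fractions$same_continent_tonnage))
  cat(sprintf("  same subregion: %.1f%% of pairs, %.1f%% of tonnage\n",
              100 * x$fractions$same_subregion_count,
              100 * x$fractions$same_subregion_tonnage))
  print(head(x$pairs, 10))
  invisible(x)
}

#' Rank species by redundant volume, with IUCN categories and top partners
#'
#' Sums redundant tonnage per species across pairs and years, attaches each
#' species' share of the global total, joins IUCN Red List categories by
#' normalized name (species absent from the lookup get `"NA"`, Not
#' Assessed), and computes, per species, the partner pairs carrying its
#' redundancy with their within-species shares.
#'
#' @param flows output of [compute_redundant_flows()].
#' @param iucn_table optional lookup from [read_iucn_table()].
#' @return a list of class `species_ranking`: `species` (sorted by
#'   decreasing redundant tonnage, ties broken by name) and `pair_shares`
#'   (species x pair redundancy with `share_within_species`, sorted within
#'   species by decreasing tonnage).
#' @export
species_ranking <- function(flows, iucn_table = NULL) {
  sp <- flows[, .(redundant_tonnes = sum(redundant_tonnes)), by = species]
  global <- sum(sp$redundant_tonnes)
  sp[, share_of_global :=
       if (global > 0) redundant_tonnes / global else NA_real_]
  if (!is.null(iucn_table)) {
    it <- data.table::as.data.table(iucn_table)
    sp[, iucn_category := it$iucn_category[match(species, it$taxon_name)]]
    sp[is.na(iucn_category), iucn_category := "NA"]
  } else {
    sp[, iucn_category := "NA"]
  }
  pair_shares <- flows[, .(redundant_tonnes = sum(redundant_tonnes)),
                       by = .(species, country_a, country_b)]
  pair_shares[, share_within_species :=
                redundant_tonnes / sum(redundant_tonnes), by = species]
  structure(list(
    species = sp[order(-redundant_tonnes, species)][],
    pair_shares = pair_shares[order(species, -redundant_tonnes,
                                    country_a, country_b)][]
  ), class = "species_ranking")
}

#' @export
print.species_ranking <- function(x, ...) {
  cat(sprintf("Redundantly traded species: %d\n", nrow(x$species)))
  print(head(x$species, 10))
  invisible(x)
}

#' Smallest top-k set covering a share threshold
#'
#' Given shares sorted in decreasing order, returns the smallest `k` such
#' that the cumulative share of the top `k` items reaches `threshold`,
#' together with that cumulative share.
#'
#' @param shares numeric vector of non-negative shares; sorted internally in
#'   decreasing order if not already.
#' @param threshold target cumulative share in (0, 1].
#' @return list with `k` and `cumulative_share`.
#' @export
topk_coverage <- function(shares, threshold) {
  assert_scalar_number(threshold, "threshold", lower = .Machine$double.eps,
                       upper = 1)
  shares <- as.numeric(shares)
  if (length(shares) == 0L) {
    stop("empty share vector; top-k coverage undefined", call. = FALSE)
  }
  if (any(!is.finite(shares)) || any(shares < 0)) {
    stop("shares must be non-negative and finite", call. = FALSE)
  }
  shares <- sort(shares, decreasing = TRUE)
  cum <- cumsum(shares)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(shares)  # shares need not sum exactly to 1
  list(k = as.integer(k), cumulative_share = cum[[k]])
}

#' Share of redundant tonnage in threatened IUCN categories
#'
#' Tonnage-weighted fraction of redundant trade carried by species listed as
#' Endangered (EN) or Vulnerable (VU), plus species counts per category.
#'
#' @param species_summary the `species` table of a [species_ranking()]
#'   result (or the `species_ranking` object itself).
#' @param categories which categories count as threatened (default
#'   `c("EN", "VU")`).
#' @return list with `fraction` (0 when there is no redundant tonnage) and
#'   `category_counts` (named integer vector over all seven categories).
#' @export
threatened_share <- function(species_summary, categories = c("EN", "VU")) {
  if (inherits(species_summary, "species_ranking")) {
    species_summary <- species_summary$species
  }
  dt <- data.table::as.data.table(species_summary)
  total <- sum(dt$redundant_tonnes)
  fraction <- if (total > 0) {
    sum(dt$redundant_tonnes[dt$iucn_category %in% categories]) / total
  } else {
    0
  }
  counts <- table(factor(dt$iucn_category, levels = iucn_categories()))
  list(fraction = fraction,
       category_counts = setNames(as.integer(counts), names(counts)))
}

#' OLS regression of redundant exports on a country-level predictor
#'
#' Ordinary least squares of `redundant_export_tonnes` on either the
#' country's total exports or its species-level reporting fraction, the two
#' standard diagnostics for what drives redundancy attribution. Plain
#' untransformed linear model; slope, intercept, R squared, the two-sided
#' slope p-value, the slope standard error and its 95% confidence interval
#' are returned.
#'
#' @param country_summary output of [country_attribution()].
#' @param x_field predictor: `"total_export_tonnes"` (default) or
#'   `"species_level_fraction"`.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `std_error`, `conf_int` (length-2 vector), `n`.
#' @export
redundancy_regression <- function(country_summary,
                                  x_field = c("total_export_tonnes",
                                              "species_level_fraction")) {
  x_field <- match.arg(x_field)
  dt <- data.table::as.data.table(country_summary)
  keep <- is.finite(dt[[x_field]]) & is.finite(dt$redundant_export_tonnes)
  dt <- dt[keep]
  if (nrow(dt) < 3L) {
    stop("need at least 3 countries with finite values for regression",
         call. = FALSE)
  }
  if (!isTRUE(var(dt[[x_field]]) > 0)) {
    stop("predictor has zero variance; regression undefined", call. = FALSE)
  }
  if (!isTRUE(var(dt$redundant_export_tonnes) > 0)) {
    ## constant response: the fit is flat by definition; summary.lm would
    ## return 0/0 noise for R^2 here
    return(list(slope = 0, intercept = mean(dt$redundant_export_tonnes),
                r_squared = 0, p_value = NA_real_, std_error = 0,
                conf_int = c(0, 0), n = nrow(dt)))
  }
  fit <- lm(dt$redundant_export_tonnes ~ dt[[x_field]])
  ## noiseless fixtures trigger summary.lm's perfect-fit warning; harmless
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  p <- sm$coefficients[2, 4]
  tcrit <- qt(0.975, df = fit$df.residual)
  list(slope = slope,
       intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = p,
       std_error = se,
       conf_int = c(slope - tcrit * se, slope + tcrit * se),
       n = nrow(dt))
}

#' Bundle headline redundancy numbers into one report
#'
#' Collects the quantities typically quoted from a redundancy analysis into
#' a single machine-readable list: global redundant tonnage and its share of
#' total and species-level trade, the percent change between the first and
#' last year, counts of participating countries, top-k coverage for pairs
#' and species, region-overlap fractions, the threatened share and both
#' regressions (regressions are `NULL` when the data are too degenerate to
#' fit).
#'
#' @param annual output of [annual_series()].
#' @param countries output of [country_attribution()].
#' @param pairs output of [pair_ranking()].
#' @param species output of [species_ranking()].
#' @param topk_threshold cumulative-share threshold for top-k coverage
#'   (default 0.9).
#' @return a named list, serializable with [jsonlite::write_json()].
#' @export
headline_report <- function(annual, countries, pairs, species,
                            topk_threshold = 0.9) {
  global_red <- sum(annual$redundant_tonnes)
  total <- sum(annual$total_tonnes)
  species_total <- sum(annual$species_level_tonnes)
  years <- range(annual$year)
  pc <- if (nrow(annual) >= 2 &&
            isTRUE(annual$redundant_tonnes[annual$year == years[1]] > 0)) {
    percent_change(annual, years[1], years[2])
  } else {
    NA_real_
  }
  top_sp <- if (nrow(species$species) > 0 && global_red > 0) {
    topk_coverage(species$species$share_of_global, topk_threshold)
  } else {
    list(k = 0L, cumulative_share = NA_real_)
  }
  top_pr <- if (nrow(pairs$pairs) > 0 && global_red > 0) {
    topk_coverage(pairs$pairs$share_of_global, topk_threshold)
  } else {
    list(k = 0L, cumulative_share = NA_real_)
  }
  reg_safe <- function(field) {
    tryCatch(redundancy_regression(countries, field),
             error = function(e) NULL)
  }
  list(
    years = list(from = years[1], to = years[2]),
    global_redundant_tonnes = global_red,
    total_tonnes = total,
    species_level_tonnes = species_total,
    redundant_share_of_total = if (total > 0) global_red / total else NA_real_,
    redundant_share_of_species = if (species_total > 0) {
      global_red / species_total
    } else {
      NA_real_
    },
    redundant_percent_change = pc,
    n_countries = nrow(countries),
    n_countries_redundant = sum(countries$redundant_export_tonnes > 0),
    n_pairs = pairs$fractions$n_pairs,
    n_species_redundant = nrow(species$species),
    topk_threshold = topk_threshold,
    species_topk = top_sp,
    pair_topk = top_pr,
    region_overlap = pairs$fractions[c("same_continent_count",
                                       "same_subregion_count",
                                       "same_continent_tonnage",
                                       "same_subregion_tonnage")],
    threatened = threatened_share(species),
    regression_total_exports = reg_safe("total_export_tonnes"),
    regression_species_fraction = reg_safe("species_level_fraction")
  )
}
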