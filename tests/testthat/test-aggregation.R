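## small hand-checkable network used across aggregation tests:
## 2000: CAN<->USA Gadus morhua (10, 5)  -> redundant 10
## 2000: DNK<->SWE Clupea harengus (4, 4) -> redundant 8
## 2001: DNK->SWE Clupea harengus 6 (one-way, no match)
agg_fixture <- function() {
  rbind(
    worked_example_records(),
    make_records(c(2000, 2000), c("DNK", "SWE"), c("SWE", "DNK"),
                 "Clupea harengus", c(4, 4)),
    make_records(2001, "DNK", "SWE", "Clupea harengus", 6)
  )
}

region_fixture <- function() {
  data.table(
    country_iso3 = c("CAN", "USA", "DNK", "SWE"),
    continent = c("Americas", "Americas", "Europe", "Europe"),
    subregion = c("Northern America", "Northern America",
                  "Northern Europe", "Northern Europe")
  )
}

test_that("annual_series reproduces the single-year worked example", {
  rec <- worked_example_records()
  an <- annual_series(rec)
  expect_equal(nrow(an), 1)
  expect_equal(an$total_tonnes, 15)
  expect_equal(an$species_level_tonnes, 15)
  expect_equal(an$redundant_tonnes, 10)
  expect_equal(an$redundant_share_of_total, 10 / 15)
})

test_that("annual_series funnel invariants hold and years with no match are 0", {
  rec <- agg_fixture()
  an <- annual_series(rec)
  expect_equal(an$year, c(2000L, 2001L))
  expect_equal(an$redundant_tonnes, c(18, 0))
  expect_true(all(an$redundant_tonnes <= an$species_level_tonnes))
  expect_true(all(an$species_level_tonnes <= an$total_tonnes))
  expect_true(all(an$total_tonnes <= an$gross_tonnes))

  ## per-year values match brute-force recomputation on random fixtures
  for (seed in c(5, 6)) {
    r <- random_fixture(seed)
    a <- annual_series(r)
    o <- oracle_by(oracle_redundant_flows(r), "year")
    got <- setNames(a$redundant_tonnes, a$year)
    expect_equal(got[names(o)], o[names(o)], tolerance = 1e-12)
  }
})

test_that("percent_change follows its definition and flags a zero baseline", {
  s <- data.table(year = c(2000, 2015), redundant_tonnes = c(100, 143.4))
  expect_equal(percent_change(s, 2000, 2015), 43.4)
  expect_equal(percent_change(c("2000" = 200, "2015" = 150), 2000, 2015), -25)
  expect_equal(percent_change(c("2000" = 7, "2015" = 7), 2000, 2015), 0)
  expect_error(percent_change(s, 1999, 2015), "not present")
  expect_warning(out <- percent_change(c("2000" = 0, "2015" = 3),
                                       2000, 2015), "zero")
  expect_true(is.na(out))
})

test_that("country_attribution splits each match between both partners", {
  rec <- worked_example_records()
  flows <- compute_redundant_flows(rec)
  cs <- country_attribution(flows, rec)
  expect_equal(sort(cs$country), c("CAN", "USA"))
  expect_equal(cs$redundant_export_tonnes, c(5, 5))
  expect_equal(sum(cs$redundant_export_tonnes), sum(flows$redundant_tonnes))
  ## proportions: CAN exported 10 (5 redundant), USA exported 5 (5 redundant)
  expect_equal(cs[country == "CAN", redundancy_proportion], 0.5)
  expect_equal(cs[country == "USA", redundancy_proportion], 1.0)
  ## trade basis uses exports + imports
  cs2 <- country_attribution(flows, rec, proportion_basis = "trade")
  expect_equal(cs2[country == "CAN", redundancy_proportion], 5 / 15)
})

test_that("one-way-only countries appear with zero redundancy", {
  rec <- rbind(worked_example_records(),
               make_records(2000, "NOR", "GBR", "Salmo salar", 3))
  cs <- country_attribution(compute_redundant_flows(rec), rec)
  expect_equal(cs[country == "NOR", redundant_export_tonnes], 0)
  expect_equal(cs[country == "NOR", redundancy_proportion], 0)
  expect_equal(cs[country == "NOR", n_redundant_species], 0L)
})

test_that("country_attribution matches a brute-force per-country loop", {
  for (seed in c(21, 22, 23)) {
    rec <- random_fixture(seed)
    cs <- country_attribution(compute_redundant_flows(rec), rec)
    o <- oracle_by(oracle_redundant_flows(rec), "country")
    got <- setNames(cs$redundant_export_tonnes, cs$country)
    expect_equal(got[names(o)], o[names(o)], tolerance = 1e-12)
    ## countries with no redundancy are zero-filled, not dropped
    expect_true(all(setdiff(cs$country, names(o)) %in%
                      c(rec$exporter, rec$importer)))
  }
})

test_that("pair_ranking computes shares, overlap flags and both bases", {
  rec <- agg_fixture()
  flows <- compute_redundant_flows(rec)
  pr <- pair_ranking(flows, region_fixture())
  expect_s3_class(pr, "pair_ranking")
  expect_equal(nrow(pr$pairs), 2)
  ## sorted by tonnage: CAN-USA (10) above DNK-SWE (8)
  expect_equal(pr$pairs$country_a, c("CAN", "DNK"))
  expect_equal(sum(pr$pairs$share_of_global), 1)
  expect_true(all(pr$pairs$same_continent))
  expect_true(all(pr$pairs$same_subregion))
  expect_equal(pr$fractions$same_continent_count, 1)
  expect_equal(pr$fractions$same_subregion_tonnage, 1)

  ## one intra-continent pair of two -> 50% on the count basis
  rm2 <- region_fixture()
  rm2[country_iso3 == "USA", `:=`(continent = "Oceania",
                                  subregion = "Polynesia")]
  pr2 <- pair_ranking(flows, rm2)
  expect_equal(pr2$fractions$same_continent_count, 0.5)
  expect_equal(pr2$fractions$same_subregion_count, 0.5)
  ## tonnage basis weights by redundant volume: only DNK-SWE (8 of 18)
  expect_equal(pr2$fractions$same_continent_tonnage, 8 / 18)
})

test_that("unmapped countries warn, get NA flags and shrink denominators", {
  rec <- agg_fixture()
  flows <- compute_redundant_flows(rec)
  rm <- region_fixture()[country_iso3 != "CAN"]
  expect_warning(pr <- pair_ranking(flows, rm), "CAN")
  expect_true(is.na(pr$pairs[country_a == "CAN", same_continent]))
  expect_equal(pr$fractions$n_pairs_with_regions, 1)
  expect_equal(pr$fractions$same_continent_count, 1)  # DNK-SWE only
  ## shares still cover all pairs
  expect_equal(sum(pr$pairs$share_of_global), 1)
})

test_that("species_ranking joins IUCN categories and computes shares", {
  rec <- agg_fixture()
  flows <- compute_redundant_flows(rec)
  iucn <- data.table(taxon_name = "Gadus morhua", iucn_category = "VU")
  sr <- species_ranking(flows, iucn)
  expect_equal(sr$species$species, c("Gadus morhua", "Clupea harengus"))
  expect_equal(sr$species$share_of_global, c(10, 8) / 18)
  expect_equal(sr$species$iucn_category, c("VU", "NA"))  # absent -> NA
  ## per-species pair shares sum to one
  expect_equal(sr$pair_shares[, sum(share_within_species), by = species]$V1,
               c(1, 1))
  ## single-species fixture has share 1
  sr1 <- species_ranking(compute_redundant_flows(worked_example_records()))
  expect_equal(sr1$species$share_of_global, 1)

  ## shares equal brute-force recomputation
  for (seed in c(31, 32)) {
    r <- random_fixture(seed)
    s <- species_ranking(compute_redundant_flows(r))
    o <- oracle_by(oracle_redundant_flows(r), "species")
    got <- setNames(s$species$redundant_tonnes, s$species$species)
    expect_equal(got[names(o)], o[names(o)], tolerance = 1e-12)
  }
})

test_that("topk_coverage finds the smallest covering prefix", {
  expect_equal(topk_coverage(c(0.6, 0.3, 0.1), 0.9),
               list(k = 2L, cumulative_share = 0.9))
  expect_equal(topk_coverage(c(0.6, 0.3, 0.1), 1.0)$k, 3L)
  expect_equal(topk_coverage(1, 0.5), list(k = 1L, cumulative_share = 1))
  expect_error(topk_coverage(numeric(), 0.9), "empty")
  expect_error(topk_coverage(c(0.5, 0.5), 0), "threshold")
  ## monotone in the threshold
  set.seed(9)
  sh <- prop.table(rlnorm(20))
  ks <- vapply(seq(0.1, 1, by = 0.1),
               function(t) topk_coverage(sh, t)$k, integer(1))
  expect_true(all(diff(ks) >= 0))
  ## unsorted input is sorted internally
  expect_equal(topk_coverage(c(0.1, 0.6, 0.3), 0.9)$k, 2L)
})

test_that("threatened_share weights by tonnage over EN and VU", {
  sp <- data.table(
    species = c("a", "b", "c", "d"),
    redundant_tonnes = c(10, 30, 40, 20),
    iucn_category = c("EN", "VU", "LC", "DD")
  )
  ts <- threatened_share(sp)
  expect_equal(ts$fraction, 0.4)  # (10 + 30) / 100
  expect_equal(ts$category_counts[["EN"]], 1L)
  expect_equal(ts$category_counts[["NA"]], 0L)
  expect_equal(threatened_share(sp[iucn_category == "LC"])$fraction, 0)
  expect_equal(threatened_share(sp[iucn_category == "VU"])$fraction, 1)
})

test_that("redundancy_regression recovers exact and degenerate cases", {
  cs <- data.table(
    country = LETTERS[1:5],
    total_export_tonnes = c(1, 2, 3, 4, 5),
    species_level_fraction = c(0.2, 0.4, 0.5, 0.7, 0.9),
    redundant_export_tonnes = c(2, 4, 6, 8, 10)  # y = 2x exactly
  )
  fit <- redundancy_regression(cs)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  ## constant response: R^2 = 0
  cs2 <- data.table::copy(cs)[, redundant_export_tonnes := 3]
  expect_equal(redundancy_regression(cs2)$r_squared, 0, tolerance = 1e-12)

  ## degenerate predictor and tiny n are refused
  cs3 <- data.table::copy(cs)[, total_export_tonnes := 7]
  expect_error(redundancy_regression(cs3), "variance")
  expect_error(redundancy_regression(cs[1:2]), "at least 3")
})

test_that("aggregate conservation: all breakdowns equal the global total", {
  for (seed in c(41, 42, 43, 44)) {
    rec <- random_fixture(seed, n_rows = 80)
    flows <- compute_redundant_flows(rec)
    global <- sum(flows$redundant_tonnes)
    an <- annual_series(rec, flows)
    cs <- country_attribution(flows, rec)
    pr <- pair_ranking(flows, region_map_all())
    sr <- species_ranking(flows)
    expect_equal(sum(an$redundant_tonnes), global, tolerance = 1e-9)
    expect_equal(sum(cs$redundant_export_tonnes), global, tolerance = 1e-9)
    expect_equal(sum(pr$pairs$redundant_tonnes), global, tolerance = 1e-9)
    expect_equal(sum(sr$species$redundant_tonnes), global, tolerance = 1e-9)
    if (global > 0) {
      expect_equal(sum(pr$pairs$share_of_global), 1, tolerance = 1e-9)
      expect_equal(sum(sr$species$share_of_global), 1, tolerance = 1e-9)
    }
  }
})

test_that("headline_report bundles consistent numbers", {
  rec <- agg_fixture()
  flows <- compute_redundant_flows(rec)
  hl <- headline_report(annual_series(rec, flows),
                        country_attribution(flows, rec),
                        pair_ranking(flows, region_fixture()),
                        species_ranking(flows))
  expect_equal(hl$global_redundant_tonnes, 18)
  expect_equal(hl$n_countries_redundant, 4)
  expect_equal(hl$redundant_share_of_total, 18 / sum(rec$tonnes))
  expect_equal(hl$species_topk$k, 2)  # both species needed for 90%
  expect_true(is.null(hl$regression_total_exports) ||
                is.finite(hl$regression_total_exports$slope))
})
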