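## Shared fixtures and independent brute-force oracles.
## The oracles deliberately use plain loops and base R subsetting so they
## share no code path with the data.table implementation they check.

library(data.table)

## quick constructor of clean (capture, non-re-export, species-level) records
make_records <- function(year, exporter, importer, taxon, tonnes,
                         method = "capture", reexport = FALSE,
                         rank = NULL) {
  dt <- data.table(
    year = as.integer(year), exporter = exporter, importer = importer,
    taxon_name = taxon,
    taxon_rank = if (is.null(rank)) {
      normalize_taxon(taxon)$taxon_rank
    } else {
      rank
    },
    production_method = method, is_reexport = reexport,
    tonnes = as.numeric(tonnes)
  )
  dt
}

## records table -> raw CSV-layout data.frame accepted by as_trade_records
as_raw_table <- function(records) {
  df <- as.data.frame(records)
  names(df)[names(df) == "exporter"] <- "exporter_iso3"
  names(df)[names(df) == "importer"] <- "importer_iso3"
  df
}

## random clean fixture within the oracle-tractable envelope
## (<= 10 countries x 5 species x 3 years)
random_fixture <- function(seed, n_rows = 50, n_countries = 10,
                           n_species = 5, n_years = 3) {
  set.seed(seed)
  countries <- c("ARG", "BRA", "CAN", "DNK", "ESP", "FRA", "GBR", "NOR",
                 "SWE", "USA")[seq_len(n_countries)]
  species <- c("Gadus morhua", "Clupea harengus", "Scomber scombrus",
               "Katsuwonus pelamis", "Salmo salar")[seq_len(n_species)]
  years <- 2000L + seq_len(n_years) - 1L
  exporter <- sample(countries, n_rows, replace = TRUE)
  importer <- sample(countries, n_rows, replace = TRUE)
  keep <- exporter != importer
  make_records(sample(years, n_rows, replace = TRUE)[keep],
               exporter[keep], importer[keep],
               sample(species, n_rows, replace = TRUE)[keep],
               round(rlnorm(n_rows, log(50), 1), 3)[keep])
}

## brute-force Eq.-style enumeration: triple loop over (pair, species, year)
oracle_redundant_flows <- function(records) {
  df <- as.data.frame(records)
  countries <- sort(unique(c(df$exporter, df$importer)))
  out <- list()
  for (i in seq_along(countries)) {
    for (j in seq_along(countries)) {
      if (j <= i) next
      a <- countries[i]
      b <- countries[j]
      for (sp in sort(unique(df$taxon_name))) {
        for (yr in sort(unique(df$year))) {
          e_ab <- sum(df$tonnes[df$exporter == a & df$importer == b &
                                  df$taxon_name == sp & df$year == yr])
          e_ba <- sum(df$tonnes[df$exporter == b & df$importer == a &
                                  df$taxon_name == sp & df$year == yr])
          m <- min(e_ab, e_ba)
          if (m > 0) {
            out[[length(out) + 1L]] <- data.frame(
              year = yr, country_a = a, country_b = b, species = sp,
              export_ab = e_ab, export_ba = e_ba, matched_min = m,
              redundant_tonnes = 2 * m, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(year = integer(), country_a = character(),
                      country_b = character(), species = character(),
                      export_ab = numeric(), export_ba = numeric(),
                      matched_min = numeric(), redundant_tonnes = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$year, res$country_a, res$country_b, res$species), ,
      drop = FALSE]
}

## loop-based aggregations over an oracle flow table
oracle_by <- function(oflows, what) {
  flat <- function(v) setNames(as.numeric(v), names(v))  # drop tapply dims
  agg <- function(keys) {
    if (nrow(oflows) == 0L) return(setNames(numeric(0), character(0)))
    key <- do.call(paste, c(oflows[keys], sep = "|"))
    flat(tapply(oflows$redundant_tonnes, key, sum))
  }
  switch(what,
         year = agg("year"),
         pair = agg(c("country_a", "country_b")),
         species = agg("species"),
         country = {
           if (nrow(oflows) == 0L) return(setNames(numeric(0), character(0)))
           long <- rbind(
             data.frame(country = oflows$country_a, v = oflows$matched_min),
             data.frame(country = oflows$country_b, v = oflows$matched_min))
           flat(tapply(long$v, long$country, sum))
         })
}

expect_flows_equal_oracle <- function(flows, oflows) {
  expect_equal(nrow(flows), nrow(oflows))
  f <- as.data.frame(flows)
  rownames(f) <- rownames(oflows) <- NULL
  expect_identical(f$year, as.integer(oflows$year))
  expect_identical(f$country_a, oflows$country_a)
  expect_identical(f$country_b, oflows$country_b)
  expect_identical(f$species, oflows$species)
  expect_identical(f$export_ab, oflows$export_ab)
  expect_identical(f$export_ba, oflows$export_ba)
  expect_identical(f$redundant_tonnes, oflows$redundant_tonnes)
}

## region map covering every country random_fixture() can emit
region_map_all <- function() {
  data.table(
    country_iso3 = c("ARG", "BRA", "CAN", "DNK", "ESP", "FRA", "GBR",
                     "NOR", "SWE", "USA"),
    continent = c("Americas", "Americas", "Americas", "Europe", "Europe",
                  "Europe", "Europe", "Europe", "Europe", "Americas"),
    subregion = c("South America", "South America", "Northern America",
                  "Northern Europe", "Southern Europe", "Western Europe",
                  "Northern Europe", "Northern Europe", "Northern Europe",
                  "Northern America")
  )
}

## the in-text worked example: 10 t one way, 5 t back, one species, one year
worked_example_records <- function() {
  make_records(c(2000, 2000), c("CAN", "USA"), c("USA", "CAN"),
               "Gadus morhua", c(10, 5))
}
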