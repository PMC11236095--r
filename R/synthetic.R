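## Pools for the synthetic generator. Real ISO 3166-1 alpha-3 codes and real
## commercially traded marine taxa, so downstream joins and the taxon-rank
## classifier are exercised with realistic strings.

iso3_pool <- c(
  "ARG", "AUS", "AUT", "BEL", "BGD", "BRA", "CAN", "CHL", "CHN", "CIV",
  "COL", "DEU", "DNK", "ECU", "EGY", "ESP", "EST", "FIN", "FRA", "FRO",
  "GBR", "GHA", "GRC", "GRL", "HRV", "IDN", "IND", "IRL", "ISL", "ITA",
  "JPN", "KOR", "LKA", "LTU", "LVA", "MAR", "MDV", "MEX", "MMR", "MOZ",
  "MRT", "MYS", "NAM", "NGA", "NLD", "NOR", "NZL", "OMN", "PAK", "PAN",
  "PER", "PHL", "POL", "PRT", "RUS", "SEN", "SGP", "SVN", "SWE", "THA",
  "TUR", "TWN", "TZA", "UKR", "URY", "USA", "VNM", "YEM", "ZAF", "ARE",
  "BGR", "BLZ", "CPV", "CYP", "DZA", "FJI", "GAB", "GEO", "GIN", "GMB",
  "GNB", "GUY", "HND", "HTI", "JAM", "KEN", "KHM", "KIR", "LBN", "LBR",
  "MDG", "MLT", "NIC", "PNG", "PRK", "ROU", "SLB", "SLE", "SUR", "SYC",
  "TGO", "TON", "TTO", "TUN", "VUT", "WSM", "ALB", "BHS", "BRB", "COM",
  "CRI", "CUB", "DJI", "DOM", "ERI", "GTM", "ISR", "KWT", "BHR", "QAT"
)

species_pool <- c(
  "Clupea harengus", "Gadus morhua", "Katsuwonus pelamis",
  "Scomber scombrus", "Trachurus trachurus", "Merluccius senegalensis",
  "Apostichopus japonicus", "Salmo salar", "Thunnus albacares",
  "Thunnus obesus", "Thunnus alalunga", "Thunnus thynnus",
  "Engraulis ringens", "Engraulis encrasicolus", "Sardina pilchardus",
  "Sardinella aurita", "Sprattus sprattus", "Mallotus villosus",
  "Micromesistius poutassou", "Melanogrammus aeglefinus",
  "Pollachius virens", "Gadus chalcogrammus", "Merluccius merluccius",
  "Merluccius hubbsi", "Merluccius productus", "Merlangius merlangus",
  "Pleuronectes platessa", "Solea solea", "Hippoglossus hippoglossus",
  "Reinhardtius hippoglossoides", "Sebastes norvegicus",
  "Dicentrarchus labrax", "Sparus aurata", "Xiphias gladius",
  "Coryphaena hippurus", "Lophius piscatorius", "Anguilla anguilla",
  "Oncorhynchus gorbuscha", "Oncorhynchus keta", "Oncorhynchus nerka",
  "Oncorhynchus kisutch", "Salvelinus alpinus", "Osmerus mordax",
  "Ammodytes marinus", "Brevoortia tyrannus", "Scomberomorus commerson",
  "Scomber japonicus", "Sarda sarda", "Auxis thazard", "Euthynnus affinis",
  "Istiophorus platypterus", "Makaira nigricans", "Mugil cephalus",
  "Lates calcarifer", "Pagrus pagrus", "Dentex dentex",
  "Lutjanus campechanus", "Epinephelus marginatus", "Sciaenops ocellatus",
  "Argyrosomus regius", "Pangasianodon hypophthalmus", "Cyprinus carpio",
  "Ctenopharyngodon idella", "Oreochromis niloticus", "Clarias gariepinus",
  "Homarus americanus", "Nephrops norvegicus", "Penaeus monodon",
  "Pandalus borealis", "Crangon crangon", "Cancer pagurus",
  "Chionoecetes opilio", "Callinectes sapidus", "Octopus vulgaris",
  "Loligo vulgaris", "Dosidicus gigas", "Illex argentinus",
  "Sepia officinalis", "Mytilus edulis", "Crassostrea gigas",
  "Pecten maximus", "Placopecten magellanicus", "Ruditapes philippinarum",
  "Haliotis rubra", "Strongylocentrotus droebachiensis",
  "Palinurus elephas", "Panulirus argus", "Scylla serrata",
  "Anoplopoma fimbria", "Dissostichus eleginoides"
)

coarse_taxon_pool <- c(
  "miscellaneous marine fishes", "Elasmobranchii",
  "miscellaneous marine molluscs", "marine animals",
  "miscellaneous pelagic fishes", "miscellaneous demersal fishes",
  "marine crustaceans nei", "cephalopods nei"
)

continent_pool <- c("Europe", "Asia", "Africa", "Americas", "Oceania")

#' Configuration for the synthetic trade-network generator
#'
#' Builds and validates the parameter set consumed by
#' [generate_trade_network()]. Defaults describe a desk-scale trade network
#' with the qualitative structure of a global wild-capture seafood trade
#' database over 2000-2015: sparse directed flows (most country pairs do
#' not trade a given species at all), heavy-tailed log-normal volumes, a
#' minority of trading cells matched in both directions, and contaminant
#' records (aquaculture production, re-exports, coarse taxon groups)
#' injected on top of the clean rows so that every exclusion filter is
#' exercised and the clean ground truth stays exactly known.
#'
#' @param n_countries number of countries (>= 2, at most the packaged ISO3
#'   pool size).
#' @param n_species number of species-level taxa (>= 1, at most the
#'   packaged pool size).
#' @param years integer vector of calendar years.
#' @param edge_density probability that a (pair, species, year) cell trades
#'   at all.
#' @param two_way_fraction probability that a trading cell trades in both
#'   directions (the planted redundancy fraction).
#' @param volume_meanlog,volume_sdlog log-normal location/scale of directed
#'   cell volumes, tonnes.
#' @param aquaculture_rate,reexport_rate,coarse_taxon_rate,unknown_method_rate
#'   contaminant row counts as fractions of the clean row count.
#' @param n_continents,subregions_per_continent region scheme; countries
#'   are assigned round-robin to continents, then cyclically to subregions
#'   within each continent.
#' @param seed integer RNG seed; the whole generation is a pure function of
#'   the config.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_countries = 40,
                             n_species = 60,
                             years = 2000:2015,
                             edge_density = 0.02,
                             two_way_fraction = 0.2,
                             volume_meanlog = log(100),
                             volume_sdlog = 1.5,
                             aquaculture_rate = 0.30,
                             reexport_rate = 0.15,
                             coarse_taxon_rate = 0.45,
                             unknown_method_rate = 0.02,
                             n_continents = 5,
                             subregions_per_continent = 4,
                             seed = 1L) {
  n_countries <- assert_count(n_countries, "n_countries", lower = 2L)
  n_species <- assert_count(n_species, "n_species", lower = 1L)
  if (n_countries > length(iso3_pool)) {
    stop("`n_countries` exceeds the packaged ISO3 pool (",
         length(iso3_pool), ")", call. = FALSE)
  }
  if (n_species > length(species_pool)) {
    stop("`n_species` exceeds the packaged species pool (",
         length(species_pool), ")", call. = FALSE)
  }
  years <- as.integer(years)
  if (length(years) == 0L || anyNA(years)) {
    stop("`years` must be a nonempty integer vector", call. = FALSE)
  }
  for (p in c("edge_density", "two_way_fraction", "aquaculture_rate",
              "reexport_rate", "coarse_taxon_rate", "unknown_method_rate")) {
    assert_scalar_number(get(p), p, lower = 0, upper = 1)
  }
  assert_scalar_number(volume_meanlog, "volume_meanlog")
  assert_scalar_number(volume_sdlog, "volume_sdlog",
                       lower = .Machine$double.eps)
  n_continents <- assert_count(n_continents, "n_continents", lower = 1L)
  if (n_continents > length(continent_pool)) {
    stop("`n_continents` exceeds the packaged continent pool (",
         length(continent_pool), ")", call. = FALSE)
  }
  subregions_per_continent <- assert_count(subregions_per_continent,
                                           "subregions_per_continent",
                                           lower = 1L)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(list(
    n_countries = n_countries, n_species = n_species, years = sort(years),
    edge_density = edge_density, two_way_fraction = two_way_fraction,
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
    aquaculture_rate = aquaculture_rate, reexport_rate = reexport_rate,
    coarse_taxon_rate = coarse_taxon_rate,
    unknown_method_rate = unknown_method_rate,
    n_continents = n_continents,
    subregions_per_continent = subregions_per_continent,
    seed = seed
  ), class = "synthetic_config")
}

#' Generate a synthetic bilateral trade network with exact ground truth
#'
#' Simulates a long-format trade table, a region map and an IUCN lookup,
#' together with a ground-truth record that makes the expected output of
#' the whole analysis pipeline exactly computable.
#'
#' Draw order is fixed and documented: (1) one uniform per (pair, species,
#' year) cell deciding whether it trades, in cell order (pairs in
#' lexicographic order x species x years); (2) one uniform per trading cell
#' deciding two-way vs one-way; (3) one uniform per one-way cell picking
#' the direction; (4) log-normal volumes for every directed positive flow;
#' (5) contaminant rows. Clean rows are always wild-capture, non-re-export,
#' species level. Contaminants are added as extra rows - never replacing
#' clean rows - so the clean ground truth is exact: aquaculture rows,
#' re-export rows, coarse-taxon rows (drawn from group labels such as
#' "miscellaneous marine fishes") and unknown-method rows, each tagged with
#' the filter bucket that must claim it.
#'
#' IUCN categories are sampled per species with Least Concern most common
#' and roughly 40% Data Deficient or Not Assessed, the typical profile of
#' commercially traded marine taxa.
#'
#' @param config a `synthetic_config`.
#' @return list of class `synthetic_trade` with elements `trade` (the raw
#'   table in the documented CSV column layout, contaminants included),
#'   `region_map`, `iucn_table`, and `ground_truth`: a list holding `cells`
#'   (every trading cell with its directed clean volumes `export_ab`,
#'   `export_ba`), `clean_rows`, `contaminants` (with their `bucket` tag),
#'   `n_trading_cells`, `n_two_way_cells`, and the `config`.
#' @export
generate_trade_network <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  countries <- sort(iso3_pool[seq_len(config$n_countries)])
  species <- species_pool[seq_len(config$n_species)]
  continents <- continent_pool[seq_len(config$n_continents)]
  idx <- seq_along(countries)
  continent <- continents[(idx - 1L) %% config$n_continents + 1L]
  within <- (idx - 1L) %/% config$n_continents
  sub_idx <- within %% config$subregions_per_continent + 1L
  region_map <- data.table(
    country_iso3 = countries,
    continent = continent,
    subregion = paste(c("Northern", "Southern", "Eastern", "Western",
                        "Central")[(sub_idx - 1L) %% 5L + 1L], continent)
  )

  pair_idx <- utils::combn(countries, 2L)
  cells <- data.table::CJ(pair = seq_len(ncol(pair_idx)),
                          species = species, year = config$years,
                          sorted = FALSE)
  data.table::setorder(cells, pair, species, year)
  cells[, `:=`(country_a = pair_idx[1L, pair],
               country_b = pair_idx[2L, pair])]

  ## (1) which cells trade, (2) two-way?, (3) direction of one-way cells
  cells[, cell_trades := runif(.N) < config$edge_density]
  cells <- cells[cell_trades == TRUE]
  n_cells <- nrow(cells)
  if (n_cells > 0L) {
    cells[, two_way := runif(.N) < config$two_way_fraction]
    cells[, dir_ab := TRUE]
    one_way <- which(!cells$two_way)
    if (length(one_way)) {
      cells$dir_ab[one_way] <- runif(length(one_way)) < 0.5
    }
    ## (4) volumes for each realized directed flow
    has_ab <- cells$two_way | cells$dir_ab
    has_ba <- cells$two_way | !cells$dir_ab
    cells[, export_ab := 0]
    cells[, export_ba := 0]
    cells$export_ab[has_ab] <- rlnorm(sum(has_ab), config$volume_meanlog,
                                      config$volume_sdlog)
    cells$export_ba[has_ba] <- rlnorm(sum(has_ba), config$volume_meanlog,
                                      config$volume_sdlog)
  } else {
    cells[, `:=`(two_way = logical(), dir_ab = logical(),
                 export_ab = numeric(), export_ba = numeric())]
  }
  gt_cells <- cells[, .(year, country_a, country_b, species,
                        export_ab, export_ba, two_way)]

  clean_rows <- rbind(
    cells[export_ab > 0, .(year, exporter = country_a, importer = country_b,
                           taxon_name = species, tonnes = export_ab)],
    cells[export_ba > 0, .(year, exporter = country_b, importer = country_a,
                           taxon_name = species, tonnes = export_ba)]
  )
  clean_rows[, `:=`(taxon_rank = "species", production_method = "capture",
                    is_reexport = FALSE)]
  n_clean <- nrow(clean_rows)

  ## (5) contaminants: extra rows per rate, each tagged with its bucket
  draw_rows <- function(n, taxa, rank, method, reexport, bucket) {
    if (n <= 0L) {
      return(data.table(year = integer(), exporter = character(),
                        importer = character(), taxon_name = character(),
                        tonnes = numeric(), taxon_rank = character(),
                        production_method = character(),
                        is_reexport = logical(), bucket = character()))
    }
    exp_i <- sample.int(length(countries), n, replace = TRUE)
    imp_i <- sample.int(length(countries) - 1L, n, replace = TRUE)
    imp_i <- imp_i + (imp_i >= exp_i)  # uniform over partners != exporter
    data.table(
      year = sample(config$years, n, replace = TRUE),
      exporter = countries[exp_i],
      importer = countries[imp_i],
      taxon_name = sample(taxa, n, replace = TRUE),
      tonnes = rlnorm(n, config$volume_meanlog, config$volume_sdlog),
      taxon_rank = rank, production_method = method, is_reexport = reexport,
      bucket = bucket
    )
  }
  n_of <- function(rate) as.integer(round(rate * n_clean))
  contaminants <- rbind(
    draw_rows(n_of(config$aquaculture_rate), species, "species",
              "aquaculture", FALSE, "aquaculture"),
    draw_rows(n_of(config$unknown_method_rate), species, "species",
              "unknown", FALSE, "unknown_method"),
    draw_rows(n_of(config$reexport_rate), species, "species",
              "capture", TRUE, "reexport"),
    draw_rows(n_of(config$coarse_taxon_rate), coarse_taxon_pool, "higher",
              "capture", FALSE, "non_species")
  )
  ## collapse colliding contaminant keys so the emitted table has unique
  ## record keys; buckets never share a key, so bucket tonnages are unchanged
  contaminants <- contaminants[, .(tonnes = sum(tonnes)),
                               by = .(year, exporter, importer, taxon_name,
                                      taxon_rank, production_method,
                                      is_reexport, bucket)]
  data.table::setcolorder(contaminants,
                          c("year", "exporter", "importer", "taxon_name",
                            "tonnes", "taxon_rank", "production_method",
                            "is_reexport", "bucket"))

  trade <- rbind(clean_rows, contaminants[, -"bucket"], use.names = TRUE)
  data.table::setnames(trade, c("exporter", "importer"),
                       c("exporter_iso3", "importer_iso3"))
  data.table::setcolorder(trade, c("year", "exporter_iso3", "importer_iso3",
                                   "taxon_name", "taxon_rank",
                                   "production_method", "is_reexport",
                                   "tonnes"))
  data.table::setorder(trade, year, exporter_iso3, importer_iso3, taxon_name,
                       production_method, is_reexport)

  iucn_table <- data.table(
    taxon_name = species,
    iucn_category = sample(iucn_categories(), config$n_species,
                           replace = TRUE,
                           prob = c(0.40, 0.07, 0.08, 0.04, 0.02, 0.14, 0.25))
  )
  data.table::setkeyv(iucn_table, "taxon_name")

  structure(list(
    trade = trade[],
    region_map = region_map,
    iucn_table = iucn_table,
    ground_truth = list(
      cells = gt_cells[order(year, country_a, country_b, species)][],
      clean_rows = clean_rows[],
      contaminants = contaminants[],
      n_trading_cells = n_cells,
      n_two_way_cells = if (n_cells > 0L) sum(cells$two_way) else 0L,
      config = config
    )
  ), class = "synthetic_trade")
}

#' @export
print.synthetic_trade <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf(paste0("Synthetic trade network: %d rows (%d clean, %d ",
                     "contaminant), %d trading cells (%d two-way)\n"),
              nrow(x$trade), nrow(gt$clean_rows), nrow(gt$contaminants),
              gt$n_trading_cells, gt$n_two_way_cells))
  invisible(x)
}

#' Expected redundancy from synthetic ground truth
#'
#' Applies the matched-minimum statistic directly to the clean directed
#' cell volumes recorded at generation time, bypassing the reader, filters
#' and flow computation entirely. This is the independent oracle for
#' end-to-end pipeline tests: on any seed the pipeline must reproduce these
#' numbers exactly.
#'
#' @param ground_truth the `ground_truth` element of a
#'   [generate_trade_network()] result.
#' @return list with `global_redundant_tonnes`, `flows` (the expected
#'   redundant-flow table), and `by_year`, `by_country`, `by_pair`,
#'   `by_species` breakdowns.
#' @export
expected_redundancy <- function(ground_truth) {
  cells <- data.table::as.data.table(ground_truth$cells)
  flows <- cells[pmin(export_ab, export_ba) > 0,
                 .(year, country_a, country_b, species, export_ab, export_ba,
                   matched_min = pmin(export_ab, export_ba),
                   redundant_tonnes = 2 * pmin(export_ab, export_ba))]
  data.table::setorder(flows, year, country_a, country_b, species)
  by_country <- rbind(
    flows[, .(country = country_a, matched_min)],
    flows[, .(country = country_b, matched_min)]
  )[, .(redundant_export_tonnes = sum(matched_min)), by = country][
    order(country)]
  list(
    global_redundant_tonnes = sum(flows$redundant_tonnes),
    flows = flows[],
    by_year = flows[, .(redundant_tonnes = sum(redundant_tonnes)),
                    by = year][order(year)],
    by_country = by_country,
    by_pair = flows[, .(redundant_tonnes = sum(redundant_tonnes)),
                    by = .(country_a, country_b)][order(country_a,
                                                        country_b)],
    by_species = flows[, .(redundant_tonnes = sum(redundant_tonnes)),
                       by = species][order(species)]
  )
}

#' Write a synthetic trade network to disk
#'
#' Writes `trade.csv`, `regions.csv` and `iucn.csv` in the documented
#' layouts, plus `ground_truth.json` with the clean cell volumes and
#' contaminant tags.
#'
#' @param sim a `synthetic_trade` object.
#' @param dir output directory, created if needed.
#' @return named character vector of paths, invisibly.
#' @export
write_synthetic_data <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_trade"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trade = file.path(dir, "trade.csv"),
             regions = file.path(dir, "regions.csv"),
             iucn = file.path(dir, "iucn.csv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  fwrite_precise(sim$trade, paths[["trade"]])
  data.table::fwrite(sim$region_map, paths[["regions"]])
  data.table::fwrite(sim$iucn_table, paths[["iucn"]])
  gt <- sim$ground_truth
  jsonlite::write_json(list(
    cells = gt$cells,
    contaminants = gt$contaminants,
    n_trading_cells = gt$n_trading_cells,
    n_two_way_cells = gt$n_two_way_cells,
    config = unclass(gt$config)
  ), paths[["ground_truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
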