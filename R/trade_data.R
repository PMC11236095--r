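#' Normalize a taxon name and classify its taxonomic rank
#'
#' Trade databases mix species-level binomials (`"Gadus morhua"`) with coarse
#' commodity groups (`"miscellaneous marine fishes"`, `"Elasmobranchii"`).
#' Redundancy analysis is restricted to species-level records, so every taxon
#' string is normalized (trimmed, internal whitespace collapsed, case
#' canonicalized) and classified as `"species"` or `"higher"`.
#'
#' A name is species-level iff, after normalization, it is a two-token
#' alphabetic binomial (capitalized genus, lower-case epithet) or it appears
#' in `species_whitelist` (matched case-insensitively after whitespace
#' normalization). Binomials are case-folded to `"Genus epithet"`; all other
#' names to sentence case. The function is idempotent and vectorized.
#'
#' @param raw_name character vector of taxon names as found in the input.
#' @param species_whitelist optional character vector of names to force to
#'   rank `"species"` even when they do not match the binomial pattern.
#' @return a `data.table` with columns `taxon_name` (normalized name,
#'   `NA` for empty/whitespace-only input) and `taxon_rank`
#'   (`"species"`/`"higher"`, `NA` where the name is `NA`).
#' @examples
#' normalize_taxon(c("Gadus  morhua", "ELASMOBRANCHII ",
#'                   "miscellaneous marine fishes"))
#' @export
normalize_taxon <- function(raw_name, species_whitelist = NULL) {
  raw_name <- as.character(raw_name)
  name <- gsub("\\s+", " ", trimws(raw_name))
  name[!nzchar(name) | is.na(name)] <- NA_character_

  tokens <- strsplit(name, " ", fixed = TRUE)
  n_tok <- lengths(tokens)
  alpha <- vapply(tokens, function(tk) all(grepl("^[A-Za-z-]+$", tk)), logical(1))
  binomial <- !is.na(name) & n_tok == 2L & alpha

  sentence_case <- function(x) {
    out <- tolower(x)
    substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
    out
  }
  norm <- name
  norm[binomial] <- vapply(tokens[binomial], function(tk) {
    paste(sentence_case(tk[1L]), tolower(tk[2L]))
  }, character(1))
  other <- !is.na(name) & !binomial
  norm[other] <- sentence_case(name[other])

  rank <- ifelse(is.na(norm), NA_character_,
                 ifelse(binomial, "species", "higher"))
  if (!is.null(species_whitelist) && length(species_whitelist)) {
    wl <- tolower(gsub("\\s+", " ", trimws(as.character(species_whitelist))))
    rank[!is.na(norm) & tolower(norm) %in% wl] <- "species"
  }
  data.table(taxon_name = norm, taxon_rank = rank)
}

parse_logical_flag <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[key %in% c("false", "f", "0", "no", "n", "")] <- NA
  out[key %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Validate a data frame of bilateral trade flow records
#'
#' Core validation behind [read_trade_table()], usable directly on in-memory
#' tables (e.g. from [generate_trade_network()]). Expects the documented
#' column set: `year`, `exporter_iso3`, `importer_iso3`, `taxon_name`,
#' optional `taxon_rank`, `production_method`, `is_reexport`, `tonnes`.
#'
#' Hard invariant violations are rejected row-wise and tallied by reason:
#' `bad_year` (unparseable/non-integer year), `bad_country_code` (exporter or
#' importer not a three-letter ISO 3166-1 alpha-3 code), `self_trade`
#' (exporter equals importer), `empty_taxon`, `bad_reexport_flag`,
#' `nonfinite_volume` and `negative_volume`. Production methods other than
#' `capture`/`aquaculture` are coerced to `unknown` (counted, not rejected).
#' Zero-tonne rows are retained but counted. Rows that share the full key
#' (year, exporter, importer, taxon, method, re-export flag) are merged by
#' summing tonnes, since the redundancy statistic operates on annual totals.
#'
#' An explicit `taxon_rank` column (`"species"`/`"higher"`) overrides both
#' the binomial pattern and the whitelist for that row.
#'
#' @param df data.frame with the columns above.
#' @param species_whitelist optional character vector passed to
#'   [normalize_taxon()].
#' @return an object of class `trade_table`: a list with `records`
#'   (validated `data.table` keyed by year/exporter/importer/taxon) and
#'   `report` (class `trade_validation_report`).
#' @export
as_trade_records <- function(df, species_whitelist = NULL) {
  dt <- data.table::as.data.table(df)
  required <- c("year", "exporter_iso3", "importer_iso3", "taxon_name",
                "production_method", "is_reexport", "tonnes")
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) == 0L) stop("trade table has no data rows", call. = FALSE)
  rows_in <- nrow(dt)

  year <- suppressWarnings(as.numeric(dt$year))
  year_ok <- !is.na(year) & year == floor(year)
  exporter <- toupper(trimws(as.character(dt$exporter_iso3)))
  importer <- toupper(trimws(as.character(dt$importer_iso3)))
  country_ok <- grepl("^[A-Z]{3}$", exporter) & grepl("^[A-Z]{3}$", importer)
  self_trade <- country_ok & exporter == importer
  tx <- normalize_taxon(dt$taxon_name, species_whitelist)
  taxon_ok <- !is.na(tx$taxon_name)
  reexp <- parse_logical_flag(dt$is_reexport)
  reexp_ok <- !is.na(reexp)
  tonnes <- suppressWarnings(as.numeric(dt$tonnes))
  finite_ok <- is.finite(tonnes)
  nonneg_ok <- finite_ok & tonnes >= 0

  method <- tolower(trimws(as.character(dt$production_method)))
  method_known <- method %in% c("capture", "aquaculture")
  method[!method_known] <- "unknown"

  rank <- tx$taxon_rank
  if ("taxon_rank" %in% names(dt)) {
    given <- tolower(trimws(as.character(dt$taxon_rank)))
    override <- given %in% c("species", "higher")
    rank[override] <- given[override]
  }

  ## first failing reason per row, in a fixed reporting order
  reason <- rep(NA_character_, rows_in)
  claim <- function(bad, label) reason[is.na(reason) & bad] <<- label
  claim(!year_ok, "bad_year")
  claim(!country_ok, "bad_country_code")
  claim(self_trade, "self_trade")
  claim(!taxon_ok, "empty_taxon")
  claim(!reexp_ok, "bad_reexport_flag")
  claim(!finite_ok, "nonfinite_volume")
  claim(finite_ok & !nonneg_ok, "negative_volume")
  keep <- is.na(reason)

  rec <- data.table(
    year = as.integer(year[keep]),
    exporter = exporter[keep],
    importer = importer[keep],
    taxon_name = tx$taxon_name[keep],
    taxon_rank = rank[keep],
    production_method = method[keep],
    is_reexport = reexp[keep],
    tonnes = tonnes[keep]
  )
  zero_rows <- sum(rec$tonnes == 0)
  merged <- rec[, .(tonnes = sum(tonnes)),
                by = .(year, exporter, importer, taxon_name, taxon_rank,
                       production_method, is_reexport)]
  data.table::setcolorder(merged, record_columns)
  data.table::setkeyv(merged, c("year", "exporter", "importer", "taxon_name"))

  rejected <- table(factor(reason[!keep]))
  report <- structure(list(
    rows_in = rows_in,
    rows_rejected = sum(!keep),
    rejected = setNames(as.integer(rejected), names(rejected)),
    duplicates_merged = nrow(rec) - nrow(merged),
    zero_tonne_rows = zero_rows,
    method_coerced_unknown = sum(!method_known[keep]),
    records_out = nrow(merged)
  ), class = "trade_validation_report")

  structure(list(records = merged, report = report), class = "trade_table")
}

#' Read and validate a bilateral trade flow CSV
#'
#' Reads a long-format trade table (one row per year x exporter x importer x
#' taxon x production method x re-export flag, volumes in live-weight
#' tonnes) and validates it with [as_trade_records()]. Required columns:
#' `year`, `exporter_iso3`, `importer_iso3`, `taxon_name`,
#' `production_method`, `is_reexport`, `tonnes`; `taxon_rank` is optional.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @inheritParams as_trade_records
#' @return see [as_trade_records()].
#' @export
read_trade_table <- function(path, species_whitelist = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, encoding = "UTF-8", showProgress = FALSE)
  if (nrow(dt) == 0L) stop("trade table is empty: ", path, call. = FALSE)
  as_trade_records(dt, species_whitelist)
}

#' Write validated trade records back to CSV
#'
#' Inverse of [read_trade_table()]: writes the documented column layout so a
#' validated table round-trips to a fixed point.
#'
#' @param x a `trade_table` or a records `data.table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trade_table <- function(x, path) {
  rec <- check_record_columns(records_of(x))
  out <- data.table::copy(rec)
  data.table::setnames(out, c("exporter", "importer"),
                       c("exporter_iso3", "importer_iso3"))
  fwrite_precise(out, path)
  invisible(path)
}

#' @export
print.trade_validation_report <- function(x, ...) {
  cat("Trade table validation report\n")
  cat(sprintf("  rows in:            %d\n", x$rows_in))
  cat(sprintf("  rows rejected:      %d\n", x$rows_rejected))
  for (nm in names(x$rejected)) {
    cat(sprintf("    %-20s %d\n", paste0(nm, ":"), x$rejected[[nm]]))
  }
  cat(sprintf("  duplicates merged:  %d\n", x$duplicates_merged))
  cat(sprintf("  zero-tonne rows:    %d\n", x$zero_tonne_rows))
  cat(sprintf("  method -> unknown:  %d\n", x$method_coerced_unknown))
  cat(sprintf("  records out:        %d\n", x$records_out))
  invisible(x)
}

#' @export
print.trade_table <- function(x, ...) {
  cat(sprintf("Validated trade table: %d records, %d year(s), %d countries\n",
              nrow(x$records), data.table::uniqueN(x$records$year),
              data.table::uniqueN(c(x$records$exporter, x$records$importer))))
  print(x$report)
  invisible(x)
}

#' Read a country-to-region lookup table
#'
#' Region CSV columns: `country_iso3`, `continent`, `subregion` (UN M49
#' style subregion labels such as "Northern America"). One row per country;
#' empty labels and duplicated countries are fatal.
#'
#' @param path CSV path.
#' @return keyed `data.table` with the three columns.
#' @export
read_region_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, encoding = "UTF-8", showProgress = FALSE)
  missing <- setdiff(c("country_iso3", "continent", "subregion"), names(dt))
  if (length(missing)) {
    stop("region map missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt[, country_iso3 := toupper(trimws(country_iso3))]
  if (anyDuplicated(dt$country_iso3)) {
    stop("region map has duplicated country codes", call. = FALSE)
  }
  if (any(!nzchar(trimws(dt$continent)) | !nzchar(trimws(dt$subregion)))) {
    stop("region map has empty continent/subregion labels", call. = FALSE)
  }
  data.table::setkeyv(dt, "country_iso3")
  dt[]
}

#' Read a taxon-to-IUCN-category lookup table
#'
#' Columns: `taxon_name`, `iucn_category`. Categories must be in the closed
#' set LC, NT, VU, EN, CR, DD, NA ("NA" meaning Not Assessed, kept as the
#' literal string). Taxon names are normalized with [normalize_taxon()] so
#' the join to species summaries is case- and whitespace-insensitive.
#'
#' @param path CSV path.
#' @return keyed `data.table` with normalized `taxon_name` and
#'   `iucn_category`.
#' @export
read_iucn_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, encoding = "UTF-8", showProgress = FALSE,
                          na.strings = NULL,
                          colClasses = list(character = c("taxon_name",
                                                          "iucn_category")))
  missing <- setdiff(c("taxon_name", "iucn_category"), names(dt))
  if (length(missing)) {
    stop("IUCN table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dt[, taxon_name := normalize_taxon(taxon_name)$taxon_name]
  dt[, iucn_category := toupper(trimws(iucn_category))]
  bad <- setdiff(unique(dt$iucn_category), iucn_categories())
  if (length(bad)) {
    stop("unknown IUCN categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(dt$taxon_name)) {
    stop("IUCN table has duplicated taxon names", call. = FALSE)
  }
  data.table::setkeyv(dt, "taxon_name")
  dt[]
}

#' Closed set of IUCN Red List category codes used in the package
#'
#' LC = Least Concern, NT = Near Threatened, VU = Vulnerable,
#' EN = Endangered, CR = Critically Endangered, DD = Data Deficient,
#' NA = Not Assessed.
#'
#' @return character vector of the seven codes.
#' @export
iucn_categories <- function() c("LC", "NT", "VU", "EN", "CR", "DD", "NA")
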