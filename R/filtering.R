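filter_buckets <- c("aquaculture", "unknown_method", "reexport", "non_species")

#' Apply the wild-capture species-level exclusion filters
#'
#' Restricts a validated trade table to the scope in which redundancy is
#' defined: wild-capture production, no re-exports, and records resolved to
#' taxonomic species level. Each excluded tonne is attributed to exactly one
#' bucket, the first matching rule in the fixed order
#' aquaculture -> unknown production method -> re-export -> non-species.
#' The retained set does not depend on this order (the rules are independent
#' predicates); only the attribution of rows failing several rules does.
#'
#' Records with `production_method = "unknown"` are excluded into their own
#' explicit `unknown_method` bucket rather than silently treated as capture:
#' the analysis is about wild-caught trade only and unknown provenance would
#' inflate it.
#'
#' @param x a `trade_table` or validated records `data.table`.
#' @return a list with `records` (the retained `data.table`) and `report`
#'   (class `filter_report`: per-year tonnage accounting plus totals).
#' @export
apply_filters <- function(x) {
  rec <- check_record_columns(records_of(x))
  bucket_of <- function(dt) {
    data.table::fcase(
      dt$production_method == "aquaculture", "aquaculture",
      dt$production_method == "unknown", "unknown_method",
      dt$is_reexport, "reexport",
      dt$taxon_rank != "species", "non_species",
      default = "retained"
    )
  }
  if (nrow(rec) == 0L) {
    empty <- data.table(year = integer(), total_tonnes = numeric(),
                        aquaculture_tonnes = numeric(),
                        unknown_method_tonnes = numeric(),
                        reexport_tonnes = numeric(),
                        non_species_tonnes = numeric(),
                        retained_tonnes = numeric())
    totals <- setNames(numeric(7), names(empty)[-1])
    report <- structure(list(per_year = empty, totals = totals),
                        class = "filter_report")
    return(list(records = rec, report = report))
  }
  b <- bucket_of(rec)
  tmp <- data.table(year = rec$year, bucket = b, tonnes = rec$tonnes)
  wide <- data.table::dcast(tmp, year ~ bucket, value.var = "tonnes",
                            fun.aggregate = sum, fill = 0)
  for (col in c(filter_buckets, "retained")) {
    if (!col %in% names(wide)) wide[, (col) := 0]
  }
  per_year <- wide[, .(
    year,
    total_tonnes = aquaculture + unknown_method + reexport + non_species +
      retained,
    aquaculture_tonnes = aquaculture,
    unknown_method_tonnes = unknown_method,
    reexport_tonnes = reexport,
    non_species_tonnes = non_species,
    retained_tonnes = retained
  )][order(year)]
  totals <- vapply(names(per_year)[-1], function(col) sum(per_year[[col]]),
                   numeric(1))
  report <- structure(list(per_year = per_year, totals = totals),
                      class = "filter_report")
  list(records = rec[b == "retained"], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter report (tonnes)\n")
  for (nm in names(x$totals)) {
    cat(sprintf("  %-24s %.3f\n", paste0(nm, ":"), x$totals[[nm]]))
  }
  cat(sprintf("  years covered:           %d\n", nrow(x$per_year)))
  invisible(x)
}

#' Fraction of trade resolved to species level
#'
#' Retained (wild-capture, non-re-export, species-level) tonnage divided by
#' total tonnage, for the whole table or one year. The numerator is the
#' species-level volume surviving the full filter funnel, so this is the
#' "Species / Total" ratio of the annual filtering funnel.
#'
#' @param report a `filter_report` from [apply_filters()].
#' @param year optional single year; default uses the all-years totals.
#' @return a number in \[0, 1\], or `NA_real_` with a warning when the
#'   requested scope has zero (or no) total tonnage.
#' @export
species_level_fraction <- function(report, year = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (is.null(year)) {
    tot <- report$totals[["total_tonnes"]]
    ret <- report$totals[["retained_tonnes"]]
  } else {
    py <- as.data.frame(report$per_year)  # plain frame: no column capture
    row <- py[py$year == year, , drop = FALSE]
    if (nrow(row) == 0L) {
      warning("year ", year, " not present in filter report; ",
              "species-level fraction undefined")
      return(NA_real_)
    }
    tot <- row$total_tonnes
    ret <- row$retained_tonnes
  }
  if (!isTRUE(tot > 0)) {
    warning("total tonnage is zero; species-level fraction undefined")
    return(NA_real_)
  }
  ret / tot
}

#' Serialize a filter report
#'
#' Writes the per-year accounting (plus an `all` summary row) as CSV and,
#' optionally, the full report as JSON.
#'
#' @param report a `filter_report`.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_filter_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "filter_report"))
  if (!is.null(csv_path)) {
    tab <- data.table::copy(report$per_year)
    tab[, year := as.character(year)]
    total_row <- c(list(year = "all"), as.list(report$totals))
    data.table::fwrite(rbind(tab, total_row, use.names = TRUE), csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(per_year = report$per_year, totals = as.list(report$totals)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv = csv_path, json = json_path))
}
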