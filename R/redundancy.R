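#' Redundant two-way trade volume for one matched cell
#'
#' For directed annual export volumes `export_ab` (country a to b) and
#' `export_ba` (b to a) of the same species in the same year, the redundant
#' two-way volume is twice their minimum: the total tonnage that could be
#' removed from the network, split equally between the two directions,
#' without changing either country's final supply. This is the
#' identical-commodity special case of the matched (intra-industry) trade
#' component of the Grubel-Lloyd decomposition.
#'
#' @param export_ab,export_ba non-negative finite volumes in tonnes;
#'   vectorized, recycled to common length.
#' @return `2 * pmin(export_ab, export_ba)`, symmetric in its arguments.
#' @examples
#' pair_redundancy(10, 5)  # 10 tonnes redundant in total
#' @export
pair_redundancy <- function(export_ab, export_ba) {
  check_volumes(export_ab, export_ba)
  2 * pmin(export_ab, export_ba)
}

#' Avoidable export volume per country in a matched cell
#'
#' The matched minimum `min(export_ab, export_ba)`: the export volume each
#' of the two partners could individually stop shipping. Half of
#' [pair_redundancy()].
#'
#' @inheritParams pair_redundancy
#' @return `pmin(export_ab, export_ba)`.
#' @examples
#' avoided_exports(10, 5)  # each country could avoid 5 tonnes of export
#' @export
avoided_exports <- function(export_ab, export_ba) {
  check_volumes(export_ab, export_ba)
  pmin(export_ab, export_ba)
}

check_volumes <- function(export_ab, export_ba) {
  for (v in list(export_ab, export_ba)) {
    if (!is.numeric(v) || length(v) == 0L || any(!is.finite(v)) || any(v < 0)) {
      stop("export volumes must be non-negative finite numerics",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Compute redundant two-way flows for every pair x species x year cell
#'
#' Takes filtered records (wild capture, not re-exported, species level; see
#' [apply_filters()]), sums the directed annual volume per (exporter,
#' importer, species, year), and emits one row per canonical unordered
#' country pair x species x year in which both directions are positive.
#' Pair canonicalization is lexicographic (`country_a < country_b`), so the
#' symmetric statistic never produces duplicate rows.
#'
#' Matching is exact in species and calendar year: no cross-year or
#' cross-species netting. Cells where one direction is zero carry no match
#' and are omitted.
#'
#' @param x filtered records (`data.table` or the list from
#'   [apply_filters()]).
#' @param check validate that records are within the filtered scope
#'   (default `TRUE`).
#' @return a `data.table` with columns `year`, `country_a`, `country_b`,
#'   `species`, `export_ab`, `export_ba`, `matched_min`,
#'   `redundant_tonnes`, sorted by year/pair/species.
#' @export
compute_redundant_flows <- function(x, check = TRUE) {
  rec <- if (is.list(x) && !is.data.frame(x) && !is.null(x$records)) {
    x$records
  } else {
    records_of(x)
  }
  check_record_columns(rec)
  if (check && nrow(rec) > 0L) {
    in_scope <- rec$production_method == "capture" & !rec$is_reexport &
      rec$taxon_rank == "species"
    if (!all(in_scope)) {
      stop("records outside the filtered scope (capture, non-re-export, ",
           "species level); run apply_filters() first", call. = FALSE)
    }
  }
  empty <- data.table(year = integer(), country_a = character(),
                      country_b = character(), species = character(),
                      export_ab = numeric(), export_ba = numeric(),
                      matched_min = numeric(), redundant_tonnes = numeric())
  if (nrow(rec) == 0L) return(empty)

  directed <- rec[, .(tonnes = sum(tonnes)),
                  by = .(year, exporter, importer, taxon_name)]
  directed[, `:=`(
    country_a = pmin(exporter, importer),
    country_b = pmax(exporter, importer),
    direction = data.table::fifelse(exporter < importer, "export_ab",
                                    "export_ba")
  )]
  flows <- data.table::dcast(directed,
                             year + country_a + country_b + taxon_name ~
                               direction,
                             value.var = "tonnes", fill = 0)
  for (col in c("export_ab", "export_ba")) {
    if (!col %in% names(flows)) flows[, (col) := 0]
  }
  data.table::setnames(flows, "taxon_name", "species")
  flows[, matched_min := pmin(export_ab, export_ba)]
  flows <- flows[matched_min > 0]
  if (nrow(flows) == 0L) return(empty)
  flows[, redundant_tonnes := 2 * matched_min]
  data.table::setcolorder(flows, names(empty))
  flows[order(year, country_a, country_b, species)][]
}

#' Export redundant flows as a weighted undirected edge list
#'
#' Convenience projection of [compute_redundant_flows()] output for network
#' tools: one edge per canonical pair x year x species with the redundant
#' tonnage as weight.
#'
#' @param flows output of [compute_redundant_flows()].
#' @param path optional CSV path; when given the table is also written.
#' @return `data.table` with columns `country_a`, `country_b`, `year`,
#'   `species`, `redundant_tonnes`.
#' @export
redundancy_edge_list <- function(flows, path = NULL) {
  edges <- flows[, .(country_a, country_b, year, species, redundant_tonnes)]
  if (!is.null(path)) data.table::fwrite(edges, path)
  edges[]
}
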