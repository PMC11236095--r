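## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## scalar checks used across the public surface
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s], got: %s",
                 name, format(lower), format(upper),
                 paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) ||
      x < lower) {
    stop(sprintf("`%s` must be a single integer >= %d", name, lower),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

## Accept either a trade_table (list with $records) or a bare records table.
records_of <- function(x) {
  if (inherits(x, "trade_table")) return(x$records)
  if (is.data.frame(x)) return(data.table::as.data.table(x))
  stop("expected a trade_table or a data.frame of trade records", call. = FALSE)
}

## fwrite truncates doubles at 15 significant digits, which does not
## round-trip; 17 does. Used for every CSV whose volumes feed back into
## exact-equality pipelines.
fwrite_precise <- function(dt, path) {
  out <- data.table::copy(data.table::as.data.table(dt))
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[, (col) := sprintf("%.17g", get(col))]
    }
  }
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

record_columns <- c("year", "exporter", "importer", "taxon_name", "taxon_rank",
                    "production_method", "is_reexport", "tonnes")

check_record_columns <- function(dt, context = "records") {
  missing <- setdiff(record_columns, names(dt))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(dt)
}
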