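---
title: "Quantifying redundant two-way trade: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying redundant two-way trade: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redtrade)
library(data.table)
```

## The statistic

Two countries often ship the same commodity to each other in the same
period. For an unordered country pair $(i, j)$, a taxonomic species $s$ and
a calendar year, let $E_{ijs}$ and $E_{jis}$ be the two directed annual
export volumes in live-weight tonnes. The *redundant two-way* volume is

$$R_{ij} = \min(E_{ijs}, E_{jis}) \times 2 .$$

$\min(E_{ijs}, E_{jis})$ is the export volume *each* partner could stop
shipping with no change to final supply on either side; doubling it counts
both avoidable directions. This is the identical-commodity special case of
the matched (intra-industry) component in the Grubel–Lloyd decomposition:
because the commodity on both sides is the *same species*, the matched
volume is interpretable as genuinely redundant exchange rather than product
differentiation.

The statistic is symmetric, monotone non-decreasing in each flow,
positively homogeneous of degree one, zero exactly when trade is one-way,
and bounded by the combined flow $E_{ijs} + E_{jis}$. All five properties
are enforced as randomized property tests.

## Analysis scope and the filter funnel

Redundancy is only meaningful where the two sides are comparable, so the
pipeline restricts the input to wild-capture, non-re-exported,
species-level records, in that order of attribution:

1. **Aquaculture** records are excluded: a farmed product is not clearly
   exchangeable with a wild-caught one.
2. **Unknown production method** records are excluded into their own
   explicit bucket. Treating them as capture would silently inflate the
   wild-capture totals; they are a separate line in the report instead.
3. **Re-exports** are excluded; the input's re-export flag is trusted (the
   source-data convention is that flows are attributed to the initial
   exporter and final importer, so flagged rows are double counting).
4. **Non-species records** ("miscellaneous marine fishes",
   "Elasmobranchii", …) are excluded: a coarse group matched against itself
   is not the same commodity.

Each excluded tonne is claimed by the *first* matching rule, which makes
the report an exact partition of the input tonnage (tested to 1e-12). The
retained set itself does not depend on the rule order — the rules are
independent predicates — only the attribution of rows failing several rules
does. The per-year report exposes both the gross total (everything
validated) and the wild-capture total, because which of the two a "Total"
series should mean is a presentation choice, not a property of the data.

A consequence the package inherits rather than fixes: matching is exact in
species and *calendar year*. Seasonal complementarity (country A exports in
spring, imports in autumn) is counted as redundant at annual resolution,
and different product forms of one species (fresh vs canned) are
indistinguishable. Annual, species-level aggregation is the stated
granularity of this analysis.

## Species-level detection

A taxon is species-level iff its normalized name is a two-token alphabetic
binomial (capitalized genus + lower-case epithet), or it appears in a
user-supplied whitelist, or an explicit `taxon_rank` input column says so
(the column overrides both rules). Normalization (trim, collapse internal
whitespace, canonical case) is idempotent, so re-validating a validated
table is a fixed point — also tested.

## Aggregation choices

* **Country attribution.** Each matched cell credits its matched minimum to
  *both* partners as "redundant exports". Under this attribution the
  country totals sum exactly to the global redundant tonnage (each
  $2\min$ splits as $\min + \min$), which is the only attribution under
  which top-$k$ country shares of the global figure are coherent.
* **Country redundancy proportion.** The denominator is the country's total
  wild-capture non-re-export *exports* by default (pre species filter);
  an exports+imports basis is available via `proportion_basis = "trade"`
  because the field's phrase "proportion of total trade" is ambiguous. The
  choice is a parameter, not a guess.
* **Region overlap.** Same-continent and same-subregion fractions are
  reported on two bases: pair counts (matching the usual "70% of partners
  were within the same continent" phrasing) and redundant tonnage.
  Countries missing from the region map get `NA` flags and leave the
  fraction denominators, with a warning.
* **Global share.** Both `redundant / total` and `redundant /
  species-level` shares are reported; which denominator a headline share
  should use depends on whether the reader wants coverage of all trade or
  of the analyzable trade.
* **Regressions.** Redundant exports are regressed on total exports and on
  the species-level reporting fraction with plain untransformed OLS — the
  standard diagnostic pair for "big exporters have more redundancy" and
  "better reporters appear more redundant". A constant response returns
  $R^2 = 0$ by definition rather than the 0/0 numerical noise `summary.lm`
  would produce.
* **Determinism.** Every ranking has an explicit tie-break (pair key,
  species name, country code); re-running on identical inputs produces
  byte-identical output files.

## The synthetic generator: what it emulates and what it does not

Real global seafood trade databases are proprietary, so verification rests
on a seeded generator whose *ground truth is exact by construction*:

* Sparse directed flows: each (pair, species, year) cell trades with
  probability `edge_density` (default 0.02 — most pairs do not trade a
  given species at all).
* A planted two-way fraction: a trading cell is matched in both directions
  with probability `two_way_fraction` (default 0.2); otherwise the
  direction is a fair coin.
* Heavy-tailed volumes: log-normal (default meanlog $\log 100$, sdlog 1.5),
  the standard positive heavy-tailed choice; the source data's true volume
  law is unknown, so the parameters are exposed rather than defended.
* Contaminants injected as *additional* rows, never replacing clean rows:
  aquaculture (rate 0.30), re-exports (0.15), coarse taxa (0.45 — chosen
  because roughly half of real wild-capture trade tonnage is not resolved
  to species level), unknown method (0.02). Each carries its expected
  filter bucket in the ground truth, so filter accounting is checkable
  exactly, not statistically.
* IUCN categories sampled with Least Concern most common and ~39% of
  species Data Deficient or Not Assessed, the typical profile of
  commercially traded marine taxa.
* Default years 2000:2015; default 40 countries × 60 species keeps the
  default generation desk-scale (the packaged pools hold 120 ISO codes and
  90 binomials for larger runs).

Draw order is fixed and documented (cell-trading uniforms in canonical cell
order, then two-way uniforms, direction uniforms, volumes, contaminants),
so a config is a pure function to a dataset — same seed, byte-identical
files. One limitation accepted knowingly: draws are order-keyed, not
content-keyed, so *extending the generator's schema* in a future version
could reshuffle draws for old seeds; within any released version
reproducibility is exact.

What a green end-to-end test establishes: the pipeline inverts the
generator exactly — filters remove precisely the tagged contaminants and
the matched-minimum computation reproduces the planted two-way cells. What
it does not establish: agreement with any real database's marginals,
seasonality, country/species heterogeneity in reporting quality, or
re-export chain resolution. Headline figures from the real proprietary
data are therefore out of reach by design; the in-text worked example
(10 t / 5 t → 10 t redundant) is the only externally anchored number, and
it is exact.

## Numerical choices

* Volumes are doubles throughout. `min` and `×2` are exact floating-point
  operations, so flow-level tests assert exact equality; sums are asserted
  at 1e-9 relative tolerance (conservation invariants) or bit-exactly where
  both sides provably accumulate in the same order.
* CSVs that feed exact-equality pipelines are written with 17 significant
  digits; 15 (the `fwrite` default) does not round-trip a double.
* Degenerate inputs are explicit: zero-total scopes return `NA` with a
  warning (`species_level_fraction`, `percent_change` at zero baseline),
  empty share vectors and <3-country regressions are errors, an empty
  retained set is a warning plus zeroed outputs and a status flag, not a
  crash.

## Worked example

```{r worked}
worked <- data.frame(
  year = 2000L,
  exporter_iso3 = c("CAN", "USA"), importer_iso3 = c("USA", "CAN"),
  taxon_name = "Gadus morhua", production_method = "capture",
  is_reexport = FALSE, tonnes = c(10, 5)
)
trade <- as_trade_records(worked)
flows <- compute_redundant_flows(apply_filters(trade)$records)
flows[, .(country_a, country_b, export_ab, export_ba, redundant_tonnes)]
sum(flows$redundant_tonnes)   # 10 tonnes redundant in total
avoided_exports(10, 5)        # 5 tonnes avoidable per country
```

## Known limitations

* Annual, species-level matching only — no seasonal or product-form
  resolution (a granularity limitation of the field's data, inherited
  deliberately).
* Re-export chains are not resolved; the input flag is trusted.
* Country harmonization is the caller's responsibility beyond requiring
  ISO 3166-1 alpha-3 codes; there is no fuzzy name matching.
* The generator does not mimic real-world country or species marginals;
  statistical realism claims end at sparsity, heavy tails and the planted
  redundancy fraction.
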