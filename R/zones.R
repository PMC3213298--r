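#' Homology-zone threshold tables
#'
#' The Safe / Twilight 1 / Twilight 2 / Dark zone boundaries used to decide
#' whether a template's alignment is similar enough for interface transfer.
#' Thresholds were calibrated on transient dimer complexes and are
#' intentionally conservative; they can be relaxed (e.g. for obligate
#' queries) by editing the returned tibble or loading an alternative with
#' [read_zone_config()].
#'
#' All comparisons are inclusive: a hit is in a zone when
#' `log_eval <= max_log_eval` and every other statistic is `>=` its minimum.
#' `min_positive` is on the 0-100 percent scale; the partner-specific
#' fraction minima are percent thresholds compared against
#' `100 * frac_aa` / `100 * frac_bb`.
#'
#' @return A tibble with one row per zone, strictest first.
#' @export
nps_zones <- function() {
  tibble(
    zone = zone_levels(),
    max_log_eval = c(-100, -50, 1, 1),
    min_positive = c(80, 65, 60, 0),
    min_log_lal = c(5.2, 4, 4, 0)
  )
}

#' @rdname nps_zones
#' @export
ps_zones <- function() {
  tibble(
    zone = zone_levels(),
    max_log_eval = c(-100, -50, 1, 1),
    min_positive = c(70, 60, 55, 0),
    min_frac_aa = c(80, 60, 40, 0),
    min_frac_bb = c(80, 60, 40, 0)
  )
}

# first (strictest) zone whose conditions all hold; NA when none do.
# conds: list of logical matrices [hit x zone]
.first_zone <- function(zones, conds) {
  ok <- Reduce(`&`, conds)
  idx <- apply(ok, 1L, function(row) {
    i <- which(row)
    if (length(i) == 0) NA_integer_ else i[1L]
  })
  factor(zones$zone[idx], levels = zone_levels())
}

#' Classify hits into homology zones
#'
#' Adds a `zone` column (ordered factor `Safe > Twilight1 > Twilight2 >
#' Dark`, `NA` when no zone admits the hit) by matching each hit against the
#' zone table, strictest zone first. `classify_zone_nps()` uses the
#' non-partner-specific statistics (`log_eval`, `positive_score`,
#' `log_lal`); `classify_zone_ps()` uses the pair statistics
#' (`avg_log_eval`, `avg_positive`, `frac_aa`, `frac_bb`, the fractions on
#' the 0-1 scale).
#'
#' Hits that satisfy no row — in particular those with
#' `log_eval` above the Dark-zone ceiling of 1 but still below the BLASTP
#' search cutoff `ln(10)` — get `NA` and never contribute to predictions.
#'
#' @param stats Tibble of hits carrying the statistic columns.
#' @param zones Zone table, default [nps_zones()] / [ps_zones()].
#' @return `stats` with a `zone` factor column appended.
#' @export
classify_zone_nps <- function(stats, zones = nps_zones()) {
  conds <- list(
    outer(stats$log_eval, zones$max_log_eval, `<=`),
    outer(stats$positive_score, zones$min_positive, `>=`),
    outer(stats$log_lal, zones$min_log_lal, `>=`)
  )
  dplyr::mutate(stats, zone = .first_zone(zones, conds))
}

#' @rdname classify_zone_nps
#' @export
classify_zone_ps <- function(stats, zones = ps_zones()) {
  conds <- list(
    outer(stats$avg_log_eval, zones$max_log_eval, `<=`),
    outer(stats$avg_positive, zones$min_positive, `>=`),
    outer(100 * stats$frac_aa, zones$min_frac_aa, `>=`),
    outer(100 * stats$frac_bb, zones$min_frac_bb, `>=`)
  )
  dplyr::mutate(stats, zone = .first_zone(zones, conds))
}

#' Load and save zone threshold tables
#'
#' Zone tables are stored as YAML, one mapping per zone in strictness order,
#' e.g. `- {zone: Safe, max_log_eval: -100, min_positive: 80, min_log_lal:
#' 5.2}`. Useful for relaxing thresholds for obligate queries without
#' touching code.
#'
#' @param path YAML file path.
#' @return `read_zone_config()`: a zone tibble; `write_zone_config()`:
#'   `path`, invisibly.
#' @export
read_zone_config <- function(path) {
  rows <- yaml::read_yaml(path)
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  if (!all(out$zone %in% zone_levels())) {
    abort("zone config contains unknown zone names", class = "homint_config_error")
  }
  out
}

#' @rdname read_zone_config
#' @param zones Zone tibble to serialize.
#' @export
write_zone_config <- function(zones, path) {
  yaml::write_yaml(purrr::transpose(as.list(zones)), path)
  invisible(path)
}
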