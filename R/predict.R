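# ---- shared voting machinery -------------------------------------------

# column-by-column projection of one BLAST local alignment:
# returns (q_pos, t_pos) for columns where both sequences have a residue
project_alignment <- function(q_aln, t_aln, q_start, t_start) {
  qc <- strsplit(q_aln, "")[[1]]
  tc <- strsplit(t_aln, "")[[1]]
  qpos <- q_start - 1L + cumsum(qc != "-")
  tpos <- t_start - 1L + cumsum(tc != "-")
  both <- qc != "-" & tc != "-"
  tibble(q_pos = qpos[both], t_pos = tpos[both])
}

# majority vote over selected templates. `selected` carries one alignment
# per template; `label_of(row)` returns that template's label track as a
# character vector indexed by template position ("0"/"1"/"?", NA outside).
tally_votes <- function(query_len, selected, label_of) {
  pos_votes <- integer(query_len)
  neg_votes <- integer(query_len)
  for (i in seq_len(nrow(selected))) {
    row <- selected[i, , drop = FALSE]
    track <- label_of(row)
    map <- project_alignment(row$q_aln, row$t_aln, row$q_start, row$t_start)
    map <- map[map$q_pos >= 1 & map$q_pos <= query_len, , drop = FALSE]
    lab <- rep(NA_character_, nrow(map))
    in_track <- map$t_pos >= 1 & map$t_pos <= length(track)
    lab[in_track] <- track[map$t_pos[in_track]]
    up <- map$q_pos[!is.na(lab) & lab == "1"]
    dn <- map$q_pos[!is.na(lab) & lab == "0"]
    pos_votes[up] <- pos_votes[up] + 1L
    neg_votes[dn] <- neg_votes[dn] + 1L
  }
  n_votes <- pos_votes + neg_votes
  score <- ifelse(n_votes > 0, pos_votes / n_votes, NA_real_)
  tibble(
    pos = seq_len(query_len),
    vote_score = score,
    n_votes = n_votes,
    call = as.integer(!is.na(score) & score >= 0.5)
  )
}

new_prediction <- function(query_id, query_len, votes = NULL, query_aa = NULL,
                           zone = NA_character_, templates = character(),
                           predicted = TRUE) {
  if (is.null(votes)) {
    votes <- tibble(pos = seq_len(query_len), vote_score = NA_real_,
                    n_votes = 0L, call = NA_integer_)
    predicted <- FALSE
  }
  votes$aa <- if (is.null(query_aa)) NA_character_ else query_aa[votes$pos]
  votes <- votes[, c("pos", "aa", "vote_score", "n_votes", "call")]
  structure(list(positions = votes, query_id = query_id, zone = zone,
                 templates = templates, predicted = predicted),
            class = "ppi_prediction")
}

#' @export
print.ppi_prediction <- function(x, ...) {
  if (!x$predicted) {
    cat(sprintf("<ppi_prediction %s: no usable templates — not predicted>\n", x$query_id))
    return(invisible(x))
  }
  cat(sprintf("<ppi_prediction %s: zone %s, %d template(s), %d/%d residues called>\n",
              x$query_id, x$zone, length(x$templates),
              sum(x$positions$call == 1, na.rm = TRUE), nrow(x$positions)))
  print(x$positions)
  invisible(x)
}

#' Tidy accessors for interface predictions
#'
#' `tidy()` returns the per-position table (`query_id`, `pos`, `aa`,
#' `vote_score`, `n_votes`, `call`); `glance()` a one-row summary.
#'
#' @param x A `ppi_prediction`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ppi_prediction <- function(x, ...) {
  dplyr::mutate(x$positions, query_id = x$query_id, .before = 1)
}

#' @rdname tidy.ppi_prediction
#' @export
glance.ppi_prediction <- function(x, ...) {
  tibble(
    query_id = x$query_id,
    predicted = x$predicted,
    zone = x$zone,
    n_templates = length(x$templates),
    n_positions = nrow(x$positions),
    n_called = sum(x$positions$call == 1, na.rm = TRUE),
    n_no_vote = sum(x$positions$n_votes == 0)
  )
}

#' Extract binary interface calls as a label track
#'
#' @param pred A `ppi_prediction`.
#' @return Character vector over query positions: `"1"`/`"0"`, or `NA` when
#'   the query was not predicted.
#' @export
prediction_labels <- function(pred) {
  if (!pred$predicted) return(rep(NA_character_, nrow(pred$positions)))
  as.character(pred$positions$call)
}

# ---- non-partner-specific predictor ------------------------------------

#' Remove untrustworthy or evaluation-biasing homologs
#'
#' Drops, with a logged reason: self hits (template sequence identical to
#' the query), templates sharing at least 95% alignment identity with the
#' query *and* coming from the same species (identity alone is not enough —
#' distinct-species near-identical templates are legitimate), and templates
#' failing the structural retention rules of [filter_templates()]
#' (non-X-ray, resolution above 3.5 Angstrom, fewer than 3 interface
#' residues).
#'
#' @param hits Alignment record tibble for one query (statistics added on
#'   the fly when absent).
#' @param query_seq Query amino-acid sequence.
#' @param query_species Query species tag (`NA` disables the species rule).
#' @param templates Template chain metadata (`chain`, `sequence`,
#'   `species`, `method`, `resolution`).
#' @param labels Template label tibble (`chain`, `pos`, `aa`, `label`).
#' @return Filtered hits; removals recorded in the `"removed"` attribute
#'   (tibble `template_id`, `reason`).
#' @export
filter_homologs <- function(hits, query_seq, query_species, templates, labels) {
  if (!"identity_score" %in% names(hits)) hits <- alignment_stats(hits)
  meta <- templates[match(hits$template_id, templates$chain), , drop = FALSE]
  tmpl_ok <- filter_templates(templates, labels)
  keep_struct <- tmpl_ok$keep[match(hits$template_id, tmpl_ok$chain)]
  struct_reason <- tmpl_ok$reason[match(hits$template_id, tmpl_ok$chain)]
  reason <- dplyr::case_when(
    !is.na(meta$sequence) & meta$sequence == query_seq ~ "self",
    hits$identity_score >= 95 & !is.na(query_species) &
      !is.na(meta$species) & meta$species == query_species ~ "identity_species",
    !keep_struct ~ struct_reason,
    TRUE ~ NA_character_
  )
  removed <- tibble(template_id = hits$template_id[!is.na(reason)],
                    reason = reason[!is.na(reason)])
  out <- hits[is.na(reason), , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Non-partner-specific interface prediction by homology transfer
#'
#' Implements the zone-cascaded majority-vote predictor: (1) classify every
#' hit into a homology zone and use the strictest zone that has any hit
#' (Safe, else Twilight 1, else Twilight 2, else Dark; no zone at all means
#' no prediction); (2) keep one alignment per template (the HSP with the
#' best predicted IC) and select the at most `k` templates with the highest
#' predicted interface conservation; (3) at every query position covered by
#' a template alignment, the aligned template residue votes for (`"1"`) or
#' against (`"0"`) interface status, abstaining on `"?"` (unresolved
#' template coordinates) and on gap columns; (4) the vote score is positive
#' votes over votes cast, and a residue is called an interface residue when
#' its score is at least 0.5. Positions no template covers get call 0 with
#' `n_votes = 0` so they remain identifiable.
#'
#' @param query_id Query identifier.
#' @param query_seq Query sequence (used for length and residue letters).
#' @param hits Alignment records for the query, already passed through
#'   [filter_homologs()].
#' @param labels Template label tibble (`chain`, `pos`, `aa`, `label`).
#' @param model Ranking model, default the shipped NPS [ic_model()].
#' @param zones Zone table, default [nps_zones()].
#' @param k Maximum number of templates used.
#' @return A `ppi_prediction`.
#' @export
predict_nps <- function(query_id, query_seq, hits, labels,
                        model = ic_model("nps"), zones = nps_zones(), k = 10) {
  query_aa <- strsplit(query_seq, "")[[1]]
  query_len <- length(query_aa)
  not_pred <- function() new_prediction(query_id, query_len, NULL, query_aa)
  if (nrow(hits) == 0) return(not_pred())
  if (!"log_eval" %in% names(hits)) hits <- alignment_stats(hits)
  hits <- classify_zone_nps(hits, zones)
  hits <- hits[!is.na(hits$zone), , drop = FALSE]
  if (nrow(hits) == 0) return(not_pred())
  zone_used <- zone_levels()[min(as.integer(hits$zone))]
  pool <- hits[hits$zone == zone_used, , drop = FALSE]
  pool <- dplyr::mutate(pool, predicted_ic = predict_ic(model, pool))
  # one vote per template: keep each template's best HSP
  pool <- pool |>
    dplyr::arrange(dplyr::desc(.data$predicted_ic), .data$eval) |>
    dplyr::distinct(.data$template_id, .keep_all = TRUE)
  selected <- rank_templates(pool, model, k)
  votes <- tally_votes(query_len, selected, function(row) {
    track_for_chain(labels, row$template_id)
  })
  new_prediction(query_id, query_len, votes, query_aa,
                 zone = zone_used, templates = selected$template_id)
}

# label tibble -> character track for one chain (NA-padded to max pos)
track_for_chain <- function(labels, chain_id, partner_id = NULL, complex_id = NULL) {
  rows <- labels[labels$chain == chain_id, , drop = FALSE]
  if (!is.null(partner_id)) rows <- rows[rows$partner == partner_id, , drop = FALSE]
  if (!is.null(complex_id)) rows <- rows[rows$complex_id == complex_id, , drop = FALSE]
  if (nrow(rows) == 0) return(character(0))
  track <- rep(NA_character_, max(rows$pos))
  track[rows$pos] <- rows$label
  track
}

# ---- partner-specific predictor ----------------------------------------

#' Find homo-interologs of a query protein pair
#'
#' For queries A and B, a homo-interolog is a pair (A', B') where A' is a
#' BLAST hit of A, B' a hit of B, and A' and B' interact within one solved
#' complex. Pairs are excluded, with a logged reason, when: the complex is
#' the query's own (`same_complex`), either chain is near-identical to its
#' query (at least 95% alignment identity and the same species;
#' `identity_species`), or the complex resolution is worse than 3.5
#' Angstrom (`resolution`).
#'
#' @param hits_a,hits_b Alignment record tibbles for A and B.
#' @param complex_index Tibble of interacting template chain pairs
#'   (`complex_id`, `chain_a`, `chain_b`); chains co-resident in a complex
#'   but not in contact simply have no row.
#' @param templates Template chain metadata (`chain`, `sequence`,
#'   `species`, `method`, `resolution`).
#' @param query_species Length-2 character vector (species of A and B), or
#'   `NA`.
#' @param query_complex Complex id of the query pair itself, or `NA`.
#' @param max_resolution Resolution ceiling in Angstrom.
#' @param frac_combine How Frac_AA' combines the two per-chain alignment
#'   fractions: their product (default) or their minimum.
#' @return Tibble with one row per candidate interolog HSP pair: alignment
#'   fields prefixed `a_`/`b_`, the pair statistics of [ps_pair_stats()],
#'   and bookkeeping columns `complex_id`, `template_a`, `template_b`,
#'   `template_id`, `eval`. Exclusions are recorded in the `"removed"`
#'   attribute.
#' @export
find_interologs <- function(hits_a, hits_b, complex_index, templates,
                            query_species = c(NA, NA), query_complex = NA,
                            max_resolution = 3.5,
                            frac_combine = c("product", "min")) {
  frac_combine <- match.arg(frac_combine)
  empty <- function() {
    out <- tibble(complex_id = character(), template_a = character(),
                  template_b = character(), template_id = character(),
                  eval = numeric())
    attr(out, "removed") <- tibble(complex_id = character(), template_a = character(),
                                   template_b = character(), reason = character())
    out
  }
  if (nrow(hits_a) == 0 || nrow(hits_b) == 0) return(empty())
  if (!"log_eval" %in% names(hits_a)) hits_a <- alignment_stats(hits_a)
  if (!"log_eval" %in% names(hits_b)) hits_b <- alignment_stats(hits_b)
  # undirected index: accept either orientation of the stored pair
  idx <- dplyr::bind_rows(
    complex_index,
    dplyr::rename(complex_index, chain_a = "chain_b", chain_b = "chain_a")
  ) |> dplyr::distinct()
  pa <- dplyr::rename_with(hits_a, ~ paste0("a_", .x))
  pb <- dplyr::rename_with(hits_b, ~ paste0("b_", .x))
  cand <- idx |>
    dplyr::inner_join(pa, by = c(chain_a = "a_template_id"), relationship = "many-to-many") |>
    dplyr::inner_join(pb, by = c(chain_b = "b_template_id"), relationship = "many-to-many") |>
    dplyr::rename(template_a = "chain_a", template_b = "chain_b")
  if (nrow(cand) == 0) return(empty())
  res_a <- templates$resolution[match(cand$template_a, templates$chain)]
  res_b <- templates$resolution[match(cand$template_b, templates$chain)]
  spec_a <- templates$species[match(cand$template_a, templates$chain)]
  spec_b <- templates$species[match(cand$template_b, templates$chain)]
  near <- function(ident, spec, qspec) {
    ident >= 95 & !is.na(qspec) & !is.na(spec) & spec == qspec
  }
  reason <- dplyr::case_when(
    !is.na(query_complex) & cand$complex_id == query_complex ~ "same_complex",
    near(cand$a_identity_score, spec_a, query_species[1]) |
      near(cand$b_identity_score, spec_b, query_species[2]) ~ "identity_species",
    is.na(res_a) | is.na(res_b) |
      pmax(res_a, res_b) > max_resolution ~ "resolution",
    TRUE ~ NA_character_
  )
  removed <- tibble(complex_id = cand$complex_id, template_a = cand$template_a,
                    template_b = cand$template_b, reason = reason)[!is.na(reason), ]
  out <- cand[is.na(reason), , drop = FALSE]
  out <- ps_pair_stats(out, frac_combine = frac_combine)
  out <- dplyr::mutate(out,
    template_id = paste(.data$complex_id, .data$template_a, .data$template_b, sep = "/"),
    eval = (.data$a_eval + .data$b_eval) / 2
  )
  attr(out, "removed") <- removed
  out
}

#' Pair-level alignment statistics for homo-interologs
#'
#' Combines the two chain alignments of an interolog into the statistics
#' the PS zones and the PS interface-conservation model consume:
#' `avg_log_eval` and `avg_positive` are arithmetic means of the per-chain
#' values (each chain's `log_eval` already floored at -450 for zero
#' expectation values); `frac_aa` combines the query-side and template-side
#' alignment fractions of the A chain, `(lal / len_A) * (lal / len_A')` by
#' default (`min` of the two as a documented alternative); `frac_bb`
#' likewise; `avg_log_lal` is reported for completeness but unused by the
#' PS model.
#'
#' @param pairs Tibble with `a_`/`b_`-prefixed alignment statistic columns.
#' @param frac_combine `"product"` or `"min"`.
#' @return `pairs` with `avg_log_eval`, `avg_positive`, `frac_aa`,
#'   `frac_bb`, `avg_log_lal` appended.
#' @export
ps_pair_stats <- function(pairs, frac_combine = c("product", "min")) {
  frac_combine <- match.arg(frac_combine)
  comb <- if (frac_combine == "product") `*` else pmin
  dplyr::mutate(pairs,
    avg_log_eval = (.data$a_log_eval + .data$b_log_eval) / 2,
    avg_positive = (.data$a_positive_score + .data$b_positive_score) / 2,
    frac_aa = comb(.data$a_lal / .data$a_query_len, .data$a_lal / .data$a_template_len),
    frac_bb = comb(.data$b_lal / .data$b_query_len, .data$b_lal / .data$b_template_len),
    avg_log_lal = (.data$a_log_lal + .data$b_log_lal) / 2
  )
}

#' Partner-specific interface prediction from homo-interologs
#'
#' Predicts the interface of query A with its specific partner B (and
#' symmetrically of B with A) by majority vote over the partner-specific
#' interface labels of the at most `k` closest homo-interologs. Only Safe
#' and Twilight zone interologs are ever used: the cascade is Safe, else
#' Twilight 1, else Twilight 2; with interologs at best in the Dark zone
#' (or none), no prediction is made. Ranking uses the PS
#' interface-conservation model; voting and the 0.5 call rule are exactly
#' as in [predict_nps()].
#'
#' @param query_a,query_b Lists with `id` and `seq` describing the queries.
#' @param interologs Tibble from [find_interologs()].
#' @param ps_labels Partner-specific label tibble (`complex_id`, `chain`,
#'   `partner`, `pos`, `aa`, `label`): the labels of `chain` against
#'   `partner` only.
#' @param model PS ranking model, default the shipped PS [ic_model()].
#' @param zones Zone table, default [ps_zones()].
#' @param k Maximum number of interologs used.
#' @return Named list of two `ppi_prediction`s (`a`, `b`).
#' @export
predict_ps <- function(query_a, query_b, interologs, ps_labels,
                       model = ic_model("ps"), zones = ps_zones(), k = 10) {
  aa_a <- strsplit(query_a$seq, "")[[1]]
  aa_b <- strsplit(query_b$seq, "")[[1]]
  not_pred <- function() list(
    a = new_prediction(query_a$id, length(aa_a), NULL, aa_a),
    b = new_prediction(query_b$id, length(aa_b), NULL, aa_b)
  )
  if (nrow(interologs) == 0) return(not_pred())
  pairs <- classify_zone_ps(interologs, zones)
  usable <- pairs[!is.na(pairs$zone) & pairs$zone != "Dark", , drop = FALSE]
  if (nrow(usable) == 0) return(not_pred())
  zone_used <- zone_levels()[min(as.integer(usable$zone))]
  pool <- usable[usable$zone == zone_used, , drop = FALSE]
  pool <- dplyr::mutate(pool, predicted_ic = predict_ic(model, pool))
  pool <- pool |>
    dplyr::arrange(dplyr::desc(.data$predicted_ic), .data$eval) |>
    dplyr::distinct(.data$template_id, .keep_all = TRUE)
  selected <- rank_templates(pool, model, k)
  vote_side <- function(prefix, other_prefix, query_aa) {
    side <- selected
    names(side) <- sub(paste0("^", prefix, "_"), "", names(side))
    tally_votes(length(query_aa), side, function(row) {
      track_for_chain(ps_labels,
                      chain_id = row[[paste0("template_", substr(prefix, 1, 1))]],
                      partner_id = row[[paste0("template_", substr(other_prefix, 1, 1))]],
                      complex_id = row$complex_id)
    })
  }
  list(
    a = new_prediction(query_a$id, length(aa_a), vote_side("a", "b", aa_a), aa_a,
                       zone = zone_used, templates = selected$template_id),
    b = new_prediction(query_b$id, length(aa_b), vote_side("b", "a", aa_b), aa_b,
                       zone = zone_used, templates = selected$template_id)
  )
}
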