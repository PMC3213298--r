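# shared fixture builders, all generated in code

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_sequence_for_test <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# independent oracle: the Matthews coefficient is the Pearson correlation of
# the binary prediction/truth vectors
cor_mcc <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  suppressWarnings(stats::cor(pred, truth))
}

# alignment record with sensible defaults; override any field
make_record <- function(query_id = "Q", template_id = "T", eval = 1e-60,
                        q_aln = NULL, t_aln = NULL, query_len = NULL,
                        template_len = NULL, n_identical = NULL,
                        n_positive = NULL, q_start = 1L, t_start = 1L,
                        lal = NULL) {
  if (is.null(q_aln)) q_aln <- strrep("A", 60)
  if (is.null(t_aln)) t_aln <- q_aln
  lal <- lal %||% nchar(q_aln)
  nres <- function(s) nchar(gsub("-", "", s))
  if (is.null(n_identical)) {
    qc <- strsplit(q_aln, "")[[1]]; tc <- strsplit(t_aln, "")[[1]]
    n_identical <- sum(qc == tc & qc != "-")
  }
  n_positive <- n_positive %||% n_identical
  tibble::tibble(
    query_id = query_id, template_id = template_id, eval = eval, lal = lal,
    n_identical = n_identical, n_positive = n_positive,
    query_len = query_len %||% nres(q_aln),
    template_len = template_len %||% nres(t_aln),
    q_start = q_start, q_end = q_start + nres(q_aln) - 1L,
    t_start = t_start, t_end = t_start + nres(t_aln) - 1L,
    q_aln = q_aln, t_aln = t_aln
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two 5-residue single-atom-per-residue chains; residue 3 of each chain
# faces the other at distance `gap`, every other inter-chain pair is far
two_chain_fixture <- function(gap = 3.5) {
  mk <- function(chain, ybase, flip) {
    tibble::tibble(
      chain = chain, resno = 1:5, aa = c("A", "G", "L", "S", "V"),
      atom = "CA", element = "C",
      x = c(0, 8, 16, 24, 32),
      y = ifelse(1:5 == 3, ybase + flip * 0, ybase + flip * 20),
      z = 0
    )
  }
  atoms <- dplyr::bind_rows(mk("A", 0, -1), mk("B", gap, 1))
  chains <- tibble::tibble(
    chain = c("A", "B"), sequence = c("AGLSV", "AGLSV"),
    species = c("E.coli", "B.subtilis"), method = "xray", resolution = 2.0
  )
  ppi_complex(atoms, chains)
}

# independent O(n^2) contact labelling oracle (no spatial grid)
brute_force_labels <- function(cx, dist_cutoff = 4.0, rasa_cutoff = 0.05,
                               n_points = 240) {
  rasa <- relative_asa(cx, n_points = n_points)
  out <- list()
  for (cid in cx$chains$chain) {
    partners <- setdiff(cx$chains$chain, cid)
    mine <- cx$atoms[cx$atoms$chain == cid, ]
    other <- cx$atoms[cx$atoms$chain %in% partners, ]
    track <- rasa[rasa$chain == cid, ]
    lab <- character(nrow(track))
    for (p in track$pos) {
      ma <- mine[mine$resno == p, ]
      if (nrow(ma) == 0) { lab[p] <- "?"; next }
      dmin <- Inf
      for (i in seq_len(nrow(ma))) for (j in seq_len(nrow(other))) {
        d <- sqrt((ma$x[i] - other$x[j])^2 + (ma$y[i] - other$y[j])^2 +
                    (ma$z[i] - other$z[j])^2)
        if (d < dmin) dmin <- d
      }
      r <- track$rasa[track$pos == p]
      lab[p] <- if (dmin <= dist_cutoff && !is.na(r) && r >= rasa_cutoff) "1" else "0"
    }
    out[[cid]] <- tibble::tibble(chain = cid, pos = track$pos, aa = track$aa,
                                 label = lab)
  }
  dplyr::bind_rows(out)
}

# exhaustive per-position vote recount, independent of tally_votes
recount_votes <- function(query_len, selected, labels) {
  pos_votes <- integer(query_len); neg_votes <- integer(query_len)
  for (i in seq_len(nrow(selected))) {
    row <- selected[i, ]
    qc <- strsplit(row$q_aln, "")[[1]]
    tc <- strsplit(row$t_aln, "")[[1]]
    qp <- row$q_start - 1L; tp <- row$t_start - 1L
    track <- labels$label[labels$chain == row$template_id][order(labels$pos[labels$chain == row$template_id])]
    tpos <- sort(labels$pos[labels$chain == row$template_id])
    for (k in seq_along(qc)) {
      if (qc[k] != "-") qp <- qp + 1L
      if (tc[k] != "-") tp <- tp + 1L
      if (qc[k] == "-" || tc[k] == "-") next
      if (qp < 1 || qp > query_len) next
      lab <- track[match(tp, tpos)]
      if (is.na(lab) || lab == "?") next
      if (lab == "1") pos_votes[qp] <- pos_votes[qp] + 1L
      if (lab == "0") neg_votes[qp] <- neg_votes[qp] + 1L
    }
  }
  n <- pos_votes + neg_votes
  tibble::tibble(
    pos = seq_len(query_len),
    vote_score = ifelse(n > 0, pos_votes / n, NA_real_),
    n_votes = n,
    call = as.integer(!is.na(pos_votes / pmax(n, 1)) & n > 0 & pos_votes / n >= 0.5)
  )
}

# literal transcription of the zone tables as nested conditionals,
# kept deliberately independent of the vectorised classifier
nps_zone_oracle <- function(log_eval, positive, log_lal) {
  if (log_eval <= -100 && positive >= 80 && log_lal >= 5.2) return("Safe")
  if (log_eval <= -50 && positive >= 65 && log_lal >= 4) return("Twilight1")
  if (log_eval <= 1 && positive >= 60 && log_lal >= 4) return("Twilight2")
  if (log_eval <= 1 && positive >= 0 && log_lal >= 0) return("Dark")
  NA_character_
}

ps_zone_oracle <- function(log_eval, positive, frac_aa_pct, frac_bb_pct) {
  if (log_eval <= -100 && positive >= 70 && frac_aa_pct >= 80 && frac_bb_pct >= 80) return("Safe")
  if (log_eval <= -50 && positive >= 60 && frac_aa_pct >= 60 && frac_bb_pct >= 60) return("Twilight1")
  if (log_eval <= 1 && positive >= 55 && frac_aa_pct >= 40 && frac_bb_pct >= 40) return("Twilight2")
  if (log_eval <= 1) return("Dark")
  NA_character_
}

# random small template voting case for the recount oracle
random_vote_case <- function(n_templates = NULL, query_len = NULL) {
  query_len <- query_len %||% sample(10:30, 1)
  n_templates <- n_templates %||% sample(1:5, 1)
  sel <- list(); labs <- list()
  for (t in seq_len(n_templates)) {
    tid <- paste0("T", t)
    tlen <- sample(8:30, 1)
    # random gapped alignment over a random query window
    ncol <- sample(5:min(query_len, tlen), 1)
    qc <- sample(c(letters, "-"), ncol, replace = TRUE, prob = c(rep(1, 26), 6))
    tc <- sample(c(letters, "-"), ncol, replace = TRUE, prob = c(rep(1, 26), 6))
    both_gap <- qc == "-" & tc == "-"
    qc[both_gap] <- "a"
    nq <- sum(qc != "-"); nt <- sum(tc != "-")
    if (nq == 0) { qc[1] <- "a"; nq <- sum(qc != "-") }
    if (nt == 0) { tc[1] <- "a"; nt <- sum(tc != "-") }
    q_start <- sample(seq_len(max(1, query_len - nq + 1)), 1)
    t_start <- sample(seq_len(max(1, tlen - nt + 1)), 1)
    sel[[t]] <- tibble::tibble(
      template_id = tid,
      q_aln = paste(toupper(qc), collapse = ""),
      t_aln = paste(toupper(tc), collapse = ""),
      q_start = q_start, t_start = t_start
    )
    labs[[t]] <- tibble::tibble(
      chain = tid, pos = seq_len(tlen),
      aa = sample(c("A", "G"), tlen, replace = TRUE),
      label = sample(c("0", "1", "?"), tlen, replace = TRUE, prob = c(5, 3, 2))
    )
  }
  list(query_len = query_len, selected = dplyr::bind_rows(sel),
       labels = dplyr::bind_rows(labs))
}
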