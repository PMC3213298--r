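# small deterministic template set: identical sequences, labels set by hand
vote_fixture <- function(tracks, query_len = 10) {
  seqs <- strrep("A", query_len)
  hits <- purrr::map_dfr(seq_along(tracks), function(i) {
    make_record(template_id = paste0("T", i), eval = 1e-60,
                q_aln = seqs, t_aln = seqs)
  })
  labels <- purrr::map_dfr(seq_along(tracks), function(i) {
    tibble::tibble(chain = paste0("T", i), pos = seq_len(query_len),
                   aa = "A", label = tracks[[i]])
  })
  list(query_seq = seqs, hits = alignment_stats(hits), labels = labels)
}

track_const <- function(ch, n = 10) rep(ch, n)

test_that("homolog filtering removes self, same-species near-identical and bad templates", {
  qseq <- strrep("M", 60)
  hits <- dplyr::bind_rows(
    make_record(template_id = "self", q_aln = qseq, t_aln = qseq),
    make_record(template_id = "near_same_sp", q_aln = qseq,
                t_aln = paste0(strrep("M", 58), "AA"), n_identical = 58L,
                n_positive = 58L),
    make_record(template_id = "near_diff_sp", q_aln = qseq,
                t_aln = paste0(strrep("M", 58), "AA"), n_identical = 58L,
                n_positive = 58L),
    make_record(template_id = "nmr_tmpl", q_aln = qseq,
                t_aln = paste0(strrep("M", 40), strrep("A", 20)),
                n_identical = 40L, n_positive = 40L)
  )
  templates <- tibble::tibble(
    chain = c("self", "near_same_sp", "near_diff_sp", "nmr_tmpl"),
    sequence = c(qseq, paste0(strrep("M", 58), "AA"),
                 paste0(strrep("M", 58), "AA"),
                 paste0(strrep("M", 40), strrep("A", 20))),
    species = c("H.sapiens", "H.sapiens", "E.coli", "E.coli"),
    method = c("xray", "xray", "xray", "nmr"),
    resolution = c(2, 2, 2, NA)
  )
  labels <- purrr::map_dfr(templates$chain, function(ch) {
    tibble::tibble(chain = ch, pos = 1:60, aa = "M",
                   label = c(rep("1", 5), rep("0", 55)))
  })
  kept <- filter_homologs(hits, qseq, "H.sapiens", templates, labels)
  expect_equal(kept$template_id, "near_diff_sp")
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$template_id == "self"], "self")
  expect_equal(removed$reason[removed$template_id == "near_same_sp"], "identity_species")
  expect_equal(removed$reason[removed$template_id == "nmr_tmpl"], "method")
})

test_that("a single template transfers its labels through the alignment", {
  set.seed(5)
  qseq <- random_sequence_for_test(40)
  qlab <- c(rep("0", 10), rep("1", 6), rep("0", 24))
  tm <- mutate_homolog(qseq, qlab, sub_rate = 0, template_id = "T1")
  fx <- list(hits = alignment_stats(tm$record), labels = tm$labels)
  pred <- predict_nps("Q", qseq, fx$hits, fx$labels)
  expect_true(pred$predicted)
  expect_equal(prediction_labels(pred), qlab)
  expect_equal(ic_score(prediction_labels(pred), qlab), 1)
})

test_that("majority voting follows the at-least-half rule with abstention on '?'", {
  fx <- vote_fixture(list(
    c("1", "1", "0", "?", "1", "0", "0", "1", "?", "0"),
    c("1", "0", "0", "?", "1", "0", "1", "1", "?", "0"),
    c("0", "1", "0", "?", "?", "0", "1", "0", "?", "1")
  ))
  pred <- predict_nps("Q", fx$query_seq, fx$hits, fx$labels)
  p <- pred$positions
  expect_equal(p$vote_score[1], 2 / 3)        # labels (1,1,0)
  expect_equal(p$call[1], 1L)
  expect_equal(p$vote_score[2], 2 / 3)
  expect_equal(p$vote_score[5], 1)            # the '?' abstains, 2 votes cast
  expect_equal(p$n_votes[5], 2L)
  expect_true(is.na(p$vote_score[4]))         # all templates '?': no votes
  expect_equal(p$call[4], 0L)
  expect_equal(p$n_votes[4], 0L)
  # exactly half the votes is called interface
  fx2 <- vote_fixture(list(track_const("1"), track_const("0")))
  p2 <- predict_nps("Q", fx2$query_seq, fx2$hits, fx2$labels)$positions
  expect_true(all(p2$vote_score == 0.5))
  expect_true(all(p2$call == 1L))
})

test_that("the zone cascade prefers the strictest populated zone", {
  qseq <- strrep("A", 200)
  safe_hit <- alignment_stats(make_record(template_id = "S1", eval = 0,
                                          q_aln = qseq, t_aln = qseq))
  # a long but weak alignment: Twilight 1
  tw_seq <- paste0(strrep("A", 140), strrep("G", 60))
  tw_hit <- alignment_stats(make_record(template_id = "W1", eval = 1e-30,
                                        q_aln = qseq, t_aln = tw_seq,
                                        n_identical = 140L, n_positive = 140L))
  labels <- dplyr::bind_rows(
    tibble::tibble(chain = "S1", pos = 1:200, aa = "A",
                   label = c(rep("1", 5), rep("0", 195))),
    tibble::tibble(chain = "W1", pos = 1:200, aa = "A",
                   label = c(rep("0", 195), rep("1", 5)))
  )
  both <- dplyr::bind_rows(safe_hit, tw_hit)
  pred <- predict_nps("Q", qseq, both, labels)
  expect_equal(pred$zone, "Safe")
  expect_equal(pred$templates, "S1")
  expect_equal(sum(pred$positions$call), 5)
  # without the safe hit the cascade falls through to Twilight 1
  pred2 <- predict_nps("Q", qseq, tw_hit, labels)
  expect_equal(pred2$zone, "Twilight1")
  # hits beyond every zone ceiling produce a non-prediction
  none <- alignment_stats(make_record(template_id = "N1", eval = 8, q_aln = qseq,
                                      t_aln = qseq))
  pred3 <- predict_nps("Q", qseq, none, labels)
  expect_false(pred3$predicted)
  expect_true(all(is.na(pred3$positions$call)))
  # so do queries with no hits at all, distinctly from an all-zero prediction
  pred4 <- predict_nps("Q", qseq, none[0, ], labels)
  expect_false(pred4$predicted)
})

test_that("one vote per template: the best-conserved alignment of a pair wins", {
  qseq <- strrep("A", 60)
  hsp_long <- make_record(template_id = "T1", eval = 1e-80, q_aln = qseq, t_aln = qseq)
  short <- strrep("A", 55)
  hsp_short <- make_record(template_id = "T1", eval = 1e-30,
                           q_aln = short, t_aln = short)
  labels <- tibble::tibble(chain = "T1", pos = 1:60, aa = "A",
                           label = c(rep("1", 3), rep("0", 57)))
  pred <- predict_nps("Q", qseq, alignment_stats(dplyr::bind_rows(hsp_short, hsp_long)),
                      labels)
  expect_equal(length(pred$templates), 1)
  # the 60-column HSP covers all 60 positions; the 55-column one could not
  expect_true(all(pred$positions$n_votes == 1L))
})

test_that("votes match an exhaustive recount on random template sets", {
  set.seed(61)
  for (case in 1:60) {
    rc <- random_vote_case()
    got <- homint:::tally_votes(rc$query_len, rc$selected, function(row) {
      rows <- rc$labels[rc$labels$chain == row$template_id, ]
      track <- rep(NA_character_, max(rows$pos))
      track[rows$pos] <- rows$label
      track
    })
    want <- recount_votes(rc$query_len, rc$selected, rc$labels)
    expect_equal(got, want, info = paste("case", case))
  }
})

test_that("prediction is deterministic and tidies into stable tables", {
  set.seed(71)
  qseq <- random_sequence_for_test(50)
  qlab <- sample(c("0", "1"), 50, replace = TRUE, prob = c(4, 1))
  tms <- purrr::map(1:3, ~ mutate_homolog(qseq, qlab, sub_rate = 0.1,
                                          template_id = paste0("T", .x), seed = .x))
  hits <- alignment_stats(purrr::map_dfr(tms, "record"))
  labels <- purrr::map_dfr(tms, "labels")
  p1 <- predict_nps("Q", qseq, hits, labels)
  p2 <- predict_nps("Q", qseq, hits, labels)
  expect_identical(p1, p2)
  td <- tidy(p1)
  expect_equal(names(td), c("query_id", "pos", "aa", "vote_score", "n_votes", "call"))
  g <- glance(p1)
  expect_equal(g$n_templates, 3)
  expect_equal(g$n_positions, 50)
})
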