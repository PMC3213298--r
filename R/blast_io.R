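#' Default BLASTP tabular column layout
#'
#' The column order produced by
#' `blastp -outfmt "6 qseqid sseqid evalue length nident positive qlen slen
#' qstart qend sstart send qseq sseq"`. Any permutation can be supplied to
#' [read_blast_tabular()]; percentage columns `pident`/`ppos` are accepted in
#' place of the integer counts `nident`/`positive`.
#'
#' @return Character vector of column names.
#' @export
blast_columns <- function() {
  c("qseqid", "sseqid", "evalue", "length", "nident", "positive",
    "qlen", "slen", "qstart", "qend", "sstart", "send", "qseq", "sseq")
}

# canonical internal names for the per-HSP record
.record_cols <- c("query_id", "template_id", "eval", "lal", "n_identical",
                  "n_positive", "query_len", "template_len",
                  "q_start", "q_end", "t_start", "t_end", "q_aln", "t_aln")

#' Read BLASTP tabular output into a tidy hit table
#'
#' Parses NCBI `-outfmt 6` output (one high-scoring segment pair per line)
#' into a tibble of alignment records with 1-based inclusive coordinates.
#' Lines that violate the record invariants (aligned-string lengths, gapless
#' residue counts, count ordering) are collected in the `"problems"`
#' attribute rather than silently dropped.
#'
#' @param file Path to a tabular BLASTP result (or a literal data string via
#'   [I()]).
#' @param columns Column names, in file order. Must cover the mandatory
#'   fields of [blast_columns()]; `pident`/`ppos` may replace
#'   `nident`/`positive`, in which case counts are recovered by rounding
#'   `percent * length / 100` to the nearest integer.
#' @return A tibble with columns `query_id`, `template_id`, `eval`, `lal`,
#'   `n_identical`, `n_positive`, `query_len`, `template_len`, `q_start`,
#'   `q_end`, `t_start`, `t_end`, `q_aln`, `t_aln`, and a `"problems"`
#'   attribute (tibble of rejected rows with a `reason` column).
#' @export
read_blast_tabular <- function(file, columns = blast_columns()) {
  mandatory <- list(
    qseqid = "qseqid", sseqid = "sseqid", evalue = "evalue", length = "length",
    nident = c("nident", "pident"), positive = c("positive", "ppos"),
    qlen = "qlen", slen = "slen", qstart = "qstart", qend = "qend",
    sstart = "sstart", send = "send", qseq = "qseq", sseq = "sseq"
  )
  for (field in names(mandatory)) {
    if (!any(mandatory[[field]] %in% columns)) {
      abort(sprintf("BLAST column specification is missing '%s' (or an accepted alias)",
                    field),
            class = "homint_config_error")
    }
  }
  raw <- readr::read_tsv(file, col_names = columns, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#")
  if (nrow(raw) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(character()), length(.record_cols)), .record_cols))
    out <- dplyr::mutate(out, across(c("eval"), as.numeric),
                         across(c("lal", "n_identical", "n_positive", "query_len",
                                  "template_len", "q_start", "q_end", "t_start", "t_end"),
                                as.integer))
    attr(out, "problems") <- tibble(line = integer(), reason = character())
    return(out)
  }
  num <- function(col) as.numeric(raw[[col]])
  int <- function(col) as.integer(round(as.numeric(raw[[col]])))
  lal <- int("length")
  n_identical <- if ("nident" %in% columns) int("nident") else
    as.integer(round(num("pident") * lal / 100))
  n_positive <- if ("positive" %in% columns) int("positive") else
    as.integer(round(num("ppos") * lal / 100))
  out <- tibble(
    query_id = raw$qseqid, template_id = raw$sseqid,
    eval = num("evalue"), lal = lal,
    n_identical = n_identical, n_positive = n_positive,
    query_len = int("qlen"), template_len = int("slen"),
    q_start = int("qstart"), q_end = int("qend"),
    t_start = int("sstart"), t_end = int("send"),
    q_aln = raw$qseq, t_aln = raw$sseq
  )
  validate_alignments(out)
}

# splits a candidate record table into valid rows + a problems attribute
validate_alignments <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  n_res <- function(s) nchar(gsub("-", "", s, fixed = TRUE))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(!is.finite(records$eval) | records$eval < 0, "negative or missing evalue")
  reason <- bad(is.na(records$lal) | records$lal < 1, "missing or zero alignment length")
  reason <- bad(nchar(records$q_aln) != records$lal | nchar(records$t_aln) != records$lal,
                "aligned string length disagrees with the length field")
  reason <- bad(n_res(records$q_aln) != records$q_end - records$q_start + 1,
                "query coordinates disagree with non-gap residue count")
  reason <- bad(n_res(records$t_aln) != records$t_end - records$t_start + 1,
                "template coordinates disagree with non-gap residue count")
  reason <- bad(records$n_identical < 0 | records$n_identical > records$n_positive |
                  records$n_positive > records$lal,
                "identity/positive counts out of order")
  ok <- is.na(reason)
  problems <- tibble(line = which(!ok), reason = reason[!ok])
  if (nrow(problems) > 0) {
    warn(sprintf("%d malformed BLAST record(s) rejected; see attr(., 'problems')",
                 nrow(problems)))
  }
  out <- records[ok, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Write alignment records as BLASTP default-dialect tabular
#'
#' Inverse of [read_blast_tabular()] with the default column layout;
#' round-trips all record fields exactly.
#'
#' @param records Tibble of alignment records.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_blast_tabular <- function(records, file) {
  out <- tibble(
    qseqid = records$query_id, sseqid = records$template_id,
    evalue = format(records$eval, digits = 17, scientific = TRUE, trim = TRUE),
    length = records$lal, nident = records$n_identical, positive = records$n_positive,
    qlen = records$query_len, slen = records$template_len,
    qstart = records$q_start, qend = records$q_end,
    sstart = records$t_start, send = records$t_end,
    qseq = records$q_aln, sseq = records$t_aln
  )
  readr::write_tsv(out, file, col_names = FALSE, progress = FALSE)
  invisible(file)
}

#' Derive the six alignment statistics from BLAST records
#'
#' Adds, per hit, the six quantities on which the homology zones and the
#' interface-conservation models operate: `log_eval` (natural log of the
#' expectation value, set to -450 when `eval == 0`), `identity_score` and
#' `positive_score` (percent of alignment columns, 0-100), `log_lal`
#' (natural log of the local alignment length, columns including gaps), and
#' the two length fractions `frac_query = lal / query_len` and
#' `frac_template = lal / template_len`.
#'
#' @param records Tibble of alignment records (see [read_blast_tabular()]).
#' @return The input with the six statistic columns appended.
#' @export
alignment_stats <- function(records) {
  if (any(records$lal == 0)) {
    abort("alignment length (lal) of 0: statistics are undefined",
          class = "homint_domain_error")
  }
  dplyr::mutate(records,
    log_eval = ifelse(.data$eval == 0, LOG_EVAL_FLOOR, log(.data$eval)),
    identity_score = 100 * .data$n_identical / .data$lal,
    positive_score = 100 * .data$n_positive / .data$lal,
    log_lal = log(.data$lal),
    frac_query = .data$lal / .data$query_len,
    frac_template = .data$lal / .data$template_len
  )
}

#' Substitution matrix and gap costs by query length
#'
#' Short queries need shallower matrices and tighter gap costs for BLASTP to
#' retain sensitivity. Ranges: 1-34 PAM30 (9,1); 35-49 PAM70 (10,1); 50-84
#' BLOSUM80 (10,1); 85+ BLOSUM62 (10,1). Boundary lengths shared by two
#' printed ranges (50, 85) resolve to the longer-query row, which keeps the
#' ranges disjoint.
#'
#' @param query_len Integer vector of query lengths (>= 1).
#' @return Tibble with columns `query_len`, `matrix`, `gap_open`,
#'   `gap_extend`.
#' @export
blast_params_for_length <- function(query_len) {
  stopifnot(all(query_len >= 1))
  band <- findInterval(query_len, c(1, 35, 50, 85))
  tibble(
    query_len = query_len,
    matrix = c("PAM30", "PAM70", "BLOSUM80", "BLOSUM62")[band],
    gap_open = c(9L, 10L, 10L, 10L)[band],
    gap_extend = 1L
  )
}

#' Run a local BLASTP search with length-appropriate parameters
#'
#' Thin wrapper over a locally installed `blastp` binary: picks the
#' substitution matrix and gap costs with [blast_params_for_length()], runs
#' with expectation-value cutoff 10, and parses the tabular result with
#' [read_blast_tabular()]. Requires a pre-formatted protein database
#' (`makeblastdb -dbtype prot`).
#'
#' @param query_fasta Path to a single-sequence query FASTA file.
#' @param db Path/name of the BLAST database.
#' @param evalue Expectation-value cutoff (default 10).
#' @param blastp Name or path of the blastp executable.
#' @return A hit tibble as from [read_blast_tabular()].
#' @export
run_blastp <- function(query_fasta, db, evalue = 10, blastp = "blastp") {
  if (Sys.which(blastp) == "") {
    abort(sprintf("blastp executable '%s' not found on PATH", blastp),
          class = "homint_config_error")
  }
  qry <- Biostrings::readAAStringSet(query_fasta)
  if (length(qry) != 1) abort("query FASTA must contain exactly one sequence")
  pars <- blast_params_for_length(Biostrings::width(qry))
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  fmt <- paste("6", paste(blast_columns(), collapse = " "))
  status <- system2(blastp, c(
    "-query", shQuote(query_fasta), "-db", shQuote(db),
    "-evalue", format(evalue), "-matrix", pars$matrix,
    "-gapopen", pars$gap_open, "-gapextend", pars$gap_extend,
    "-outfmt", shQuote(fmt), "-out", shQuote(out)
  ))
  if (status != 0) abort("blastp exited with non-zero status")
  read_blast_tabular(out)
}

#' Read and write protein FASTA files
#'
#' Convenience wrappers over Biostrings returning plain named character
#' vectors, which is the shape the rest of the package consumes.
#'
#' @param file Path to a FASTA file.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector of amino-acid sequences.
#' @export
write_fasta <- function(sequences, file) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
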