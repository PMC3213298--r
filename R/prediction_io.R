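#' Write a prediction to TSV
#'
#' Per-position table (`pos`, `aa`, `vote_score`, `call`, `n_votes`)
#' preceded by `#`-prefixed header lines recording the query id, the
#' homology zone used and the templates consulted.
#'
#' @param pred A `ppi_prediction`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_prediction_tsv <- function(pred, file) {
  header <- c(
    sprintf("# query_id: %s", pred$query_id),
    sprintf("# predicted: %s", pred$predicted),
    sprintf("# zone: %s", pred$zone %||% NA),
    sprintf("# templates: %s", paste(pred$templates, collapse = ","))
  )
  writeLines(header, file)
  readr::write_tsv(pred$positions, file, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(file)
}

#' @rdname write_prediction_tsv
#' @export
read_prediction_tsv <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "# ")]
  field <- function(key) {
    v <- sub(paste0("^# ", key, ": "), "", hdr[startsWith(hdr, paste0("# ", key, ":"))])
    if (length(v) == 0 || v %in% c("NA", "")) NA_character_ else v
  }
  body <- readr::read_tsv(I(paste(lines[!startsWith(lines, "# ")], collapse = "\n")),
                          col_types = readr::cols(
                            pos = "i", aa = "c", vote_score = "d",
                            n_votes = "i", call = "i"
                          ), progress = FALSE)
  templates <- field("templates")
  structure(list(
    positions = body,
    query_id = field("query_id"),
    zone = field("zone"),
    templates = if (is.na(templates)) character() else strsplit(templates, ",")[[1]],
    predicted = identical(field("predicted"), "TRUE")
  ), class = "ppi_prediction")
}
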