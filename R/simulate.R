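# Synthetic structures, homolog families and interolog scenarios.
#
# Everything here is generated data for offline development and testing:
# coarse-grained chains (one backbone and one side-chain pseudo-atom per
# residue) laid out so contact labels are known analytically, homologs with
# controlled divergence and exact ground-truth alignments, and a fabricated
# expectation value that is a documented decreasing function of the
# identity count (eval = LAL * exp(-lambda * n_identical)); only its order
# relative to the zone thresholds matters.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

SPECIES_POOL <- c("E.coli", "S.cerevisiae", "H.sapiens", "M.musculus",
                  "T.thermophilus", "B.subtilis")

random_sequence <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

#' Generate a synthetic protein complex with known interface labels
#'
#' Builds 2 or 3 coarse-grained chains (backbone CA plus one side-chain
#' pseudo-atom per residue) on extended, self-avoiding paths. For each
#' consecutive chain pair a contact patch of `contact_patch_size` residues
#' is placed so matched patch residues sit about 3.5 Angstrom apart
#' (within 3.2-3.8 after jitter) while every non-patch inter-chain residue
#' pair stays beyond 6 Angstrom, so the true interface labels are known by
#' construction: exactly the patch residues, provided they are surface
#' residues — which the extended geometry guarantees.
#'
#' @param n_chains 2 or 3.
#' @param len_range Integer range for per-chain lengths.
#' @param contact_patch_size Residues per contact patch (0 gives a
#'   contact-free pair of chains).
#' @param unresolved_frac Fraction of non-patch residues left without
#'   coordinates (unresolved, `"?"` in derived labels).
#' @param seed Optional RNG seed for reproducibility.
#' @param complex_id Identifier stamped on chains (`<complex_id>_A`, ...).
#' @return List: `complex` (a [ppi_complex()]), `labels` (the analytic
#'   union-interface truth, `chain`, `pos`, `aa`, `label`), `ps_labels`
#'   (partner-specific truth with a `partner` and `complex_id` column), and
#'   `patches` (per chain-pair patch positions).
#' @export
make_complex <- function(n_chains = 2, len_range = c(20, 35),
                         contact_patch_size = 4, unresolved_frac = 0,
                         seed = NULL, complex_id = "cx") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_chains %in% 2:3, contact_patch_size >= 0)
  lens <- sample(len_range[1]:len_range[2], n_chains, replace = TRUE)
  ids <- paste0(complex_id, "_", LETTERS[seq_len(n_chains)])
  jit <- function(n) runif(n, -0.05, 0.05)
  spacing <- 3.8
  # chain k baseline: k = 1 on the x axis; 2 displaced in y; 3 displaced in z
  base_offset <- list(c(0, 0, 0), c(0, 25, 0), c(0, 0, 25))
  # contact patches: chain2 touches chain1, chain3 touches chain1
  patch_len <- function(len) min(contact_patch_size, len - 2)
  atoms <- list()
  truth <- list()
  ps_truth <- list()
  patches <- list()
  seqs <- lapply(lens, random_sequence)
  patch_pos <- list()
  if (contact_patch_size > 0) {
    # patch on chain 1 for chain 2, and a disjoint one for chain 3
    p12 <- patch_len(min(lens))
    start1 <- 2
    patch_pos[["2"]] <- list(host = start1:(start1 + p12 - 1),
                             guest = start1:(start1 + p12 - 1))
    if (n_chains == 3) {
      p13 <- patch_len(min(lens[c(1, 3)]))
      start3 <- start1 + p12 + 2
      if (start3 + p13 - 1 > min(lens[c(1, 3)]) - 1) {
        abort("chains too short for two disjoint patches")
      }
      patch_pos[["3"]] <- list(host = start3:(start3 + p13 - 1),
                               guest = start3:(start3 + p13 - 1))
    }
  }
  for (k in seq_len(n_chains)) {
    len <- lens[k]
    off <- base_offset[[k]]
    ca <- cbind(spacing * seq_len(len) + jit(len), off[2] + jit(len), off[3] + jit(len))
    # side-chain pseudo-atom points away from every partner direction
    side_dir <- if (k == 1) c(0, -1.5, -1.5) else if (k == 2) c(0, 1.5, 0) else c(0, 0, 1.5)
    cb <- sweep(ca, 2, side_dir, `+`)
    if (k > 1 && !is.null(patch_pos[[as.character(k)]])) {
      pp <- patch_pos[[as.character(k)]]
      # pull guest patch residues to ~3.5 A of the matching host residues
      if (k == 2) {
        ca[pp$guest, 2] <- 3.5 + jit(length(pp$guest))
        cb[pp$guest, 2] <- ca[pp$guest, 2] + 1.5
      } else {
        ca[pp$guest, 3] <- 3.5 + jit(length(pp$guest))
        cb[pp$guest, 3] <- ca[pp$guest, 3] + 1.5
      }
      ca[pp$guest, 1] <- spacing * pp$host + jit(length(pp$guest))
      cb[pp$guest, 1] <- ca[pp$guest, 1]
    }
    aa <- strsplit(seqs[[k]], "")[[1]]
    resolved <- rep(TRUE, len)
    if (unresolved_frac > 0) {
      protected <- unique(unlist(lapply(patch_pos, function(p) c(p$host, p$guest))))
      candidates <- setdiff(seq_len(len), protected)
      n_drop <- floor(unresolved_frac * length(candidates))
      if (n_drop > 0) resolved[sample(candidates, n_drop)] <- FALSE
    }
    keep <- which(resolved)
    atoms[[k]] <- tibble(
      chain = ids[k],
      resno = rep(keep, each = 2),
      aa = rep(aa[keep], each = 2),
      atom = rep(c("CA", "CB"), length(keep)),
      element = "C",
      x = as.vector(rbind(ca[keep, 1], cb[keep, 1])),
      y = as.vector(rbind(ca[keep, 2], cb[keep, 2])),
      z = as.vector(rbind(ca[keep, 3], cb[keep, 3]))
    )
    lab <- rep("0", len)
    if (contact_patch_size > 0) {
      if (k == 1) {
        for (g in names(patch_pos)) lab[patch_pos[[g]]$host] <- "1"
      } else if (!is.null(patch_pos[[as.character(k)]])) {
        lab[patch_pos[[as.character(k)]]$guest] <- "1"
      }
    }
    lab[!resolved] <- "?"
    truth[[k]] <- tibble(chain = ids[k], pos = seq_len(len), aa = aa, label = lab)
  }
  # partner-specific truth per interacting pair
  if (contact_patch_size > 0) {
    for (g in names(patch_pos)) {
      k <- as.integer(g)
      pp <- patch_pos[[g]]
      host_lab <- rep("0", lens[1]); host_lab[pp$host] <- "1"
      guest_lab <- rep("0", lens[k]); guest_lab[pp$guest] <- "1"
      host_lab[truth[[1]]$label == "?"] <- "?"
      guest_lab[truth[[k]]$label == "?"] <- "?"
      ps_truth[[length(ps_truth) + 1]] <- dplyr::bind_rows(
        tibble(complex_id = complex_id, chain = ids[1], partner = ids[k],
               pos = seq_len(lens[1]), aa = truth[[1]]$aa, label = host_lab),
        tibble(complex_id = complex_id, chain = ids[k], partner = ids[1],
               pos = seq_len(lens[k]), aa = truth[[k]]$aa, label = guest_lab)
      )
      patches[[g]] <- pp
    }
  }
  chains <- tibble(
    chain = ids,
    sequence = unlist(seqs),
    species = sample(SPECIES_POOL, n_chains, replace = TRUE),
    method = "xray",
    resolution = round(runif(n_chains, 1.2, 3.0), 2)
  )
  list(
    complex = ppi_complex(dplyr::bind_rows(atoms), chains),
    labels = dplyr::bind_rows(truth),
    ps_labels = if (length(ps_truth) > 0) dplyr::bind_rows(ps_truth) else
      tibble(complex_id = character(), chain = character(), partner = character(),
             pos = integer(), aa = character(), label = character()),
    patches = patches
  )
}

#' Mutate a sequence into a homolog with a known alignment
#'
#' Applies point substitutions and short indels at the given rates and
#' emits the exact ground-truth pairwise alignment, so BLAST-style records
#' with exact statistics can be fabricated without running BLAST.
#' Interface positions are substituted at the reduced rate
#' `sub_rate * (1 - interface_bias)`, mimicking interface conservation;
#' when a position is substituted, the homolog's interface label flips with
#' probability `label_flip_rate`, so label divergence tracks sequence
#' divergence. The fabricated expectation value is
#' `lal * exp(-lambda * n_identical)` — a monotone stand-in whose only job
#' is to place fixtures on the intended side of the zone thresholds.
#'
#' @param sequence Parent amino-acid sequence.
#' @param labels Parent label track (character vector `"0"`/`"1"`/`"?"`),
#'   length `nchar(sequence)`.
#' @param sub_rate Per-position substitution probability outside
#'   interfaces.
#' @param indel_rate Per-position probability of opening a 1-2 residue
#'   insertion or deletion.
#' @param interface_bias In `[0, 1]`: 0 mutates interfaces like everything
#'   else, 1 freezes them.
#' @param label_flip_rate Probability that a substituted position's label
#'   flips in the homolog.
#' @param lambda Decay constant of the fabricated expectation value.
#' @param seed Optional RNG seed.
#' @param query_id,template_id Identifiers for the emitted record.
#' @return List: `sequence` (homolog), `labels` (tibble `chain`, `pos`,
#'   `aa`, `label` for the homolog), `record` (one-row alignment record
#'   tibble in the canonical layout).
#' @export
mutate_homolog <- function(sequence, labels, sub_rate = 0.2, indel_rate = 0,
                           interface_bias = 0.5, label_flip_rate = 0.3,
                           lambda = 1.5, seed = NULL,
                           query_id = "query", template_id = "tmpl") {
  if (!is.null(seed)) set.seed(seed)
  q <- strsplit(sequence, "")[[1]]
  stopifnot(length(labels) == length(q))
  q_aln <- character(0); t_aln <- character(0)
  t_seq <- character(0); t_lab <- character(0)
  blosum <- positive_matrix()
  for (i in seq_along(q)) {
    # deletion: query residue unmatched
    if (indel_rate > 0 && runif(1) < indel_rate / 2) {
      dlen <- min(sample(1:2, 1), length(q) - i)
      if (dlen >= 1 && i < length(q)) {
        q_aln <- c(q_aln, q[i]); t_aln <- c(t_aln, "-")
        next
      }
    }
    rate <- if (labels[i] == "1") sub_rate * (1 - interface_bias) else sub_rate
    new_aa <- q[i]
    lab <- labels[i]
    if (runif(1) < rate) {
      new_aa <- sample(setdiff(AA_ALPHABET, q[i]), 1)
      if (lab %in% c("0", "1") && runif(1) < label_flip_rate) {
        lab <- if (lab == "1") "0" else "1"
      }
    }
    q_aln <- c(q_aln, q[i]); t_aln <- c(t_aln, new_aa)
    t_seq <- c(t_seq, new_aa); t_lab <- c(t_lab, lab)
    # insertion: extra template residues
    if (indel_rate > 0 && runif(1) < indel_rate / 2) {
      ilen <- sample(1:2, 1)
      ins <- sample(AA_ALPHABET, ilen, replace = TRUE)
      q_aln <- c(q_aln, rep("-", ilen)); t_aln <- c(t_aln, ins)
      t_seq <- c(t_seq, ins); t_lab <- c(t_lab, rep("0", ilen))
    }
  }
  lal <- length(q_aln)
  match_col <- q_aln != "-" & t_aln != "-"
  n_identical <- sum(match_col & q_aln == t_aln)
  pos_sub <- match_col & q_aln != t_aln &
    blosum[cbind(match(q_aln, AA_ALPHABET), match(t_aln, AA_ALPHABET))] > 0
  pos_sub[is.na(pos_sub)] <- FALSE
  n_positive <- n_identical + sum(pos_sub)
  eval <- lal * exp(-lambda * n_identical)
  record <- tibble(
    query_id = query_id, template_id = template_id,
    eval = eval, lal = lal,
    n_identical = n_identical, n_positive = n_positive,
    query_len = length(q), template_len = length(t_seq),
    q_start = 1L, q_end = length(q),
    t_start = 1L, t_end = length(t_seq),
    q_aln = paste(q_aln, collapse = ""), t_aln = paste(t_aln, collapse = "")
  )
  list(
    sequence = paste(t_seq, collapse = ""),
    labels = tibble(chain = template_id, pos = seq_along(t_seq),
                    aa = t_seq, label = t_lab),
    record = record
  )
}

# BLOSUM62 scores over the 20-letter alphabet (for synthetic positives)
positive_matrix <- function() {
  m <- get_blosum62()
  m[AA_ALPHABET, AA_ALPHABET]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Generate a partner-specific prediction scenario
#'
#' Emulates the situation that makes partner-specific prediction matter: a
#' query protein A with two distinct interfaces, one used with partner B
#' and a disjoint one used with partner C. The generator builds the two
#' query complexes, homolog templates forming interologs for each pair
#' (divergence tuned to land in the Twilight zones), a decoy interolog in a
#' low-resolution complex, the query's own complex (which must be
#' excluded), and the complex index. The union (non-partner-specific)
#' labels of A cover both patches while the partner-specific labels differ
#' by partner.
#'
#' @param seed RNG seed.
#' @param len Length of query A (B and C are similar).
#' @param patch_size Interface patch size.
#' @param sub_rate Template divergence.
#' @return List with `queries` (named list of `id`/`seq`/`species`),
#'   `truth` (partner-specific truth tracks for A|B, A|C, B|A, C|A and the
#'   union track of A), `hits_a`, `hits_b`, `hits_c` (alignment records),
#'   `templates` (chain metadata), `ps_labels`, `complex_index`, and
#'   `query_complex` (the id to exclude).
#' @export
make_ps_scenario <- function(seed = 1, len = 70, patch_size = 5, sub_rate = 0.12) {
  set.seed(seed)
  seq_a <- random_sequence(len)
  seq_b <- random_sequence(len - 5)
  seq_c <- random_sequence(len + 5)
  # two disjoint patches on A
  p_b <- 5:(4 + patch_size)
  p_c <- (len - 4 - patch_size):(len - 5)
  patch_b_on_b <- 3:(2 + patch_size)
  patch_c_on_c <- 8:(7 + patch_size)
  track <- function(n, patch) { x <- rep("0", n); x[patch] <- "1"; x }
  truth <- list(
    a_with_b = track(len, p_b),
    a_with_c = track(len, p_c),
    b_with_a = track(nchar(seq_b), patch_b_on_b),
    c_with_a = track(nchar(seq_c), patch_c_on_c),
    a_union = track(len, c(p_b, p_c))
  )
  species <- c(a = "H.sapiens", b = "H.sapiens", c = "M.musculus")

  # scenario templates keep exact partner-specific labels (label_flip_rate 0):
  # the scenario probes partner-specific transfer, not label noise
  new_template <- function(parent_seq, parent_track, tid, bias = 0.9, rate = sub_rate) {
    mutate_homolog(parent_seq, parent_track, sub_rate = rate,
                   interface_bias = bias, label_flip_rate = 0,
                   template_id = tid, query_id = "placeholder")
  }
  templates <- list(); ps_labels <- list()
  hits <- list(a = list(), b = list(), c = list())
  index <- list()
  add_complex <- function(cxid, tmpl_1, tmpl_2, resolution = 2.0, species_1, species_2) {
    templates[[length(templates) + 1]] <<- tibble(
      chain = c(tmpl_1$record$template_id, tmpl_2$record$template_id),
      sequence = c(tmpl_1$sequence, tmpl_2$sequence),
      species = c(species_1, species_2), method = "xray", resolution = resolution
    )
    ps_labels[[length(ps_labels) + 1]] <<- dplyr::bind_rows(
      dplyr::mutate(tmpl_1$labels, complex_id = cxid,
                    partner = tmpl_2$record$template_id),
      dplyr::mutate(tmpl_2$labels, complex_id = cxid,
                    partner = tmpl_1$record$template_id)
    )
    index[[length(index) + 1]] <<- tibble(
      complex_id = cxid,
      chain_a = tmpl_1$record$template_id, chain_b = tmpl_2$record$template_id
    )
  }
  hit_of <- function(tmpl, qid) dplyr::mutate(tmpl$record, query_id = qid)

  # two good interolog complexes per partner pair
  for (i in 1:2) {
    ta <- new_template(seq_a, truth$a_with_b, sprintf("tAB%d_A", i))
    tb <- new_template(seq_b, truth$b_with_a, sprintf("tAB%d_B", i))
    add_complex(sprintf("cAB%d", i), ta, tb,
                species_1 = "T.thermophilus", species_2 = "B.subtilis")
    hits$a[[length(hits$a) + 1]] <- hit_of(ta, "A")
    hits$b[[length(hits$b) + 1]] <- hit_of(tb, "B")
    ta2 <- new_template(seq_a, truth$a_with_c, sprintf("tAC%d_A", i))
    tc <- new_template(seq_c, truth$c_with_a, sprintf("tAC%d_C", i))
    add_complex(sprintf("cAC%d", i), ta2, tc,
                species_1 = "E.coli", species_2 = "S.cerevisiae")
    hits$a[[length(hits$a) + 1]] <- hit_of(ta2, "A")
    hits$c[[length(hits$c) + 1]] <- hit_of(tc, "C")
  }
  # decoy: interolog in a complex with unusable resolution
  ta_bad <- new_template(seq_a, truth$a_with_b, "tBAD_A")
  tb_bad <- new_template(seq_b, truth$b_with_a, "tBAD_B")
  add_complex("cBAD", ta_bad, tb_bad, resolution = 3.8,
              species_1 = "E.coli", species_2 = "E.coli")
  hits$a[[length(hits$a) + 1]] <- hit_of(ta_bad, "A")
  hits$b[[length(hits$b) + 1]] <- hit_of(tb_bad, "B")
  # the query's own complex: perfect self-hits that must be excluded
  ta_self <- new_template(seq_a, truth$a_with_b, "qA", rate = 0)
  tb_self <- new_template(seq_b, truth$b_with_a, "qB", rate = 0)
  add_complex("cQUERY", ta_self, tb_self,
              species_1 = species[["a"]], species_2 = species[["b"]])
  hits$a[[length(hits$a) + 1]] <- hit_of(ta_self, "A")
  hits$b[[length(hits$b) + 1]] <- hit_of(tb_self, "B")

  list(
    queries = list(
      a = list(id = "A", seq = seq_a, species = species[["a"]]),
      b = list(id = "B", seq = seq_b, species = species[["b"]]),
      c = list(id = "C", seq = seq_c, species = species[["c"]])
    ),
    truth = truth,
    hits_a = dplyr::bind_rows(hits$a),
    hits_b = dplyr::bind_rows(hits$b),
    hits_c = dplyr::bind_rows(hits$c),
    templates = dplyr::bind_rows(templates),
    ps_labels = dplyr::bind_rows(ps_labels),
    complex_index = dplyr::bind_rows(index),
    query_complex = "cQUERY"
  )
}

#' Read and write the complex interaction index
#'
#' TSV with columns `complex_id`, `chain_a`, `chain_b`: one row per pair of
#' template chains in physical contact within a solved complex.
#'
#' @param file TSV path.
#' @export
read_complex_index <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(.default = "c"), progress = FALSE)
}

#' @rdname read_complex_index
#' @param index Index tibble.
#' @export
write_complex_index <- function(index, file) {
  readr::write_tsv(index, file, progress = FALSE)
  invisible(file)
}

#' Read and write template chain metadata
#'
#' TSV with columns `chain`, `sequence`, `species`, `method`, `resolution`.
#'
#' @param file TSV path.
#' @export
read_template_meta <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    chain = "c", sequence = "c", species = "c", method = "c", resolution = "d"
  ), progress = FALSE)
}

#' @rdname read_template_meta
#' @param templates Metadata tibble.
#' @export
write_template_meta <- function(templates, file) {
  readr::write_tsv(templates, file, progress = FALSE)
  invisible(file)
}
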