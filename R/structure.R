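#' Assemble a multi-chain structure from tidy atom and chain tables
#'
#' The package represents a structure as two tibbles: `atoms` with one row
#' per atom (`chain`, `resno` — the 1-based position in the chain's full
#' sequence — `aa` one-letter residue type, `atom` name, `element`, `x`,
#' `y`, `z` in Angstrom) and `chains` with one row per chain (`chain`,
#' `sequence` — the full sequence including residues without coordinates —
#' `species`, `method` one of `"xray"`, `"nmr"`, `"other"`, `resolution` in
#' Angstrom or `NA`). Residues of the full sequence with no atom rows are
#' treated as unresolved.
#'
#' @param atoms Atom tibble.
#' @param chains Chain metadata tibble.
#' @return An object of class `ppi_complex`.
#' @export
ppi_complex <- function(atoms, chains) {
  atoms <- as_tibble(atoms)
  chains <- as_tibble(chains)
  stopifnot(all(c("chain", "resno", "aa", "atom", "element", "x", "y", "z") %in% names(atoms)),
            all(c("chain", "sequence") %in% names(chains)))
  if (!all(atoms$chain %in% chains$chain)) {
    abort("atoms reference chains absent from the chain table")
  }
  for (cid in unique(atoms$chain)) {
    a <- atoms[atoms$chain == cid, ]
    seq <- chains$sequence[chains$chain == cid]
    res <- dplyr::distinct(a, .data$resno, .data$aa)
    if (any(res$resno < 1) || any(res$resno > nchar(seq))) {
      abort(sprintf("chain %s: residue numbers outside 1..%d", cid, nchar(seq)))
    }
    seq_aa <- strsplit(seq, "")[[1]][res$resno]
    if (any(seq_aa != res$aa)) {
      abort(sprintf("chain %s: resolved residue types disagree with the full sequence", cid))
    }
    if (is.unsorted(unique(a$resno))) {
      abort(sprintf("chain %s: residue numbering not increasing", cid))
    }
  }
  structure(list(atoms = atoms, chains = chains), class = "ppi_complex")
}

#' @export
print.ppi_complex <- function(x, ...) {
  cat(sprintf("<ppi_complex: %d chain(s), %d atoms>\n",
              nrow(x$chains), nrow(x$atoms)))
  print(x$chains)
  invisible(x)
}

#' Van der Waals radii by element
#'
#' Bondi radii for the elements found in protein heavy atoms plus hydrogen;
#' unknown elements fall back to carbon's 1.70 Angstrom.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  out <- unname(r[toupper(element)])
  out[is.na(out)] <- 1.70
  out
}

#' Maximum residue solvent accessibility reference
#'
#' Theoretical maximum accessible surface areas (Angstrom^2) of residue X in
#' an extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical column),
#' used to normalise absolute SASA to relative SASA.
#'
#' @return Named numeric vector over the 20 one-letter residue codes.
#' @export
max_asa_table <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
    G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
    P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' Classic sphere-sampling SASA: each atom's solvent sphere (van der Waals
#' radius + probe radius) is sampled with a fixed Fibonacci point lattice; a
#' point is accessible when it lies outside every other atom's solvent
#' sphere. Deterministic for a fixed `n_points`.
#'
#' @param atoms Atom tibble (one structural context; pass a single chain for
#'   unbound-chain accessibility).
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-atom SASA in Angstrom^2, in row order.
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 240) {
  n <- nrow(atoms)
  if (n == 0) return(numeric(0))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  rad <- vdw_radius(atoms$element) + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)
  # neighbour prefilter keeps the per-atom work proportional to local density
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rad[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    out[i] <- frac * 4 * pi * rad[i]^2
  }
  out
}

#' Relative solvent accessibility per residue
#'
#' Computes each resolved residue's SASA in the isolated context of its own
#' chain (unbound-chain accessibility, so that surface status does not
#' depend on the binding partner) and divides by the per-residue-type
#' maximum from `max_asa`. Values can exceed 1 for highly exposed or
#' terminal residues. Unknown residue types use the median reference value
#' with a warning. Unresolved positions get `NA`.
#'
#' @param cx A [ppi_complex()].
#' @param probe Probe radius (Angstrom).
#' @param n_points Shrake-Rupley sample points per atom.
#' @param max_asa Named reference vector, default [max_asa_table()].
#' @return Tibble `chain`, `pos`, `aa`, `sasa`, `rasa` covering every
#'   position of every chain's full sequence.
#' @export
relative_asa <- function(cx, probe = 1.4, n_points = 240, max_asa = max_asa_table()) {
  stopifnot(inherits(cx, "ppi_complex"))
  purrr::map_dfr(seq_len(nrow(cx$chains)), function(ci) {
    cid <- cx$chains$chain[ci]
    seq <- strsplit(cx$chains$sequence[ci], "")[[1]]
    track <- tibble(chain = cid, pos = seq_along(seq), aa = seq,
                    sasa = NA_real_, rasa = NA_real_)
    a <- cx$atoms[cx$atoms$chain == cid, , drop = FALSE]
    if (nrow(a) == 0) return(track)
    sasa_atom <- atom_sasa(a, probe = probe, n_points = n_points)
    per_res <- tapply(sasa_atom, a$resno, sum)
    pos <- as.integer(names(per_res))
    track$sasa[pos] <- as.numeric(per_res)
    ref <- max_asa[track$aa[pos]]
    if (anyNA(ref)) {
      warn("unknown residue type(s); using the median reference max-ASA")
      ref[is.na(ref)] <- stats::median(max_asa)
    }
    track$rasa[pos] <- track$sasa[pos] / ref
    track
  })
}

# cell-list inter-chain contact search: for every residue of `chain_id`,
# the minimum distance from its atoms to any atom of `partner_ids`.
# cell width >= cutoff so only the 27 neighbouring cells need scanning.
min_partner_distance <- function(atoms, chain_id, partner_ids, cutoff) {
  mine <- atoms[atoms$chain == chain_id, , drop = FALSE]
  other <- atoms[atoms$chain %in% partner_ids, , drop = FALSE]
  res <- sort(unique(mine$resno))
  out <- setNames(rep(Inf, length(res)), res)
  if (nrow(mine) == 0 || nrow(other) == 0) return(out)
  cell <- max(cutoff, 1)
  key <- function(m) {
    ix <- floor(m[, 1] / cell); iy <- floor(m[, 2] / cell); iz <- floor(m[, 3] / cell)
    list(ix = ix, iy = iy, iz = iz, id = paste(ix, iy, iz))
  }
  oxyz <- cbind(other$x, other$y, other$z)
  ok <- key(oxyz)
  bins <- split(seq_len(nrow(other)), ok$id)
  mxyz <- cbind(mine$x, mine$y, mine$z)
  mk <- key(mxyz)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (i in seq_len(nrow(mine))) {
    neigh <- paste(mk$ix[i] + off[, 1], mk$iy[i] + off[, 2], mk$iz[i] + off[, 3])
    cand <- unlist(bins[neigh], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    d2 <- (oxyz[cand, 1] - mxyz[i, 1])^2 + (oxyz[cand, 2] - mxyz[i, 2])^2 +
      (oxyz[cand, 3] - mxyz[i, 3])^2
    dmin <- sqrt(min(d2))
    r <- as.character(mine$resno[i])
    if (dmin < out[r]) out[r] <- dmin
  }
  out
}

#' Derive per-residue interface labels from a multi-chain structure
#'
#' A residue is labelled an interface residue (`"1"`) when it is on the
#' surface of its own chain (relative accessibility at least `rasa_cutoff`,
#' computed on the unbound chain) and at least one of its atoms lies within
#' `dist_cutoff` of any atom of a partner chain. Surface or interior
#' residues without such a contact are `"0"`; residues without coordinates
#' are `"?"`. Distances use all atoms present (heavy atoms when hydrogens
#' are absent).
#'
#' With `partner_ids = NULL` every other chain counts as a partner, giving
#' the non-partner-specific union interface; restricting `partner_ids`
#' yields partner-specific labels.
#'
#' @param cx A [ppi_complex()] with at least two chains.
#' @param partner_ids Optional character vector of chains counted as
#'   binding partners.
#' @param dist_cutoff Contact distance cutoff in Angstrom.
#' @param rasa_cutoff Surface threshold on relative accessibility.
#' @param probe,n_points Passed to [relative_asa()].
#' @param rasa Optional precomputed [relative_asa()] table (saves recomputing
#'   accessibility when labelling the same structure against several partner
#'   sets).
#' @return Tibble `chain`, `pos`, `aa`, `label` (`"0"`/`"1"`/`"?"`) on full
#'   sequence coordinates, all chains stacked.
#' @export
label_interfaces <- function(cx, partner_ids = NULL, dist_cutoff = 4.0,
                             rasa_cutoff = 0.05, probe = 1.4, n_points = 240,
                             rasa = NULL) {
  stopifnot(inherits(cx, "ppi_complex"))
  if (nrow(cx$chains) < 2) {
    abort("interface labelling needs at least two chains", class = "homint_domain_error")
  }
  rasa <- rasa %||% relative_asa(cx, probe = probe, n_points = n_points)
  purrr::map_dfr(cx$chains$chain, function(cid) {
    partners <- setdiff(partner_ids %||% cx$chains$chain, cid)
    if (length(partners) == 0) {
      abort(sprintf("chain %s has no partner chain", cid), class = "homint_domain_error")
    }
    track <- rasa[rasa$chain == cid, , drop = FALSE]
    dmin <- min_partner_distance(cx$atoms, cid, partners, dist_cutoff)
    contact <- rep(FALSE, nrow(track))
    contact[as.integer(names(dmin))] <- dmin <= dist_cutoff
    tibble(
      chain = cid, pos = track$pos, aa = track$aa,
      label = dplyr::case_when(
        is.na(track$rasa) ~ "?",
        contact & track$rasa >= rasa_cutoff ~ "1",
        TRUE ~ "0"
      )
    )
  })
}

#' Template retention rules
#'
#' A template chain is usable for interface transfer only when its labels
#' are trustworthy: the structure must be an X-ray structure, its resolution
#' at most 3.5 Angstrom, and the chain must have at least 3 interface
#' residues. Applied per chain; the first rule violated is reported.
#'
#' @param chains Chain metadata tibble (`chain`, `method`, `resolution`).
#' @param labels Label tibble as from [label_interfaces()].
#' @param max_resolution Resolution ceiling in Angstrom.
#' @param min_interface Minimum number of `"1"` labels.
#' @return Tibble `chain`, `keep` (logical), `reason` (`NA` when kept).
#' @export
filter_templates <- function(chains, labels, max_resolution = 3.5, min_interface = 3) {
  n_iface <- labels |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(n_interface = sum(.data$label == "1"), .groups = "drop")
  chains |>
    dplyr::left_join(n_iface, by = "chain") |>
    dplyr::mutate(
      n_interface = dplyr::coalesce(.data$n_interface, 0L),
      reason = dplyr::case_when(
        .data$method != "xray" ~ "method",
        is.na(.data$resolution) | .data$resolution > max_resolution ~ "resolution",
        .data$n_interface < min_interface ~ "few_interface_residues",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    ) |>
    dplyr::select(dplyr::all_of(c("chain", "keep", "reason")))
}

#' Read a multi-chain structure from a PDB file
#'
#' Parses standard-residue ATOM records of the first model via
#' `bio3d::read.pdb()`. Full sequences are reconstructed from residue
#' numbering: position `i` of a chain is its residue numbered `i`
#' (after shifting each chain so its first residue is 1 when
#' `renumber = TRUE`); numbering gaps become unresolved positions with
#' residue type `X`. When `chains` metadata with authoritative full
#' sequences is supplied, observed residues are mapped onto them instead —
#' directly when the numbering is consistent, otherwise through a local
#' alignment of the observed residue string against the full sequence.
#'
#' @param file PDB file path.
#' @param chains Optional chain metadata tibble (`chain`, `sequence`, and
#'   optionally `species`, `method`, `resolution`).
#' @param renumber Shift each chain's numbering to start at 1.
#' @return A [ppi_complex()].
#' @export
read_pdb_complex <- function(file, chains = NULL, renumber = is.null(chains)) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  a <- as_tibble(pdb$atom)
  a <- a[a$type == "ATOM" & a$resid %in% names(aa_three_to_one()), , drop = FALSE]
  atoms <- tibble(
    chain = as.character(a$chain),
    resno = as.integer(a$resno),
    aa = unname(aa_three_to_one()[a$resid]),
    atom = as.character(a$elety),
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(gsub("[0-9]", "", a$elety), 1, 1), a$elesy),
    x = a$x, y = a$y, z = a$z
  )
  # PDB chain identifiers are single characters; when supplied metadata uses
  # longer ids, re-identify chains by order of appearance
  pdb_chains <- unique(atoms$chain)
  if (!is.null(chains) && !all(pdb_chains %in% chains$chain)) {
    if (length(pdb_chains) != nrow(chains)) {
      abort("cannot match PDB chains to the supplied chain metadata",
            class = "homint_config_error")
    }
    atoms$chain <- setNames(chains$chain, pdb_chains)[atoms$chain]
  }
  out_chains <- list()
  out_atoms <- list()
  for (cid in unique(atoms$chain)) {
    ca <- atoms[atoms$chain == cid, , drop = FALSE]
    if (!is.null(chains) && cid %in% chains$chain) {
      meta <- chains[chains$chain == cid, , drop = FALSE]
      full <- meta$sequence
      ca <- map_atoms_to_sequence(ca, full)
      out_chains[[cid]] <- tibble(
        chain = cid, sequence = full,
        species = meta$species %||% NA_character_,
        method = meta$method %||% "xray",
        resolution = meta$resolution %||% NA_real_
      )
    } else {
      if (renumber) ca$resno <- ca$resno - min(ca$resno) + 1L
      full <- rep("X", max(ca$resno))
      res <- dplyr::distinct(ca, .data$resno, .data$aa)
      full[res$resno] <- res$aa
      out_chains[[cid]] <- tibble(chain = cid, sequence = paste(full, collapse = ""),
                                  species = NA_character_, method = "xray",
                                  resolution = NA_real_)
    }
    out_atoms[[cid]] <- ca
  }
  ppi_complex(dplyr::bind_rows(out_atoms), dplyr::bind_rows(out_chains))
}

# place observed residues onto an authoritative full sequence: trust the
# numbering when consistent, otherwise locally align the observed residue
# string and renumber from the alignment.
map_atoms_to_sequence <- function(atoms, full_sequence) {
  seq <- strsplit(full_sequence, "")[[1]]
  res <- dplyr::distinct(atoms, .data$resno, .data$aa)
  direct_ok <- all(res$resno >= 1 & res$resno <= length(seq)) &&
    all(seq[res$resno] == res$aa)
  if (direct_ok) return(atoms)
  obs <- paste(res$aa[order(res$resno)], collapse = "")
  aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(obs),
                                       Biostrings::AAString(full_sequence),
                                       type = "local", gapOpening = 10, gapExtension = 2)
  qs <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ss <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  remap <- integer(0)
  for (k in seq_along(qs)) {
    if (qs[k] != "-") qi <- qi + 1L
    if (ss[k] != "-") si <- si + 1L
    if (qs[k] != "-" && ss[k] != "-" && qs[k] == ss[k]) remap[qi] <- si
  }
  old <- sort(unique(res$resno))
  new <- remap[match(atoms$resno, old)]
  keep <- !is.na(new)
  atoms <- atoms[keep, , drop = FALSE]
  atoms$resno <- new[keep]
  atoms
}

#' @rdname read_pdb_complex
#' @param cx A [ppi_complex()] to serialize.
#' @export
write_pdb_complex <- function(cx, file) {
  stopifnot(inherits(cx, "ppi_complex"))
  a <- cx$atoms
  # PDB holds one character per chain: map longer ids onto A, B, C, ...
  ids <- unique(a$chain)
  if (any(nchar(ids) > 1)) {
    a$chain <- setNames(LETTERS[seq_along(ids)], ids)[a$chain]
  }
  bio3d::write.pdb(
    pdb = NULL, file = file,
    xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
    type = rep("ATOM", nrow(a)),
    resno = a$resno,
    resid = unname(aa_one_to_three()[a$aa]),
    eleno = seq_len(nrow(a)),
    elety = a$atom,
    chain = a$chain,
    elesy = a$element
  )
  invisible(file)
}

aa_three_to_one <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
    GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V")
}

aa_one_to_three <- function() {
  setNames(names(aa_three_to_one()), unname(aa_three_to_one()))
}

#' Read and write per-residue label tracks
#'
#' The interchange format for interface labels is a TSV with columns
#' `chain`, `pos`, `aa`, `label` — the same format the predictors consume
#' for template labels.
#'
#' @param file TSV path.
#' @return `read_labels_tsv()`: a label tibble.
#' @export
read_labels_tsv <- function(file) {
  readr::read_tsv(file, col_types = readr::cols(
    chain = "c", pos = "i", aa = "c", label = "c"
  ), progress = FALSE)
}

#' @rdname read_labels_tsv
#' @param labels Label tibble.
#' @export
write_labels_tsv <- function(labels, file) {
  readr::write_tsv(labels, file, progress = FALSE)
  invisible(file)
}
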