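# frozen oracle values computed once with an independent Shrake-Rupley
# implementation (biotite 1.4.0, Fibonacci sampling, Bondi single-element
# radii, probe 1.4, 2000 points)
test_that("solvent accessibility matches an independent implementation", {
  atoms <- tibble::tibble(
    chain = "A", resno = 1L, aa = "A", atom = c("C1", "N1", "O1", "S1"),
    element = c("C", "N", "O", "S"),
    x = c(0, 1.4, -1.2, 0.5), y = c(0, 0, 1.1, -1.3), z = c(0, 0.3, 0, 2.8)
  )
  s <- atom_sasa(atoms, n_points = 2000)
  expect_equal(s, c(28.1981, 45.0558, 60.0553, 88.9176), tolerance = 1e-3)
  ala <- tibble::tibble(
    chain = "A", resno = 1L, aa = "A",
    atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
    x = c(1.458, 0, -0.551, 0.189, -0.540),
    y = c(0, 0, 1.420, 2.400, -0.740),
    z = c(0, 0, 0, 0, -1.210)
  )
  expect_equal(sum(atom_sasa(ala, n_points = 2000)), 207.5661, tolerance = 1e-2)
})

test_that("relative accessibility flags exposure and burial correctly", {
  # an isolated residue is maximally exposed: above the folded-context
  # reference by construction
  iso <- ppi_complex(
    tibble::tibble(chain = "A", resno = 1L, aa = "A", atom = "CA",
                   element = "C", x = 0, y = 0, z = 0),
    tibble::tibble(chain = "A", sequence = "A", species = NA, method = "xray",
                   resolution = 2)
  )
  r <- relative_asa(iso, n_points = 500)
  expect_gte(r$rasa, 0.9)
  # a residue at the centre of a close-packed same-chain cluster is buried
  shell <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3), z = c(-3, 0, 3)))
  shell <- shell[rowSums(shell^2) > 0, ]
  atoms <- dplyr::bind_rows(
    tibble::tibble(chain = "A", resno = 1L, aa = "G", atom = "CA", element = "C",
                   x = 0, y = 0, z = 0),
    tibble::tibble(chain = "A", resno = 2L, aa = "G", atom = paste0("X", seq_len(nrow(shell))),
                   element = "C", x = shell[, 1], y = shell[, 2], z = shell[, 3])
  )
  cx <- ppi_complex(atoms, tibble::tibble(chain = "A", sequence = "GG",
                                          species = NA, method = "xray", resolution = 2))
  r2 <- relative_asa(cx, n_points = 500)
  expect_lt(r2$rasa[r2$pos == 1], 0.05)
  # unresolved positions carry NA accessibility
  part <- ppi_complex(
    tibble::tibble(chain = "A", resno = 2L, aa = "G", atom = "CA", element = "C",
                   x = 0, y = 0, z = 0),
    tibble::tibble(chain = "A", sequence = "AGA", species = NA, method = "xray",
                   resolution = 2)
  )
  r3 <- relative_asa(part, n_points = 100)
  expect_equal(is.na(r3$rasa), c(TRUE, FALSE, TRUE))
  # empty chain: empty track with NA everywhere
  expect_warning(
    relative_asa(ppi_complex(
      tibble::tibble(chain = "A", resno = 1L, aa = "X", atom = "CA", element = "C",
                     x = 0, y = 0, z = 0),
      tibble::tibble(chain = "A", sequence = "X", species = NA, method = "xray",
                     resolution = 2)
    ), n_points = 50),
    "unknown residue"
  )
})

test_that("interface labels are exactly the contacting surface residues", {
  cx <- two_chain_fixture(gap = 3.5)
  lab <- label_interfaces(cx, n_points = 240)
  expect_equal(lab$label[lab$chain == "A"], c("0", "0", "1", "0", "0"))
  expect_equal(lab$label[lab$chain == "B"], c("0", "0", "1", "0", "0"))
  # widening the gap past the cutoff removes every interface label
  far <- label_interfaces(two_chain_fixture(gap = 4.5), n_points = 240)
  expect_true(all(far$label == "0"))
  # exact-boundary contact is inclusive
  at4 <- label_interfaces(two_chain_fixture(gap = 4.0), n_points = 240)
  expect_equal(sum(at4$label == "1"), 2)
})

test_that("a buried residue is never an interface residue despite contact", {
  cx <- two_chain_fixture(gap = 3.5)
  # entomb residue 3 of chain A in same-chain shell atoms (partner side open
  # enough to keep the 3.5 A contact, but accessibility collapses)
  shell <- as.matrix(expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5),
                                 z = c(-2.5, 0, 2.5)))
  shell <- shell[rowSums(shell^2) > 0, ]
  extra <- tibble::tibble(
    chain = "A", resno = 4L, aa = "S",   # shell belongs to a neighbouring residue
    atom = paste0("S", seq_len(nrow(shell))), element = "C",
    x = 16 + shell[, 1], y = shell[, 2], z = shell[, 3]
  )
  atoms <- dplyr::bind_rows(cx$atoms, extra) |> dplyr::arrange(chain, resno)
  cx2 <- ppi_complex(atoms, cx$chains)
  r <- relative_asa(cx2, n_points = 240)
  expect_lt(r$rasa[r$chain == "A" & r$pos == 3], 0.05)
  lab <- label_interfaces(cx2, n_points = 240)
  expect_equal(lab$label[lab$chain == "A" & lab$pos == 3], "0")
  # chain B still sees a contact: its partner atoms did not move
  expect_equal(lab$label[lab$chain == "B" & lab$pos == 3], "1")
})

test_that("grid-based contact search equals the brute-force scan on random complexes", {
  for (seed in 1:10) {
    sim <- make_complex(seed = seed, len_range = c(10, 16), contact_patch_size = 3)
    got <- label_interfaces(sim$complex, n_points = 120)
    want <- brute_force_labels(sim$complex, n_points = 120)
    expect_equal(got, want, info = paste("seed", seed))
    expect_equal(got, sim$labels, info = paste("seed", seed))
  }
})

test_that("contact labelling is symmetric and monotone in the cutoff", {
  sim <- make_complex(seed = 99, contact_patch_size = 5)
  l4 <- label_interfaces(sim$complex, dist_cutoff = 4, n_points = 120)
  l6 <- label_interfaces(sim$complex, dist_cutoff = 6, n_points = 120)
  for (cid in unique(l4$chain)) {
    other <- setdiff(unique(l4$chain), cid)
    if (any(l4$label[l4$chain == cid] == "1")) {
      expect_true(any(l4$label[l4$chain %in% other] == "1"))
    }
  }
  was_1 <- l4$label == "1"
  expect_true(all(l6$label[was_1] == "1"))
})

test_that("unresolved residues are question marks on full-sequence coordinates", {
  sim <- make_complex(seed = 13, len_range = c(20, 24), contact_patch_size = 3,
                      unresolved_frac = 0.3)
  lab <- label_interfaces(sim$complex, n_points = 120)
  expect_equal(lab, sim$labels)
  expect_gt(sum(lab$label == "?"), 0)
  for (cid in unique(lab$chain)) {
    expect_equal(nrow(lab[lab$chain == cid, ]),
                 nchar(sim$complex$chains$sequence[sim$complex$chains$chain == cid]))
  }
})

test_that("template retention applies method, resolution and interface-count rules", {
  labels <- dplyr::bind_rows(
    tibble::tibble(chain = "ok", pos = 1:10, aa = "A",
                   label = c(rep("1", 4), rep("0", 6))),
    tibble::tibble(chain = "sparse", pos = 1:10, aa = "A",
                   label = c("1", "1", rep("0", 8))),
    tibble::tibble(chain = "nmr", pos = 1:10, aa = "A", label = "1"),
    tibble::tibble(chain = "coarse", pos = 1:10, aa = "A", label = "1")
  )
  chains <- tibble::tibble(
    chain = c("ok", "sparse", "nmr", "coarse"),
    sequence = strrep("A", 10),
    species = NA, method = c("xray", "xray", "nmr", "xray"),
    resolution = c(2.0, 2.0, NA, 3.6)
  )
  got <- filter_templates(chains, labels)
  expect_equal(got$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(got$reason, c(NA, "few_interface_residues", "method", "resolution"))
})

test_that("structures round-trip through pdb files", {
  sim <- make_complex(seed = 7, len_range = c(12, 15), contact_patch_size = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_complex(sim$complex, f)
  back <- read_pdb_complex(f, chains = sim$complex$chains)
  expect_equal(back$atoms$resno, sim$complex$atoms$resno)
  expect_equal(back$atoms$aa, sim$complex$atoms$aa)
  expect_equal(back$atoms$x, sim$complex$atoms$x, tolerance = 1e-3)
  expect_equal(back$chains$sequence, sim$complex$chains$sequence)
  expect_equal(label_interfaces(back, n_points = 120),
               label_interfaces(sim$complex, n_points = 120))
  # without metadata, single-letter PDB chain ids and 1-based numbering
  anon <- read_pdb_complex(f)
  expect_equal(nrow(anon$chains), nrow(sim$complex$chains))
  expect_equal(min(anon$atoms$resno), 1L)
})

test_that("inconsistent residue numbering falls back to sequence alignment", {
  sim <- make_complex(seed = 8, len_range = c(20, 22), contact_patch_size = 3)
  shifted <- sim$complex$atoms
  shifted$resno <- shifted$resno + 50L   # e.g. author numbering offset
  f <- withr::local_tempfile(fileext = ".pdb")
  shifted_cx <- structure(list(atoms = shifted, chains = sim$complex$chains),
                          class = "ppi_complex")
  write_pdb_complex(shifted_cx, f)
  back <- read_pdb_complex(f, chains = sim$complex$chains)
  expect_equal(back$atoms$resno, sim$complex$atoms$resno)
})

test_that("label tracks round-trip through tsv", {
  sim <- make_complex(seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_labels_tsv(sim$labels, f)
  expect_equal(read_labels_tsv(f), sim$labels)
})
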