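# helper: hand-written mmCIF with the same content as a chain
write_cif_fixture <- function(x, path) {
  lines <- c("data_synth", "#", "loop_", "_atom_site.group_PDB",
             "_atom_site.id", "_atom_site.type_symbol",
             "_atom_site.label_atom_id", "_atom_site.label_alt_id",
             "_atom_site.label_comp_id", "_atom_site.label_asym_id",
             "_atom_site.label_entity_id", "_atom_site.label_seq_id",
             "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
             "_atom_site.Cartn_y", "_atom_site.Cartn_z",
             "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
             "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
             "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
             "_atom_site.pdbx_PDB_model_num")
  k <- 0L
  for (ch in x$chains) for (i in seq_along(ch$bases)) {
    for (a in cssr_atom_types()) {
      co <- ch$xyz[[a]][i, ]
      if (is.na(co[1])) next
      k <- k + 1L
      nm <- if (a == "N") {
        if (ch$bases[i] %in% c("A", "G")) "N9" else "N1"
      } else a
      nmq <- paste0('"', nm, '"')
      lines <- c(lines, sprintf(
        'ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1',
        k, substr(nm, 1, 1), nmq, ch$bases[i], ch$chain_id, i,
        co[1], co[2], co[3], i, ch$bases[i], ch$chain_id, nmq))
    }
  }
  writeLines(c(lines, "#"), path)
  path
}

test_that("PDB round-trip preserves sequence, atoms and coordinates", {
  fx <- make_hairpin(8, 4, seed = 21, gu_frac = 0.2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$structure, f)
  x2 <- read_structure(f)
  expect_identical(structure_sequences(x2),
                   structure_sequences(fx$structure))
  for (a in cssr_atom_types()) {
    m1 <- fx$structure$chains[[1]]$xyz[[a]]
    m2 <- x2$chains[[1]]$xyz[[a]]
    expect_identical(is.na(m1), is.na(m2))
    expect_lt(max(abs(m1 - m2), na.rm = TRUE), 1e-3)
  }
  # two-chain duplex keeps its TER-separated chains
  d <- make_duplex(6, seed = 22)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(d$structure, f2)
  x3 <- read_structure(f2)
  expect_length(x3$chains, 2L)
  expect_identical(structure_sequences(x3),
                   structure_sequences(d$structure))
})

test_that("atom counting and P-only filtering behave by construction", {
  d <- make_duplex(10, seed = 23)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(new_rna_structure_for_test(d$structure$chains[1]), f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "ATOM")), 100L)  # 10 atoms x 10 nt
  expect_equal(sum(startsWith(lines, "TER")), 1L)
  p_only <- read_structure(f, atom_subset = "P")
  counts <- vapply(cssr_atom_types(), function(a)
    sum(!is.na(p_only$chains[[1]]$xyz[[a]][, 1])), integer(1))
  expect_equal(unname(counts[["P"]]), 10L)
  expect_equal(sum(counts), 10L)   # exactly one coordinate per nucleotide
})

test_that("atom-subset retention is monotone under subset inclusion", {
  fx <- make_hairpin(6, 4, seed = 24)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$structure, f)
  A <- c("P", "C4'")
  B <- c("P", "C4'", "C1'", "N")
  xa <- read_structure(f, atom_subset = A)
  xb <- read_structure(f, atom_subset = B)
  for (a in A) {
    ina <- !is.na(xa$chains[[1]]$xyz[[a]][, 1])
    inb <- !is.na(xb$chains[[1]]$xyz[[a]][, 1])
    expect_true(all(!ina | inb))
  }
})

test_that("non-RNA and garbled inputs raise distinct errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), class = "cssr_no_rna_error")
  g <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", g)
  err <- tryCatch(read_structure(g), error = function(e) e)
  expect_false(inherits(err, "cssr_no_rna_error") && FALSE)
  expect_true(inherits(err, "cssr_parse_error") ||
                inherits(err, "cssr_no_rna_error"))
  expect_error(read_structure(tempfile()), class = "cssr_io_error")
})

test_that("mmCIF parses to the same structure as PDB", {
  fx <- make_hairpin(6, 4, seed = 25)
  f <- withr::local_tempfile(fileext = ".cif")
  write_cif_fixture(fx$structure, f)
  x2 <- read_structure(f)
  expect_identical(structure_sequences(x2),
                   structure_sequences(fx$structure))
  expect_lt(max(abs(x2$chains[[1]]$xyz$P - fx$structure$chains[[1]]$xyz$P)),
            1e-3)
})

test_that("modified residues map to parent bases; unknowns are retained as X", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P   PSU A   1       0.000   0.000   0.000  1.00  0.00           P",
    "ATOM      2  C1' PSU A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  P   1MG A   2       3.000   0.000   0.000  1.00  0.00           P",
    "ATOM      4  P   XYZ A   3       6.000   0.000   0.000  1.00  0.00           P",
    "ATOM      5  C1' XYZ A   3       7.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  x <- read_structure(f)
  expect_identical(unname(structure_sequences(x)), "UGX")
  # unknown bases can never enter a candidate pair
  expect_equal(nrow(candidate_pairs(x, min_separation = 1)), 1L)  # U:G only
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P  A  A A   1       1.000   0.000   0.000  0.40  0.00           P",
    "ATOM      2  P  B  A A   1       2.000   0.000   0.000  0.60  0.00           P",
    "ATOM      3  P  A  U A   2       5.000   0.000   0.000  0.50  0.00           P",
    "ATOM      4  P  B  U A   2       6.000   0.000   0.000  0.50  0.00           P",
    "END"), f)
  x <- read_structure(f)
  expect_equal(x$chains[[1]]$xyz$P[1, 1], 2.0)  # occupancy 0.6 wins
  expect_equal(x$chains[[1]]$xyz$P[2, 1], 5.0)  # tie -> first
})

test_that("multi-model files honor model_index", {
  fx <- make_duplex(4, seed = 26)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fx$structure, f1)
  body <- readLines(f1)
  body <- body[body != "END"]
  shifted <- add_noise(fx$structure, 1.0, seed = 9)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(shifted, f2)
  body2 <- readLines(f2)
  body2 <- body2[body2 != "END"]
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", body2, "ENDMDL", "END"), f)
  m1 <- read_structure(f, model_index = 1)
  m2 <- read_structure(f, model_index = 2)
  expect_lt(max(abs(m1$chains[[1]]$xyz$P - fx$structure$chains[[1]]$xyz$P)),
            1e-3)
  expect_gt(max(abs(m2$chains[[1]]$xyz$P - m1$chains[[1]]$xyz$P)), 0.1)
  expect_error(read_structure(f, model_index = 3), class = "cssr_io_error")
})

test_that("writing an empty structure errors", {
  expect_error(write_structure(structure(list(chains = list()),
                                         class = "rna_structure"),
                               tempfile()),
               "empty")
})
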