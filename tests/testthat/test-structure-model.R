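# Coordinate I/O: round trips, selection determinism, policy enforcement.

test_that("write/read round trip preserves the model", {
  m <- makeBentDimer(12, withBinder = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, f)
  m2 <- readStructure(f)
  a1 <- atomTable(m)
  a2 <- atomTable(m2)
  expect_identical(nrow(a1), nrow(a2))
  expect_identical(a1$chain, a2$chain)
  expect_identical(a1$resno, a2$resno)
  expect_identical(a1$resid, a2$resid)
  expect_identical(trimws(a1$elety), trimws(a2$elety))
  expect_lt(max(abs(coordMatrix(a1) - coordMatrix(a2))), 1e-3)
  # read(write(read(f))) identical to read(f)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m2, f2)
  m3 <- readStructure(f2)
  expect_equal(atomTable(m3), atomTable(m2))
})

test_that("written PDB is parseable by an independent reader", {
  m <- makeBentDimer(18.2)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m, f)
  ext <- bio3d::read.pdb(f, verbose = FALSE)
  expect_identical(nrow(ext$atom), nrow(atomTable(m)))
  expect_lt(max(abs(cbind(ext$atom$x, ext$atom$y, ext$atom$z) -
                  coordMatrix(atomTable(m)))), 1e-3)
  expect_setequal(unique(ext$atom$chain), chainIds(m))
})

test_that("a minimal hand-written PDB parses to the expected model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tinyPdbLines(), f)
  m <- readStructure(f)
  expect_identical(chainIds(m), "A")
  expect_identical(nrow(unique(atomTable(m)[, c("resno", "insert")])), 2L)
})

test_that("a minimal mmCIF parses via the mmcif branch", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TEST",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    paste("ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00",
          "? 1 ALA A CA 1"),
    paste("ATOM 2 C CA . GLY A 1 2 ? 4.000 5.000 6.000 1.00 0.00",
          "? 2 GLY A CA 1")), f)
  m <- readStructure(f)  # format auto-detected from extension
  expect_identical(m@sourceFormat, "mmcif")
  expect_identical(nrow(atomTable(m)), 2L)
  expect_equal(atomTable(m)$x, c(1, 4))
})

test_that("truncated coordinate records are a parse error, not a partial model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- tinyPdbLines()
  lines[3] <- substr(lines[3], 1, 40)  # chop a record mid-coordinates
  writeLines(lines, f)
  expect_error(readStructure(f), "truncated")
  expect_error(readStructure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  CA AALA A   1       0.000   0.000   0.000",
           "  0.40  0.00           C"),
    paste0("ATOM      2  CA BALA A   1       9.000   0.000   0.000",
           "  0.60  0.00           C"),
    paste0("ATOM      3  CA AGLY A   2       1.000   0.000   0.000",
           "  0.50  0.00           C"),
    paste0("ATOM      4  CA BGLY A   2       8.000   0.000   0.000",
           "  0.50  0.00           C"),
    "END"), f)
  at <- atomTable(readStructure(f))
  expect_identical(nrow(at), 2L)
  expect_equal(at$x[at$resno == 1], 9)      # higher occupancy wins
  expect_equal(at$x[at$resno == 2], 1)      # tie broken by altloc letter
})

test_that("selection is deterministic, supports filters, flags bad chains", {
  helix <- makeIdealHelix(30)
  sel <- selectAtoms(helix, chains = "A", residues = 1:10, atomNames = "CA")
  expect_identical(nrow(sel), 10L)
  sel2 <- selectAtoms(helix, chains = "A", residues = 224:243 - 200)
  expect_identical(selectAtoms(helix, chains = "A"),
                   selectAtoms(helix, chains = "A"))
  expect_error(selectAtoms(helix, chains = "Z"), "no such chain")
  expect_identical(nrow(selectAtoms(helix, residues = integer(0))), 0L)
  # 20 residues out of a 30-residue helix
  expect_identical(nrow(selectAtoms(helix, residues = 5:24,
                                    atomNames = "CA")), 20L)
})

test_that("heavyOnly drops hydrogens and writeStructure enforces format", {
  at <- data.frame(chain = "A", resno = c(1L, 1L), resid = "ALA",
                   elety = c("CA", "HA"), elesym = c("C", "H"),
                   x = c(0, 1), y = 0, z = 0)
  m <- structureFromAtoms("hmodel", at)
  expect_identical(nrow(selectAtoms(m, heavyOnly = TRUE)), 1L)
  expect_identical(nrow(selectAtoms(m)), 2L)
  bad <- structureFromAtoms("bad", transform(at, chain = "AB"))
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(writeStructure(bad, f), "format error")
  m2 <- makeBentDimer(1.1)
  writeStructure(m2, f)
  expect_identical(sort(unique(bio3d::read.pdb(f, verbose = FALSE)$atom$chain)),
                   c("A", "B"))
})
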