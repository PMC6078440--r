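test_that("Sparky peak-list parsing maps fields and skips headers", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("Assignment w1 w2 Height",
               "G68N-H 109.8 8.42 1.2e6"), f)
  pk <- read_sparky_peaklist(f)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$w1, 109.8)
  expect_equal(pk$w2, 8.42)
  expect_equal(pk$height, 1.2e6)
  expect_equal(pk$label, "G68N-H")

  writeLines("Assignment w1 w2", f)
  expect_warning(pk0 <- read_sparky_peaklist(f), "No data rows")
  expect_equal(nrow(pk0), 0)

  writeLines(c("?-? 115.2 8.10", "G9N-H 109.1 8.30 2e5"), f)
  pk2 <- read_sparky_peaklist(f)
  expect_true(is.na(pk2$label[1])) # ?-? means unassigned
  expect_equal(nrow(pk2), 2)      # nothing silently dropped
})

test_that("Sparky parsing errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".list")
  writeLines(c("A1N-H 115.0 8.2", "A2N-H 116.0 8.2x3"), f)
  expect_error(read_sparky_peaklist(f), "line 2")
  writeLines(character(), f)
  expect_warning(expect_equal(nrow(read_sparky_peaklist(f)), 0),
                 "Empty peak list")
})

test_that("peak lists round-trip losslessly through the Sparky format", {
  pk <- random_peaklist(50, seed = 11)
  f <- withr::local_tempfile(fileext = ".list")
  write_sparky_peaklist(pk, f)
  back <- read_sparky_peaklist(f)
  expect_equal(as.data.frame(back), as.data.frame(pk))
})

test_that("peak-list construction enforces uniqueness and warns off-window", {
  expect_error(peaklist(data.frame(w1 = c(110, 110), w2 = c(8, 8),
                                   label = c("a", "a"))), "Duplicate")
  expect_warning(peaklist(data.frame(w1 = 50, w2 = 8)), "amide window")
  expect_silent(pk <- peaklist(data.frame(w1 = 110, w2 = 8,
                                          height = -5)))
  expect_equal(pk$height, -5) # negative artifact peaks allowed
})

test_that("TSV shift tables read prolines as missing and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\taa\tH\tN",
               "10\tG\t8.31\t109.2",
               "11\tP\t\t",
               "12\tA\t8.10\t122.9"), f)
  st <- read_shift_table(f, dialect = "tsv")
  expect_equal(nrow(st), 3)
  expect_true(is.na(st$H[2]) && is.na(st$N[2]))

  big <- random_shift_table(200, seed = 5)
  write_shift_table(big, f, dialect = "tsv")
  expect_equal(as.data.frame(read_shift_table(f, "tsv")),
               as.data.frame(big))
})

test_that("NMR-STAR chemical-shift loops read and round-trip", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_",
               "_Atom_chem_shift.Comp_index_ID",
               "_Atom_chem_shift.Comp_ID",
               "_Atom_chem_shift.Atom_ID",
               "_Atom_chem_shift.Val",
               "68 GLY H 8.42",
               "68 GLY N 109.8",
               "stop_"), f)
  st <- read_shift_table(f, dialect = "nmrstar")
  expect_equal(st$residue, 68)
  expect_equal(st$aa, "G")
  expect_equal(st$H, 8.42)
  expect_equal(st$N, 109.8)

  big <- random_shift_table(60, seed = 9)
  write_shift_table(big, f, dialect = "nmrstar")
  expect_equal(as.data.frame(read_shift_table(f, "nmrstar")),
               as.data.frame(big))

  writeLines(c("data_x", "loop_",
               "_Atom_chem_shift.Comp_index_ID",
               "_Atom_chem_shift.Comp_ID",
               "_Atom_chem_shift.Atom_ID",
               "_Atom_chem_shift.Val",
               "68 GLY H 8.42",
               "68 GLY H 8.43",
               "stop_"), f)
  expect_error(read_shift_table(f, "nmrstar"), "Duplicate")
})

test_that("shift-table invariants reject bad input", {
  expect_error(shift_table(data.frame(residue = c(2, 1), aa = c("A", "G"),
                                      H = 8, N = 120)),
               "strictly increasing")
  expect_error(shift_table(data.frame(residue = 1, aa = "Z",
                                      H = 8, N = 120)), "Unknown")
  expect_error(shift_table(data.frame(residue = 1, aa = "P",
                                      H = 8, N = 120)), "Proline")
})

test_that("multi-model PDB files read with roster checks and round-trip", {
  tpl <- make_helix_template(5)
  ens <- generate_ensemble(tpl, sigma = 0.2, n_models = 3, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ensemble(ens, f)
  back <- read_pdb_ensemble(f)
  expect_equal(length(unique(back$model)), 3)
  expect_equal(as.data.frame(back), as.data.frame(ens))

  write_pdb_ensemble(tpl, f) # single implicit model
  one <- read_pdb_ensemble(f)
  expect_equal(unique(one$model), 1L)
  expect_equal(nrow(one), nrow(tpl))

  # drop one atom from model 2 -> roster error naming it
  write_pdb_ensemble(ens, f)
  lines <- readLines(f)
  drop <- grep("^ATOM", lines)[25] # some atom inside model 2
  writeLines(lines[-drop], f)
  expect_error(read_pdb_ensemble(f), "roster in model 2")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00",
    "ATOM      3  N   ALA A   1       2.000   0.000   0.000  1.00  0.00",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00",
    "END"), f)
  ens <- read_pdb_ensemble(f)
  expect_equal(nrow(ens), 3)
  expect_equal(ens$x[ens$elety == "CA"], 1.0)
})

test_that("binding curves round-trip through CSV", {
  bc <- generate_binding_curve(KD = 1e-7, Rmax = 1.2,
                               conc_M = c(1, 3, 10, 30, 100) * 1e-9,
                               sigma = 0.01, seed = 2,
                               analyte_label = "LRP6 E1E2")
  f <- withr::local_tempfile(fileext = ".csv")
  write_binding_curve(bc, f)
  back <- read_binding_curve(f, analyte_label = "LRP6 E1E2")
  expect_equal(back$conc_M, bc$conc_M)
  expect_equal(back$response_nm, bc$response_nm)
  expect_error(binding_curve(data.frame(conc_M = -1, response_nm = 0)),
               ">= 0")
})
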