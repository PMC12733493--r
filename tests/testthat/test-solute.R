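# Solute preparation: PQR I/O, parameter assignment, bookkeeping

test_that("a single-record PQR yields one atom with its charge and radius", {
  tf <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  CL  ION     1       0.000   0.000   0.000 -1.0000 2.0000"),
    tf)
  s <- read_pqr(tf)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$net_charge, -1)
  expect_equal(s$atoms$radius, 2.0)
  # sigma derived from radius when LJ not supplied
  expect_equal(s$atoms$sigma, 2 * 2.0 / 2^(1 / 6))
})

test_that("an empty PQR is rejected", {
  tf <- withr::local_tempfile(fileext = ".pqr")
  writeLines("REMARK nothing here", tf)
  expect_error(read_pqr(tf), "empty solute")
  expect_error(read_pqr(file.path(tempdir(), "no-such-file.pqr")),
               "no such file")
})

test_that("PQR write/read round-trips coordinates, charges and LJ terms", {
  s <- make_toy_solute(fixture_recipe("polyatomic_random", n = 12L, seed = 7L))
  tf <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(s, tf)
  s2 <- read_pqr(tf)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
  # charges print at 4 decimals, LJ remarks at 6
  expect_lt(max(abs(s2$atoms$charge - s$atoms$charge)), 1e-4)
  expect_lt(max(abs(s2$atoms$sigma - s$atoms$sigma)), 1e-5)
  expect_lt(max(abs(s2$atoms$epsilon - s$atoms$epsilon)), 1e-5)
  expect_lt(abs(s2$net_charge - s$net_charge), 1e-3)
})

# small complete PDB + toy table used for assignment tests
write_toy_pdb <- function(path, with_ssbond = FALSE) {
  lines <- c(
    if (with_ssbond)
      "SSBOND   1 CYS A    1    CYS A    2",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   GLY A   1      -0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      4  N   ALA A   2       2.000   1.300   0.000  1.00  0.00           N",
    "ATOM      5  CA  ALA A   2       3.450   1.300   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, path)
}

toy_table <- function() {
  read_parameter_table(textConnection("
# residue atom charge sigma epsilon radius
GLY N  -0.40 3.25 0.17 1.55
GLY CA  0.10 3.40 0.11 1.70
GLY H   0.30 1.07 0.02 1.20
ALA N  -0.40 3.25 0.17 1.55
ALA CA  0.40 3.40 0.11 1.70
"))
}

test_that("parameter assignment attaches charges and reports net charge", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(tf)
  s <- assign_parameters(tf, toy_table())
  expect_equal(nrow(s$atoms), 5L)
  expect_equal(s$net_charge, sum(s$atoms$charge))
  expect_equal(s$net_charge, 0, tolerance = 1e-12)
  expect_equal(s$atoms$sigma[1], 3.25)
  # idempotence: assigning twice gives an identical system
  s2 <- assign_parameters(tf, toy_table())
  expect_identical(s$atoms, s2$atoms)
})

test_that("a missing parameter entry raises an error naming the atom", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(tf)
  tb <- toy_table()
  tb <- tb[!(tb$residue == "ALA" & tb$atom == "CA"), ]
  expect_error(assign_parameters(tf, tb), "ALA CA")
})

test_that("disulfide cysteines are retyped before lookup", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "SSBOND   1 CYS A    1    CYS A    2",
    "ATOM      1  SG  CYS A   1       0.000   0.000   0.000  1.00  0.00           S",
    "ATOM      2  SG  CYS A   2       2.050   0.000   0.000  1.00  0.00           S",
    "END"), tf)
  tb <- read_parameter_table(textConnection("
CYX SG -0.10 3.56 0.25 1.80
"))
  st <- read_pdb_structure(tf)
  expect_equal(nrow(st$ssbond), 1L)
  s <- assign_parameters(st, tb)
  expect_true(all(s$atoms$resid == "CYX"))
  expect_equal(nrow(s$disulfides), 1L)
  # without the SSBOND record the CYX-only table cannot match
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(readLines(tf)[-1], tf2)
  expect_error(assign_parameters(tf2, tb), "CYS SG")
})

test_that("protonation variants redirect the table lookup", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  ND1 HIS A   9       0.000   0.000   0.000  1.00  0.00           N",
    "END"), tf)
  tb <- read_parameter_table(textConnection("
HID ND1 -0.38 3.25 0.17 1.55
"))
  expect_error(assign_parameters(tf, tb), "HIS ND1")
  spec <- data.frame(resno = 9L, residue = "HID")
  s <- assign_parameters(tf, tb, protonation_spec = spec)
  expect_equal(s$atoms$resid, "HID")
  expect_equal(s$atoms$charge, -0.38)
})
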