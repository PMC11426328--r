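minimal_cif <- function(path) {
  atoms <- tibble::tibble(
    chain = rep(c("A", "B"), each = 3),
    resno = rep(1:3, 2),
    resid = "ALA", atom = "CA", element = "C",
    x = c(0, 4, 8, 0, 4, 8), y = rep(c(0, 20), each = 3), z = 0
  )
  write_mmcif(atoms, path, "MIN1")
  path
}

test_that("mmCIF parsing round-trips a two-chain fixture", {
  f <- minimal_cif(withr::local_tempfile(fileext = ".cif"))
  s <- read_structure(f)
  expect_setequal(unique(s$chain), c("A", "B"))
  expect_equal(nrow(resolved_residues(s)), 2)
  expect_equal(resolved_residues(s)$n_residues, c(3, 3))
  expect_true(all(s$is_heavy))
})

test_that("waters and other non-polymer entities are dropped", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, 4 * (1:3), 0, 0),
    sprintf("HETATM%5d  O   HOH B%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            4:43, 101:140, runif(40, 20, 30), runif(40, 20, 30),
            runif(40, 20, 30)),
    "END"
  )
  writeLines(lines, f)
  s <- read_structure(f)
  expect_equal(unique(s$chain), "A")
  expect_equal(nrow(s), 3)
})

test_that("multi-model files yield model 1 only", {
  f <- withr::local_tempfile(fileext = ".pdb")
  model_block <- function(k, shift) {
    c(sprintf("MODEL     %4d", k),
      sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
              1:4, 1:4, 4 * (1:4) + shift, 0, 0),
      "ENDMDL")
  }
  writeLines(c(unlist(lapply(1:5, function(k) model_block(k, k - 1))),
               "END"), f)
  s <- read_structure(f)
  # 4 residues, coordinates of the first model (shift 0)
  expect_equal(nrow(s), 4)
  expect_equal(s$x, 4 * (1:4))
})

test_that("altloc resolution keeps highest occupancy, ties favour A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AALA A   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       3.000   0.000   0.000  0.50  0.00           C",
    "END"
  ), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$x, c(1, 2)) # B wins residue 1 (0.6), A wins the tie
})

test_that("parse errors are informative", {
  expect_error(read_structure(file.path(tempdir(), "nope.cif")),
               "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), f)
  expect_error(read_structure(f), "polymer")
})

test_that("representative structure maximizes resolved residues", {
  cand <- tibble::tibble(
    structure_id = c("S1", "S2"), protein_a = "P", protein_b = "Q",
    resolved = c(300, 450)
  )
  expect_equal(select_representative_structure(cand)$structure_id, "S2")
  expect_equal(
    select_representative_structure(cand[1, ])$structure_id, "S1")
  tie <- tibble::tibble(
    structure_id = c("S1", "S0"), protein_a = "P", protein_b = "Q",
    resolved = c(300, 300)
  )
  expect_equal(select_representative_structure(tie)$structure_id, "S0")
  # unordered pairs collapse
  both <- tibble::tibble(
    structure_id = c("S1", "S2"),
    protein_a = c("P", "Q"), protein_b = c("Q", "P"),
    resolved = c(10, 20)
  )
  expect_equal(nrow(select_representative_structure(both)), 1)
  expect_error(select_representative_structure(cand[0, ]), "no candidate")
})

two_atom_fixture <- function(d) {
  tibble::tibble(
    structure_id = "T", chain = c("A", "B"), resno = 1L, insert = "",
    resid = "ALA", atom = "CA", element = "C",
    x = c(0, d), y = 0, z = 0, occupancy = 1, is_heavy = TRUE
  )
}

test_that("contact boundary is inclusive at the cutoff", {
  con <- residue_contacts(two_atom_fixture(5.9), "A", "B", cutoff = 6)
  expect_equal(nrow(con), 1)
  expect_equal(con$distance, 5.9, tolerance = 1e-12)
  expect_equal(nrow(residue_contacts(two_atom_fixture(6.01), "A", "B", 6)), 0)
})

test_that("contacts equal the brute-force all-pairs oracle", {
  for (seed in 1:20) {
    atoms <- random_atoms(30, seed)
    got <- residue_contacts(atoms, "A", "B", cutoff = 6)
    want <- brute_force_contacts(atoms, "A", "B", cutoff = 6)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$resno_a, want$resno_a)
    expect_equal(got$resno_b, want$resno_b)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("hydrogens are ignored in contact detection", {
  atoms <- two_atom_fixture(5)
  atoms$element[2] <- "H"
  atoms$is_heavy[2] <- FALSE
  expect_error(residue_contacts(atoms, "A", "B", 6), "heavy atom")
})

test_that("contact relation is symmetric and monotone in cutoff", {
  atoms <- random_atoms(25, 99)
  ab <- residue_contacts(atoms, "A", "B", 6)
  ba <- residue_contacts(atoms, "B", "A", 6)
  expect_equal(
    sort(paste(ab$resno_a, ab$resno_b)),
    sort(paste(ba$resno_b, ba$resno_a))
  )
  small <- residue_contacts(atoms, "A", "B", 5)
  expect_true(all(paste(small$resno_a, small$resno_b) %in%
                    paste(ab$resno_a, ab$resno_b)))
})

test_that("SASA of an isolated atom matches the sphere closed form", {
  one <- two_atom_fixture(1000)[1, ]
  s <- sasa(one, probe_radius = 1.4, n_points = 960)
  expect_equal(s$sasa, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
})

test_that("a fully enclosed atom has (near) zero SASA", {
  pts <- eeinet:::sphere_points(200) * 3.0
  shell <- tibble::tibble(
    structure_id = "S", chain = "A", resno = 2L, insert = "",
    resid = "ALA", atom = "C", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3], occupancy = 1,
    is_heavy = TRUE
  )
  center <- shell[1, ]
  center$x <- 0; center$y <- 0; center$z <- 0; center$resno <- 1L
  s <- sasa(dplyr::bind_rows(center, shell))
  expect_lt(s$sasa[s$resno == 1], 1e-6)
})

test_that("SASA is converged at the default point count", {
  atoms <- random_atoms(15, 3)
  s1 <- sasa(atoms, n_points = 960)
  s2 <- sasa(atoms, n_points = 1920)
  rel <- abs(s1$sasa - s2$sasa) / pmax(s2$sasa, 1)
  expect_lt(max(rel), 0.01)
})

test_that("separated chains share no interface", {
  atoms <- two_atom_fixture(100)
  ir <- interface_residues(atoms, "A", "B", n_points = 480)
  expect_equal(nrow(ir), 0)
  expect_equal(attr(ir, "interface_area"), 0, tolerance = 1e-9)
  expect_error(interface_residues(atoms, "A", "C"), "chain pair")
})

test_that("designed dimer interfaces are recovered exactly", {
  d <- withr::local_tempdir()
  pairs <- tibble::tibble(res_a = c(5, 10, 15, 20), res_b = c(6, 11, 16, 21))
  cx <- synthetic_complex(d, pairs, chain_lengths = c(25, 25), seed = 11)
  atoms <- read_structure(cx$paths$structure)
  ir <- interface_residues(atoms, "A", "B", n_points = 480)
  expect_setequal(ir$resno[ir$chain == "A"], pairs$res_a)
  expect_setequal(ir$resno[ir$chain == "B"], pairs$res_b)
  expect_true(all(ir$delta_sasa > 0))
  # area identity: half the total SASA loss
  sa <- sum(sasa(dplyr::filter(atoms, chain == "A"), n_points = 480)$sasa)
  sb <- sum(sasa(dplyr::filter(atoms, chain == "B"), n_points = 480)$sasa)
  sab <- sum(sasa(atoms, n_points = 480)$sasa)
  expect_equal(attr(ir, "interface_area"), (sa + sb - sab) / 2,
               tolerance = 1e-9)
})

test_that("interface area classification follows the 2200/440 thresholds", {
  expect_equal(classify_interface_area(2500), "bio")
  expect_equal(classify_interface_area(400), "xtal")
  expect_equal(classify_interface_area(1000), "indeterminate")
  # boundaries are strict on both sides
  expect_equal(classify_interface_area(2200), "indeterminate")
  expect_equal(classify_interface_area(440), "indeterminate")
  expect_error(classify_interface_area(-1), "nonnegative")
  # total order-preserving step function
  areas <- seq(0, 3000, by = 10)
  cls <- classify_interface_area(areas)
  lev <- c(xtal = 0, indeterminate = 1, bio = 2)
  expect_true(all(diff(lev[cls]) >= 0))
})
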