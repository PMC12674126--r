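# Coordinate I/O and the chain/residue/atom data model.

test_that("a minimal hand-written PDB parses into chains, residues, atoms", {
  path <- write_minimal_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147),
    pdb_atom_line(3, "O", "ALA", "A", 1, 12.000, 7.000, -4.000),
    "END"))
  s <- read_structure(path)
  expect_s3_class(s, "actin_structure")
  expect_equal(n_frames(s), 1L)
  expect_equal(nrow(s$atoms), 3L)
  ch <- select_chain(s, "A")
  expect_equal(length(unique(ch$resno)), 1L)
  expect_equal(ch$x[trimws(ch$elety) == "CA"], 11.639)
})

test_that("altloc records are retained on load and resolved by policy", {
  path <- write_minimal_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(3, "CB", "ALA", "A", 1, 2, 0, 0),
    "END"))
  s <- read_structure(path)
  ch <- select_chain(s, "A")
  expect_equal(nrow(ch), 3L)               # both alternates retained
  expect_setequal(ch$alt[trimws(ch$elety) == "CA"], c("A", "B"))

  r <- resolve_altlocs(ch)                  # highest occupancy wins
  expect_equal(nrow(r), 2L)
  expect_equal(r$x[trimws(r$elety) == "CA"], 0)

  # occupancy tie: broken by altloc letter order
  ch$o[ch$alt %in% c("A", "B")] <- 0.5
  r <- resolve_altlocs(ch)
  expect_equal(r$alt[trimws(r$elety) == "CA"], "A")

  # prefer_A policy keeps A regardless of occupancy
  ch$o[which(ch$alt == "A")] <- 0.1
  r <- resolve_altlocs(ch, policy = "prefer_A")
  expect_equal(r$alt[trimws(r$elety) == "CA"], "A")

  # chains without altlocs pass through untouched
  plain <- straight_chain(1:10)
  expect_identical(resolve_altlocs(plain), plain)
})

test_that("hetero records are kept but excluded from protein chains", {
  path <- write_minimal_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", " CA", "A", 501, 9, 9, 9, type = "HETATM", elesy = "CA"),
    pdb_atom_line(4, "O", "HOH", "A", 601, 5, 5, 5, type = "HETATM"),
    "END"))
  s <- read_structure(path)
  expect_equal(sum(s$atoms$type == "HETATM"), 2L)
  ch <- select_chain(s, "A")
  expect_equal(nrow(ch), 2L)
  expect_true(all(ch$resid == "ALA"))
})

test_that("multi-MODEL files become multi-frame structures", {
  model_block <- function(k, dx) c(
    sprintf("MODEL %8d", k),
    pdb_atom_line(1, "CA", "GLY", "g", 1, dx, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "g", 2, dx + 3.8, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "g", 3, dx + 7.6, 0, 0),
    "ENDMDL")
  path <- write_minimal_pdb(c(unlist(lapply(1:5, function(k)
    model_block(k, dx = k))), "END"))
  s <- read_structure(path)
  expect_equal(n_frames(s), 5L)
  ch3 <- select_chain(s, "g", frame = 3)
  expect_equal(ch3$x[1], 3)                 # frame-tagged coordinates
  expect_error(select_chain(s, "g", frame = 6), "out of range")
})

test_that("selecting a missing chain reports the available ids", {
  path <- write_minimal_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "B", 1, 5, 0, 0),
    "END"))
  s <- read_structure(path)
  expect_error(select_chain(s, "Z"), "available: A, B")
})

test_that("PDB round trip preserves coordinates to format precision", {
  s <- make_conformer(phi = -12.3, noise_sigma = 0.3, seed = 11)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_lt(max(abs(s2$frames[[1]] - s$frames[[1]])), 0.001 + 1e-9)
})

test_that("multi-frame structures write one MODEL block per frame", {
  tr <- make_gate_trajectory(p_open = 0.5, n_frames = 7, seed = 3)
  f <- tempfile(fileext = ".pdb")
  write_pdb(tr, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "MODEL")), 7L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 7L)
  s2 <- read_structure(f)
  expect_equal(n_frames(s2), 7L)
  expect_lt(max(abs(s2$frames[[5]] - tr$frames[[5]])), 0.001 + 1e-9)
})

test_that("residue numbers beyond the fixed-width range are refused", {
  at <- data.frame(elety = "CA", resno = 10000L, resid = "ALA", elesy = "C")
  s <- new_structure(at, matrix(c(0, 0, 0), 1))
  expect_error(write_pdb(s, tempfile(fileext = ".pdb")), "fixed-width")
})

test_that("a minimal mmCIF file parses", {
  cif <- c(
    "data_test",
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
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 O O . ALA A 1 1 ? 12.000 7.000 -4.000 1.00 0.00 ? 1 ALA A O 1",
    "#")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  s <- read_structure(path)
  expect_equal(nrow(s$atoms), 3L)
  ch <- select_chain(s, "A")
  expect_equal(ch$y[trimws(ch$elety) == "O"], 7.000)
})

test_that("unreadable input raises a parse error naming the file", {
  bad <- tempfile(fileext = ".pdb")
  expect_error(read_structure(bad), "not found")
})
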