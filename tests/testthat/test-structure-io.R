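minimal_pdb <- c(
  "ATOM      1  N   ALA A 432      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A 432      12.560   6.071  -6.342  1.00  0.00           C",
  "ATOM      3  OE1 GLU A 433      13.252   7.314  -6.503  1.00  0.00           O")

test_that("a hand-written PDB round-trips bit-exactly", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb, tf)
  m <- read_structure(tf)
  expect_s3_class(m, "monomer_model")
  expect_identical(nrow(m$atoms), 3L)
  expect_identical(m$atoms$x, c(11.104, 12.560, 13.252))
  expect_identical(m$atoms$resno, c(432L, 432L, 433L))
  expect_identical(m$atoms$name, c("N", "CA", "OE1"))
  expect_identical(m$atoms$element, c("N", "C", "O"))
  expect_true(all(m$atoms$is_heavy))

  tf2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, tf2)
  m2 <- read_structure(tf2)
  expect_identical(m2$atoms$x, m$atoms$x)
  expect_identical(m2$atoms$resname, m$atoms$resname)
})

test_that("two identical chains become a two-subunit filament", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(minimal_pdb,
               sub(" A ", " B ", minimal_pdb)), tf)
  f <- read_structure(tf)
  expect_s3_class(f, "filament_model")
  expect_identical(vapply(f$subunits, `[[`, 0L, "index"), c(0L, 1L))
  expect_rt_equal(f$subunits[[1L]]$transform, rigid_transform())
})

test_that("malformed and empty inputs are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  bad <- minimal_pdb
  substr(bad[2L], 31L, 38L) <- "  xx.yyy"
  writeLines(bad, tf)
  expect_error(read_structure(tf), "line 2")

  writeLines("REMARK nothing here", tf)
  expect_error(read_structure(tf), "empty coordinate set")
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
  expect_error(monomer_model(data.frame()), "empty")
})

test_that("synthetic models round-trip through PDB at fixed-width precision", {
  fil <- fx_filament(12)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(fil, tf)
  f2 <- read_structure(tf)
  expect_identical(n_subunits(f2), 12L)
  a1 <- do.call(rbind, lapply(fil$subunits, `[[`, "atoms"))
  a2 <- do.call(rbind, lapply(f2$subunits, `[[`, "atoms"))
  expect_identical(nrow(a2), nrow(a1))
  expect_identical(a2$name, a1$name)
  expect_identical(a2$resno, a1$resno)
  expect_lt(max(abs(a2$x - a1$x), abs(a2$y - a1$y), abs(a2$z - a1$z)),
            5e-4 + 1e-9)

  # property: random little monomers survive the round trip
  set.seed(17)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    m <- monomer_model(atom_table(1:n, "CA", "C", 1:n, "GLY", "A",
                                  x = round(runif(n, -99, 99), 3),
                                  y = round(runif(n, -99, 99), 3),
                                  z = round(runif(n, -99, 99), 3)))
    write_structure(m, tf)
    m2 <- read_structure(tf)
    expect_identical(nrow(m2$atoms), n)
    expect_equal(m2$atoms$x, m$atoms$x, tolerance = 1e-9)
  }
})

test_that("chain ids are exhausted beyond 62 subunits", {
  fil <- build_filament(fx_monomer(), rip2_params(), 63)
  expect_error(write_structure(fil, withr::local_tempfile(fileext = ".pdb")),
               "chain-id exhaustion")
})

test_that("the mmCIF atom_site loop is read", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "ATOM 1 N N ALA A 432 11.104 6.134 -6.504",
    "ATOM 2 C CA ALA A 432 12.560 6.071 -6.342",
    "#"), tf)
  m <- read_structure(tf)
  expect_identical(nrow(m$atoms), 2L)
  expect_identical(m$atoms$x, c(11.104, 12.560))
  expect_identical(m$atoms$resno, c(432L, 432L))

  writeLines(c("data_test", "loop_", "_foo.bar", "1"), tf)
  expect_error(read_structure(tf), "atom_site")
})

test_that("helix assignment is config-driven and validated", {
  mono <- fx_monomer()
  # construction ground truth is reproduced
  truth <- mono$helix_segments
  m2 <- assign_helices(mono, truth)
  expect_identical(m2$helix_segments[order(names(m2$helix_segments))],
                   truth[order(names(truth))])

  expect_error(assign_helices(mono, truth[c("H1", "H2", "H3", "H4")]), "H1..H5")
  bad <- truth
  bad$H2 <- c(truth$H1[2L] - 1L, truth$H2[2L])
  expect_error(assign_helices(mono, bad), "non-overlapping")

  # published patch residues land on their described helices
  rip2 <- monomer_model(atom_table(1:109, "CA", "C", 432:540, "ALA", "A",
                                   x = 1:109, y = 0, z = 0))
  rip2 <- assign_helices(rip2, rip2_helix_table())
  expect_identical(helix_of(rip2, c(439, 444, 445)), rep("H1", 3L))
  expect_identical(helix_of(rip2, c(458, 461)), rep("H2", 2L))
  expect_identical(helix_of(rip2, c(471, 474)), rep("H3", 2L))
  expect_identical(helix_of(rip2, 492), "H4")
  expect_identical(helix_of(rip2, c(501, 513)), rep("H5", 2L))
  expect_identical(helix_of(rip2, c(449, 467, 483, 495)), rep("loop", 4L))
})
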