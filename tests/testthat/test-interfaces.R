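toy_filament <- function(gap) {
  # two single-atom subunits separated by `gap` along y
  a0 <- atom_table(1L, "CA", "C", 1L, "ALA", "A", x = 5, y = 0, z = 0)
  a1 <- atom_table(1L, "CA", "C", 1L, "ALA", "B", x = 5, y = gap, z = 0)
  filament_model(list(list(index = 0L, transform = rigid_transform(), atoms = a0),
                      list(index = 1L, transform = rigid_transform(), atoms = a1)))
}

test_that("contacts respect the distance cutoff", {
  expect_identical(nrow(find_contacts(toy_filament(4.4))), 1L)
  expect_identical(nrow(find_contacts(toy_filament(4.6))), 0L)
  expect_identical(nrow(find_contacts(toy_filament(4.4), cutoff = 4.0)), 0L)
  one <- toy_filament(4.4); one$subunits <- one$subunits[1L]
  expect_identical(nrow(find_contacts(one)), 0L)
  expect_error(find_contacts(toy_filament(4.4), cutoff = -1), "positive")
  ct <- find_contacts(toy_filament(4.4))
  expect_true(all(ct$subunit_i < ct$subunit_j))
})

test_that("the canonical patch set matches the published residue lists", {
  p <- rip2_patches()
  expect_setequal(p$Ia, c(444, 445, 492))
  expect_setequal(p$Ib, c(458, 461, 471, 474))
  expect_setequal(p$IIa, c(495, 497, 472, 467))
  expect_setequal(p$IIb, c(449, 452, 513))
  expect_setequal(p$IIIa, c(479, 475, 471, 472))
  expect_setequal(p$IIIb, c(483, 482, 484, 488))
  # K471 and E472 belong to two patches each
  tab <- table(unlist(p))
  expect_identical(as.integer(tab[c("471", "472")]), c(2L, 2L))
})

test_that("neighbor_geometry reports the wrapped lattice offsets", {
  ng <- neighbor_geometry(rip2_params(), 6L)
  expect_equal(ng$dz, (1:6) * 4.936)
  expect_equal(ng$dtheta[1L], -101.4)
  expect_equal(ng$dtheta[4L], -45.6, tolerance = 1e-9)   # wrap(-405.6)
  expect_equal(ng$dtheta[3L], 55.8, tolerance = 1e-9)    # wrap(-304.2)
  expect_identical(ng$dk[which.min(abs(ng$dtheta))], 4L) # near-axial shell
  expect_error(neighbor_geometry(rip2_params(), 0L), ">= 1")
})

fig6_contacts <- function(pairs, si = 0L, sj = 1L) {
  data.frame(subunit_i = si, subunit_j = sj,
             residue_i = pairs[, 1L], residue_j = pairs[, 2L],
             min_dist = 3.0, patch_i = NA_character_, patch_j = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("the published contact networks classify as their interface types", {
  ctI <- fig6_contacts(rbind(c(444, 461), c(445, 458), c(492, 474)))
  clI <- classify_interface(ctI, rip2_patches())
  expect_identical(clI$assigned_type, "I")
  expect_equal(clI$support, 1.0)

  ctII <- fig6_contacts(rbind(c(449, 495), c(452, 497), c(513, 467)))
  clII <- classify_interface(ctII, rip2_patches())
  expect_identical(clII$assigned_type, "II")
  expect_equal(clII$support, 1.0)

  ctIII <- fig6_contacts(rbind(c(479, 483), c(475, 482), c(472, 488)))
  clIII <- classify_interface(ctIII, rip2_patches())
  expect_identical(clIII$assigned_type, "III")
  expect_equal(clIII$support, 1.0)

  # patchless contacts stay unclassified; empty lists are an error
  ctN <- fig6_contacts(rbind(c(900, 901), c(902, 903)))
  expect_identical(classify_interface(ctN, rip2_patches())$assigned_type,
                   "unclassified")
  expect_error(classify_interface(ctN[0, ], rip2_patches()), "empty")
})

test_that("dual-membership residues split their vote between matching pairings", {
  patches <- list(Ia = 1L, Ib = 2L, IIa = 9L, IIb = 8L, IIIa = 2L, IIIb = 1L)
  ct <- fig6_contacts(rbind(c(1, 2)))
  cl <- classify_interface(ct, patches)
  expect_equal(unname(cl$votes[c("I", "III")]), c(0.5, 0.5))
})

test_that("ground-truth synthetic filaments classify perfectly; decoys do not", {
  fil <- fx_filament(12)
  cls <- classify_filament_interfaces(fil)
  interior <- cls[cls$subunit_i >= 3L & cls$subunit_j <= 8L, ]
  mapped <- interior[interior$dk %in% c(1L, 3L, 4L), ]
  truth <- c(`1` = "III", `3` = "I", `4` = "II")
  expect_identical(mapped$assigned_type, unname(truth[as.character(mapped$dk)]))
  expect_true(all(mapped$support >= 0.5))
  # the unplanned dk = 2 shell stays unclassified
  expect_true(all(interior$assigned_type[interior$dk == 2L] == "unclassified"))

  dec <- make_patch_decoy(fx_monomer(), seed = 7L)
  fdec <- build_filament(dec, rip2_params(), 12)
  cdec <- classify_filament_interfaces(fdec)
  expect_gte(mean(cdec$assigned_type == "unclassified"), 0.5)
})

test_that("interior contact lists are invariant under index shift", {
  ct <- find_contacts(fx_filament(10))
  key <- function(df) sort(paste(df$residue_i, df$residue_j, sep = "-"))
  for (dk in c(1L, 3L, 4L)) for (k in 3L:4L) {
    a <- ct[ct$subunit_i == k & ct$subunit_j == k + dk, ]
    b <- ct[ct$subunit_i == k + 1L & ct$subunit_j == k + 1L + dk, ]
    expect_identical(key(a), key(b))
  }
})

test_that("surface sides partition the patch set as published", {
  ss <- surface_sides()
  expect_setequal(ss$top$residues, c(458, 461, 471, 474, 449, 452, 513))
  expect_setequal(ss$bottom$residues, c(444, 445, 492, 495, 497, 472, 467))
  expect_length(intersect(ss$top$residues, ss$bottom$residues), 0L)
  expect_setequal(ss$lateral$patches, c("IIIa", "IIIb"))
})
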