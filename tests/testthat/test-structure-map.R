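test_that("toy heterodimer builds, writes and re-reads within PDB precision", {
  toy <- makeToyHeterodimer(8, 4, seed = 1)
  a <- atomTable(toy$model)
  expect_setequal(unique(a$chain), c("A", "B"))
  expect_equal(nrow(a), 2 * 8 * 2)   # CA + CB per residue per chain
  pdb <- tempfile(fileext = ".pdb")
  writeStructurePdb(toy$model, pdb)
  back <- readStructure(pdb)
  b <- atomTable(back)
  expect_equal(nrow(b), nrow(a))
  expect_lt(max(abs(b$x - a$x), abs(b$y - a$y), abs(b$z - a$z)), 1e-3)
  expect_error(makeToyHeterodimer(8, 0), "positive")
  expect_error(makeToyHeterodimer(8, -2), "positive")
})

test_that("residue minimum distances match hand geometry and the brute oracle", {
  # two single-atom residues at (0,0,0) and (3,4,0): a 3-4-5 triangle
  m <- structureModel(data.frame(
    chain = c("A", "B"), resno = 1L, resid = "GLY", elety = "CA",
    x = c(0, 3), y = c(0, 4), z = 0))
  expect_equal(residueMinDistance(m, "A", 1, "B", 1), 5)
  expect_equal(residueMinDistance(m, "B", 1, "A", 1), 5)   # symmetric
  self <- residueMinDistance(m, "A", 1, "A", 1)
  expect_equal(as.numeric(self), 0)
  expect_true(attr(self, "self"))
  expect_error(residueMinDistance(m, "A", 2, "B", 1), "not found")

  # random toy structure vs brute-force all-pairs oracle
  toy <- makeToyHeterodimer(10, 4, seed = 3, jitter_sd = 0.3)
  for (ra in c(1, 4, 9)) for (rb in c(2, 5, 10)) {
    expect_equal(residueMinDistance(toy$model, "A", ra, "B", rb),
                 bruteMinDist(toy$model, "A", ra, "B", rb),
                 tolerance = 1e-9)
  }
})

test_that("interface detection equals brute force and respects the gap", {
  for (seed in 1:3) {
    toy <- makeToyHeterodimer(12, 4, seed = seed, jitter_sd = 0.2)
    rep5 <- interfaceResidues(toy$model, "A", "B", cutoff = 5)
    oracle <- bruteInterfaceSets(toy$model, "A", "B", 5)
    expect_equal(interfaceSet(rep5, "a"), oracle$a)
    expect_equal(interfaceSet(rep5, "b"), oracle$b)
  }
  # construction truth at the ideal geometry
  toy <- makeToyHeterodimer(12, 4, seed = 1)
  rep5 <- interfaceResidues(toy$model, "A", "B", cutoff = 5)
  expect_equal(interfaceSet(rep5, "a"), toy$truth$chain_a)
  expect_equal(interfaceSet(rep5, "b"), toy$truth$chain_b)
  expect_true(nrow(rep5@residues_a) > 0)   # 4 A gap, 5 A cutoff: non-empty
  # far-apart chains share no interface
  far <- makeToyHeterodimer(12, 50, seed = 1)
  rep_far <- interfaceResidues(far$model, "A", "B", cutoff = 5)
  expect_equal(length(interfaceSet(rep_far, "a")), 0L)
  expect_error(interfaceResidues(toy$model, "A", "Z"), "not found")
})

test_that("interface sets grow monotonically with the cutoff", {
  toy <- makeToyHeterodimer(15, 4, seed = 7, jitter_sd = 0.2)
  prev <- integer()
  for (cut in c(3, 4, 5, 6, 8)) {
    cur <- interfaceSet(interfaceResidues(toy$model, "A", "B", cut), "a")
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("distance operations are rigid-body invariant", {
  toy <- makeToyHeterodimer(10, 4, seed = 5, jitter_sd = 0.25)
  for (seed in c(11, 12, 13)) {
    moved <- rigidTransform(toy$model, seed)
    expect_equal(residueMinDistance(moved, "A", 2, "B", 7),
                 residueMinDistance(toy$model, "A", 2, "B", 7),
                 tolerance = 1e-6)
    r0 <- interfaceResidues(toy$model, "A", "B", 5)
    r1 <- interfaceResidues(moved, "A", "B", 5)
    expect_equal(interfaceSet(r1, "a"), interfaceSet(r0, "a"))
    expect_equal(r1@residues_a$min_dist, r0@residues_a$min_dist,
                 tolerance = 1e-6)
  }
})

test_that("contact partners respect cutoff and sequence separation", {
  # straight chain: residues 1..8 spaced 3.8 A apart along x
  m <- structureModel(data.frame(
    chain = "A", resno = 1:8, resid = "ALA", elety = "CA",
    x = (0:7) * 3.8, y = 0, z = 0))
  cp <- contactPartners(m, "A", 4, cutoff = 4.5, min_seq_sep = 3)
  expect_equal(nrow(cp), 0L)   # i+-1 are 3.8 A away but excluded by seq sep
  cp1 <- contactPartners(m, "A", 4, cutoff = 4.5, min_seq_sep = 1)
  expect_setequal(cp1$resno, c(3, 5))
  # fold residue 8 back near residue 1 (seq sep 7, 3 A away)
  a <- atomTable(m)
  a[a$resno == 8, c("x", "y", "z")] <- c(0, 3, 0)
  m2 <- structureModel(a)
  cp2 <- contactPartners(m2, "A", 1, cutoff = 4.5, min_seq_sep = 3)
  expect_equal(cp2$resno, 8L)
  expect_equal(cp2$min_dist, 3)
  # sorted by distance
  a2 <- rbind(a, data.frame(chain = "A", resno = 9L, insert = "",
                            resid = "ALA", elety = "CA", element = "",
                            x = 0, y = -4, z = 0, het = FALSE))
  cp3 <- contactPartners(structureModel(a2), "A", 1, cutoff = 4.5,
                         min_seq_sep = 3)
  expect_equal(cp3$resno, c(8L, 9L))
  expect_equal(cp3$min_dist, sort(cp3$min_dist))
})

test_that("PDB reading honours models, altlocs, hydrogens and HETATM rules", {
  fmt <- function(rec, serial, name, resn, chain, resno, x, y, z,
                  occ = 1, alt = " ", elem = " C") {
    nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, nm, alt, resn, chain, resno, x, y, z, occ, 0, elem)
  }
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    fmt("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, alt = "A", occ = 0.4),
    fmt("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 9, alt = "B", occ = 0.6),
    fmt("ATOM", 3, "H", "ALA", "A", 1, 1, 1, 1, elem = " H"),
    fmt("ATOM", 4, "CA", "GLY", "A", 2, 3, 0, 0),
    fmt("HETATM", 5, "C1", "LIG", "A", 90, 5, 5, 5),
    fmt("HETATM", 6, "O", "HOH", "A", 99, 7, 7, 7, elem = " O"),
    "ENDMDL",
    "MODEL     2",
    fmt("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 10, alt = "A", occ = 0.4),
    fmt("ATOM", 2, "CA", "ALA", "A", 1, 9, 9, 19, alt = "B", occ = 0.6),
    fmt("ATOM", 3, "H", "ALA", "A", 1, 1, 1, 11, elem = " H"),
    fmt("ATOM", 4, "CA", "GLY", "A", 2, 3, 0, 10),
    fmt("HETATM", 5, "C1", "LIG", "A", 90, 5, 5, 15),
    fmt("HETATM", 6, "O", "HOH", "A", 99, 7, 7, 17, elem = " O"),
    "ENDMDL", "END"), pdb)
  m1 <- readStructure(pdb, model_index = 1)
  a1 <- atomTable(m1)
  expect_equal(sum(!a1$het), 2L)             # two polymer CA atoms
  expect_false(any(a1$resid == "HOH"))       # waters dropped
  expect_false(any(grepl("^H", a1$elety)))   # hydrogens dropped
  expect_equal(a1$x[a1$resno == 1 & !a1$het], 9)  # highest-occupancy altloc
  expect_true(any(a1$het & a1$resid == "LIG"))    # ligand kept, flagged
  m2 <- readStructure(pdb, model_index = 2)
  expect_equal(atomTable(m2)$z[atomTable(m2)$resno == 2],
               atomTable(m1)$z[atomTable(m1)$resno == 2] + 10)
  expect_error(readStructure(pdb, model_index = 3), "model index")

  # HETATM-only file has no polymer residues
  het <- tempfile(fileext = ".pdb")
  writeLines(c(fmt("HETATM", 1, "C1", "LIG", "A", 1, 0, 0, 0), "END"), het)
  expect_error(readStructure(het), "no polymer")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "cannot read")
})

test_that("mutations map onto the structure with interface and resolution flags", {
  toy <- makeToyHeterodimer(20, 4, seed = 1)
  iface <- toy$truth$chain_a
  non_iface <- setdiff(1:20, c(iface, 1:3))[1]
  changes <- parseProteinChange(
    c(paste0("A", iface[1], "V"),        # at the built interface
      paste0("A", non_iface, "V"),       # resolved, not interfacial
      "A400V"),                          # outside the modeled construct
    "TOY")
  changes$gene <- "TOYGENE"
  ann <- mapMutationsToStructure(changes, toy$model,
                                 c(TOYGENE = "A"))
  expect_equal(ann$resolved, c(TRUE, TRUE, FALSE))
  expect_equal(ann$in_interface[1:2], c(TRUE, FALSE))
  expect_true(is.na(ann$in_interface[3]))   # unresolved, never guessed
  # numbering offset shifts the query into the model frame
  ann_off <- mapMutationsToStructure(changes[3, ], toy$model,
                                     c(TOYGENE = "A"),
                                     numbering_offset = c(TOYGENE = -390L))
  expect_true(ann_off$resolved)
  expect_error(mapMutationsToStructure(changes, toy$model,
                                       c(OTHER = "A")), "chain mapping")
  empty <- mapMutationsToStructure(changes[0, ], toy$model,
                                   c(TOYGENE = "A"))
  expect_equal(nrow(empty), 0L)
})
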