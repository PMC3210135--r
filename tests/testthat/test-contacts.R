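pairContacts <- function(resA, atomA, resB, atomB, d,
                         cutoffs = defaultCutoffs()) {
  s <- parseStructure(makeAtomPair(resA, atomA, resB, atomB, d))
  es <- entities(typeEntities(s))
  detectDirectContacts(s, es[[1]], es[[2]], cutoffs = cutoffs)
}

test_that("interaction criteria are inclusive at their exact boundaries", {
  # hydrogen bond: donor/acceptor <= 3.6 A
  ct <- pairContacts("GLY", "N", "GLY", "O", 3.50)
  expect_true(ct$hbond[1] && ct$vdw[1] && !ct$saltBridge[1])
  ct <- pairContacts("GLY", "N", "GLY", "O", 3.60)
  expect_true(ct$hbond[1])
  ct <- pairContacts("GLY", "N", "GLY", "O", 3.70)
  expect_false(ct$hbond[1]); expect_true(ct$vdw[1])
  # salt bridge: charged atoms <= 4.0 A (3.9 also exceeds the hbond cutoff)
  ct <- pairContacts("LYS", "NZ", "ASP", "OD1", 3.90)
  expect_true(ct$saltBridge[1] && ct$vdw[1] && !ct$hbond[1])
  ct <- pairContacts("LYS", "NZ", "ASP", "OD1", 4.05)
  expect_false(ct$saltBridge[1]); expect_true(ct$vdw[1])
  # van der Waals envelope: <= 4.5 A, boundary excluded above
  expect_equal(nrow(pairContacts("ALA", "CB", "ALA", "CB", 4.50)), 1L)
  expect_equal(nrow(pairContacts("ALA", "CB", "ALA", "CB", 4.60)), 0L)
})

test_that("a close salt bridge carries all three labels", {
  ct <- pairContacts("LYS", "NZ", "ASP", "OD1", 3.20)
  expect_true(ct$hbond[1] && ct$saltBridge[1] && ct$vdw[1])
})

test_that("contact detection is symmetric in its arguments", {
  s <- parseStructure(randomStructureText(15, box = 18, seed = 42))
  es <- entities(typeEntities(s))
  ab <- detectDirectContacts(s, es[[1]], es[[2]])
  ba <- detectDirectContacts(s, es[[2]], es[[1]])
  k1 <- sort(paste(ab$chainA, ab$seqA, ab$atomA, ab$chainB, ab$seqB,
                   ab$atomB, round(ab$distance, 6)))
  k2 <- sort(paste(ba$chainB, ba$seqB, ba$atomB, ba$chainA, ba$seqA,
                   ba$atomA, round(ba$distance, 6)))
  expect_gt(nrow(ab), 0L)
  expect_equal(k1, k2)
})

test_that("enlarging any cutoff never removes a contact", {
  s <- parseStructure(randomStructureText(15, box = 18, seed = 7))
  es <- entities(typeEntities(s))
  base <- detectDirectContacts(s, es[[1]], es[[2]])
  for (grow in list(c(hbond = 4.0, salt = 4.0, vdw = 4.5, covalent = 1.9),
                    c(hbond = 3.6, salt = 4.4, vdw = 4.5, covalent = 1.9),
                    c(hbond = 3.6, salt = 4.0, vdw = 5.2, covalent = 1.9))) {
    bigger <- detectDirectContacts(s, es[[1]], es[[2]], cutoffs = grow)
    keyB <- paste(bigger$seqA, bigger$atomA, bigger$seqB, bigger$atomB)
    keyS <- paste(base$seqA, base$atomA, base$seqB, base$atomB)
    expect_true(all(keyS %in% keyB))
    expect_true(all(base$hbond <= bigger$hbond[match(keyS, keyB)]))
  }
})

test_that("spatial-index contacts equal the all-pairs brute force exactly", {
  dict <- defaultChemistry()
  for (seed in 1:8) {
    s <- parseStructure(randomStructureText(40, box = 30, seed = seed))
    es <- entities(typeEntities(s))
    got <- detectDirectContacts(s, es[[1]], es[[2]])
    a <- atoms(s)
    keysA <- paste(got$chainA, got$seqA, got$atomA)
    aA <- a[a$chain == "A", , drop = FALSE]
    aB <- a[a$chain == "B", , drop = FALSE]
    want <- bruteForceContacts(aA, aB, dict)
    gotSorted <- got[order(got$seqA, got$atomA, got$seqB, got$atomB,
                           got$distance), ]
    serialOf <- function(ch, seq, atom) {
      vapply(seq_along(seq), function(k)
        a$serial[a$chain == ch[k] & a$seqNum == seq[k] & a$name == atom[k]],
        1L)
    }
    gs <- data.frame(serialA = serialOf(gotSorted$chainA, gotSorted$seqA,
                                        gotSorted$atomA),
                     serialB = serialOf(gotSorted$chainB, gotSorted$seqB,
                                        gotSorted$atomB),
                     distance = gotSorted$distance,
                     hbond = gotSorted$hbond,
                     saltBridge = gotSorted$saltBridge)
    gs <- gs[order(gs$serialA, gs$serialB), ]
    rownames(gs) <- rownames(want) <- NULL
    expect_equal(gs, want)
  }
})

test_that("water bridges require both legs within the hydrogen-bond cutoff", {
  mkBridge <- function(dA, dB) {
    lines <- c(sprintf(
      "ATOM      1  O   GLY A   1    %8.3f   0.000   0.000  1.00  0.00           O",
      -dA), sprintf(
      "ATOM      2  N   GLY B   1    %8.3f   0.000   0.000  1.00  0.00           N",
      dB),
      "HETATM    3  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
      "END")
    s <- parseStructure(lines)
    es <- entities(typeEntities(s))
    tp <- vapply(es, entityType, "")
    detectWaterBridges(s, es[[which(tp == "peptide")[1]]],
                       es[[which(tp == "peptide")[2]]],
                       es[tp == "water"])
  }
  br <- mkBridge(2.8, 3.0)
  expect_equal(nrow(br), 1L)
  expect_equal(br$distance, 3.0)            # max of the two legs
  expect_equal(br$bridgingWater, "struct:wat:W1")
  expect_equal(nrow(mkBridge(2.8, 3.8)), 0L)  # one leg exceeds 3.6
})

test_that("two waters bridging the same residue pair give two records", {
  lines <- c(
    "ATOM      1  O   GLY A   1      -2.800   0.000   0.000  1.00  0.00           O",
    "ATOM      2  N   GLY B   1       3.000   0.000   0.000  1.00  0.00           N",
    "HETATM    3  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    4  O   HOH W   2       0.000   1.500   0.000  1.00  0.00           O",
    "END")
  s <- parseStructure(lines)
  es <- entities(typeEntities(s))
  tp <- vapply(es, entityType, "")
  br <- detectWaterBridges(s, es[[which(tp == "peptide")[1]]],
                           es[[which(tp == "peptide")[2]]], es[tp == "water"])
  # brute-force (ra, rb, W) triple enumeration: both waters qualify
  legOK <- function(w, p) sqrt(sum((w - p)^2)) <= 3.6
  waters <- list(c(0, 0, 0), c(0, 1.5, 0))
  expected <- sum(vapply(waters, function(w)
    legOK(w, c(-2.8, 0, 0)) && legOK(w, c(3, 0, 0)), TRUE))
  expect_equal(nrow(br), expected)
  expect_equal(nrow(br), 2L)
  expect_setequal(br$bridgingWater, c("struct:wat:W1", "struct:wat:W2"))
})

test_that("interfaces annotate solvation, chemistry and classes", {
  corpus <- corpusFixture()
  defs <- loadDomainDefinitions(corpus$domainDefs)
  s <- parseStructure(file.path(corpus$dir, "pdb2.pdb"))
  es <- typeEntities(s, defs)
  ifs <- structureInterfaces(s, es)
  expect_length(ifs, 1L)
  i <- ifs[[1]]
  expect_equal(ligandType(i), "peptide")
  expect_equal(complexClass(i), "hetero")   # peptide ligand, not same family
  expect_equal(chainClass(i), "inter")      # domain chain A vs peptide P
  res <- residues(i)
  expect_setequal(res$seqNum, c(10:14, 16))
  expect_equal(res$solvation[res$seqNum == 16], "wet")
  expect_true(all(res$solvation[res$seqNum %in% 10:14] == "dry"))
  expect_true(all(res$chemistry == "hydrophilic"))  # backbone N contacts
  # wet residues have a bridging-water record; dry ones do not
  ct <- contacts(i)
  wetRows <- ct[nzchar(ct$bridgingWater), ]
  expect_true(all(wetRows$seqA == 16))

  # homodimer: same family on both sides -> homo
  s4 <- parseStructure(file.path(corpus$dir, "pdb4.pdb"))
  ifs4 <- structureInterfaces(s4, typeEntities(s4, defs))
  expect_true(all(vapply(ifs4, complexClass, "") == "homo"))
  expect_true(all(vapply(ifs4, chainClass, "") == "inter"))
})

test_that("a residue with direct and water-mediated contact is dual", {
  # one domain residue whose N touches the ligand O directly and whose
  # water leg also reaches the same ligand residue
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000  -2.000   0.000  1.00  0.00           C",
    "ATOM      3  O   GLY B   1       3.300   0.000   0.000  1.00  0.00           O",
    "HETATM    4  O   HOH W   1       1.600   2.400   0.000  1.00  0.00           O",
    "END")
  s <- parseStructure(lines)
  defs <- loadDomainDefinitions(c("domain_id\tfamily_id\tpdb_id\tchain\tstart\tend",
                                  "dX\tfamX\tstruct\tA\t1\t1"))
  es <- typeEntities(s, defs)
  ifs <- structureInterfaces(s, es)
  expect_length(ifs, 1L)
  expect_equal(residues(ifs[[1]])$solvation, "dual")
})

test_that("crystal-packing filter honors hook probabilities and naive mode", {
  ifA <- mkIface("IF_1", "d1", 1:3)            # 3 residues
  ifB <- mkIface("IF_2", "d2", 1:8)            # 8 residues
  hook <- function(iface) if (interfaceId(iface) == "IF_1") 0.65 else 0.90
  kept <- filterCrystalPacking(list(ifA, ifB), hook, mode = "hook")
  expect_equal(vapply(kept, interfaceId, ""), "IF_2")
  # boundary: exactly 0.70 is kept
  kept <- filterCrystalPacking(list(ifA), function(i) 0.70, mode = "hook")
  expect_length(kept, 1L)
  # no hook: warn, keep everything
  expect_warning(kept <- filterCrystalPacking(list(ifA, ifB), NULL,
                                              mode = "hook"), "no.*hook")
  expect_length(kept, 2L)
  # naive heuristic: small protein-protein interfaces dropped
  kept <- filterCrystalPacking(list(ifA, ifB), mode = "naive")
  expect_equal(vapply(kept, interfaceId, ""), "IF_2")
  # a failing hook keeps the interface
  expect_warning(kept <- filterCrystalPacking(list(ifA),
                                              function(i) stop("boom"),
                                              mode = "hook"), "boom")
  expect_length(kept, 1L)
})
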