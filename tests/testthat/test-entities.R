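defsFor <- function(pdb, rows) {
  loadDomainDefinitions(c("domain_id\tfamily_id\tpdb_id\tchain\tstart\tend",
                          rows))
}

test_that("domain assignment follows segments and flags problems", {
  s <- parseStructure(makeProteinChain(100), pdbId = "big")
  defs <- defsFor("big", "d1\tfamA\tbig\tA\t1\t50")
  doms <- assignDomains(s, defs)
  expect_length(doms, 1L)
  expect_equal(nrow(residues(doms[[1]])), 50L)
  expect_equal(familyId(doms[[1]]), "famA")

  expect_warning(assignDomains(s, defsFor("big", "dz\tfamZ\tbig\tZ\t1\t10")),
                 "absent chain")
  overlapping <- defsFor("big", c("d1\tfamA\tbig\tA\t1\t50",
                                  "d2\tfamB\tbig\tA\t40\t90"))
  expect_error(assignDomains(s, overlapping), "overlapping")
})

test_that("peptide length boundary: 89 is a peptide, 90 is not", {
  for (n in c(89L, 90L)) {
    s <- parseStructure(makeProteinChain(n), pdbId = "chain")
    es <- typeEntities(s)
    tp <- vapply(entities(es), entityType, "")
    if (n <= 89L) {
      expect_true("peptide" %in% tp)
      expect_equal(nrow(residues(entities(es)[[which(tp == "peptide")]])), n)
    } else {
      expect_false("peptide" %in% tp)
      expect_true("unassigned-protein" %in% es@report$category)
    }
  }
})

test_that("a domain-covered chain is never a peptide", {
  s <- parseStructure(makeProteinChain(50), pdbId = "cov")
  defs <- defsFor("cov", "d1\tfamA\tcov\tA\t1\t50")
  es <- typeEntities(s, defs)
  tp <- vapply(entities(es), entityType, "")
  expect_equal(sum(tp == "domain"), 1L)
  expect_equal(sum(tp == "peptide"), 0L)
})

test_that("nucleic-acid chains merge on inter-base contact and split without", {
  one <- detectNucleicAcids(parseStructure(makeNaDuplex(4, 3.4)))
  expect_length(one, 1L)
  expect_equal(entityType(one[[1]]), "dna")
  expect_setequal(one[[1]]@memberChains, c("C", "D"))

  two <- detectNucleicAcids(parseStructure(makeNaDuplex(4, 6.0)))
  expect_length(two, 2L)

  rna <- detectNucleicAcids(parseStructure(makeNaDuplex(4, 3.4, rna = TRUE)))
  expect_length(rna, 1L)
  expect_equal(entityType(rna[[1]]), "rna")
})

test_that("chain merging is transitive and equals the union-find oracle", {
  # chains E, F, G in a row: E-F and F-G within 4.5, E-G far apart
  mk <- function(chain, x, serial0) {
    sprintf("ATOM  %5d  N3  DC  %1s%4d    %8.3f   0.000   0.000  1.00  0.00           N",
            serial0 + seq_len(2) - 1L, chain, seq_len(2), c(x, x + 1.0))
  }
  lines <- c(mk("E", 0, 1), mk("F", 4.0, 10), mk("G", 8.0, 20), "END")
  s <- parseStructure(lines)
  units <- detectNucleicAcids(s)
  expect_length(units, 1L)
  expect_setequal(units[[1]]@memberChains, c("E", "F", "G"))
  # independent oracle on the explicit pairwise edge list
  oracle <- unionFindComponents(c("E", "F", "G"), c("E", "F"), c("F", "G"))
  expect_equal(length(unique(oracle)), length(units))
})

test_that("oligosaccharide merging follows connectivity; isolated units stay apart", {
  corpus <- corpusFixture()
  s <- parseStructure(file.path(corpus$dir, "pdb3.pdb"))
  sacs <- detectSaccharides(s)
  expect_length(sacs, 1L)               # 3 NAG units, CONECT 1-2 and 2-3
  expect_equal(nrow(residues(sacs[[1]])), 3L)
  expect_false(covalentToProtein(sacs[[1]]))
  # oracle: connected components of the CONECT unit graph
  oracle <- unionFindComponents(c("u1", "u2", "u3"), c("u1", "u2"),
                                c("u2", "u3"))
  expect_equal(length(unique(oracle)), length(sacs))

  # drop the CONECT records: units are > 3 A apart -> three monosaccharides
  lines <- writeStructure(s)
  lines <- lines[!startsWith(lines, "CONECT")]
  sacsNoCon <- detectSaccharides(parseStructure(lines, pdbId = "pdb3"))
  expect_length(sacsNoCon, 3L)
})

test_that("glycosylation is flagged covalent to protein", {
  corpus <- corpusFixture()
  s <- parseStructure(file.path(corpus$dir, "pdb5.pdb"))
  defs <- loadDomainDefinitions(corpus$domainDefs)
  es <- typeEntities(s, defs)
  tab <- entityTable(es)
  sac <- tab[tab$type == "saccharide", ]
  expect_equal(nrow(sac), 1L)
  expect_true(sac$covalent_to_protein)
})

test_that("waters are single-residue entities; DOD counts; no-oxygen skipped", {
  lines <- c(
    "HETATM    1  O   HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM    2  O   DOD W   2       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  N   HOH W   3      10.000   0.000   0.000  1.00  0.00           N",
    "END")
  s <- parseStructure(lines)
  expect_warning(w <- detectWaters(s), "no oxygen")
  expect_length(w, 2L)
  expect_true(all(vapply(w, entityType, "") == "water"))
})

test_that("every residue is assigned once; unknown HETATMs are reported", {
  corpus <- corpusFixture()
  defs <- loadDomainDefinitions(corpus$domainDefs)
  for (f in corpus$structures) {
    s <- parseStructure(f)
    es <- typeEntities(s, defs)    # EntitySet validity enforces uniqueness
    expect_s4_class(es, "EntitySet")
    a <- atoms(s)
    keys <- unique(paste(a$chain, a$seqNum, a$insCode, a$resName, sep = "|"))
    assigned <- unique(unlist(lapply(entities(es), function(e)
      paste(e@residues$chain, e@residues$seqNum, e@residues$insCode,
            e@residues$resName, sep = "|"))))
    # ATOM amino acids, nucleotides, sugars and waters all covered here
    expect_setequal(assigned, keys)
  }
  junk <- c(
    "HETATM    1 FE   HEM X   1       0.000   0.000   0.000  1.00  0.00          FE",
    "ATOM      2  N   ALA A   1      10.000   0.000   0.000  1.00  0.00           N",
    "END")
  es <- typeEntities(parseStructure(junk))
  expect_true("other-het" %in% es@report$category)
})

test_that("peptide detection is invariant to chain order in the file", {
  chainA <- makeProteinChain(10, chain = "A")
  chainB <- makeProteinChain(20, chain = "B")
  strip <- function(x) x[startsWith(x, "ATOM")]
  s1 <- parseStructure(c(strip(chainA), strip(chainB), "END"), pdbId = "s")
  s2 <- parseStructure(c(strip(chainB), strip(chainA), "END"), pdbId = "s")
  t1 <- entityTable(typeEntities(s1))
  t2 <- entityTable(typeEntities(s2))
  expect_equal(t1[order(t1$entity_id), ], t2[order(t2$entity_id), ],
               ignore_attr = TRUE)
})
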