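# Self-consistent toy corpus: two protein families with observed complexes
# (DNA, peptide, homodimer and saccharide ligands, one bridging water, one
# glycosylation), one apo family reachable only through a cross-family
# correspondence. Drives the whole pipeline end-to-end without downloads.

.writeCorpusStructure <- function(rows, bonds, pdbId, dir) {
  s <- .structureFromAtoms(rows, pdbId = pdbId, bonds = bonds)
  path <- file.path(dir, paste0(pdbId, ".pdb"))
  writeStructure(s, path)
  path
}

#' Generate the synthetic toy corpus
#'
#' Writes a deterministic set of PDB fixtures plus the matching domain
#' definitions, family alignments and a cross-family correspondence map:
#'
#' * `pdb1`: family famA domain (30 residues) binding a DNA duplex through
#'   residues 10-14;
#' * `pdb2`: a second famA domain binding a 6-residue peptide through the
#'   same region, plus a water bridging domain residue 16 to the peptide;
#' * `pdb4`: a famA homodimer contacting through residues 13-18;
#' * `pdb3`: family famB domain binding a non-covalent NAG trisaccharide
#'   (units linked by CONECT records) through residues 10-12;
#' * `pdb5`: a glycoprotein — famB domain with a NAG covalently attached to
#'   Asn10 (C1 to ND2 at 1.45 Angstrom);
#' * `pdb6`: family famC apo domain, no ligand; famC gains binding
#'   information only through the famA->famC correspondence (residues 5-12),
#'   which covers 3 of the 5 DNA-interface residues (coverage 0.6).
#'
#' Output is byte-identical for a fixed `seed` (the corpus is fully
#' deterministic; the seed is recorded in the manifest).
#'
#' @param dir output directory (created if needed).
#' @param seed integer recorded in the manifest.
#' @return list(dir, seed, structures, domainDefs, alignments (named by
#'   family), correspondence).
#' @examples
#' corpus <- makeComplexCorpus(tempfile("corpus"))
#' list.files(corpus$dir)
#' @export
makeComplexCorpus <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  comb <- function(n, resNames = "ALA") .makeChainAtoms(n, resNames = resNames)

  # pdb1: famA domain + DNA duplex (chains C/D), contacts at residues 10-14
  rows <- comb(30)
  serial <- 200L
  dcAtoms <- function(chain, seq, xO2, y, dir) {
    # O2 frontier toward the domain at xO2; base recedes along dir
    at <- list(c("O2", 0, 0), c("C2", 1.6, 0), c("N1", 3.2, 0),
               c("N3", 1.6, 1.6), c("C4", 3.2, 1.6), c("C1'", 1.6, 3.2),
               c("O4'", 3.2, 3.2))
    out <- list()
    for (a in at) {
      out[[length(out) + 1L]] <-
        .atomRow(serial, a[1], "DC", chain, seq, xO2 + dir * as.numeric(a[2]),
                 y, as.numeric(a[3]))
      serial <<- serial + 1L
    }
    out
  }
  for (j in 1:5) rows <- c(rows, dcAtoms("C", j, -3.2, 36 + 4 * (j - 1L), -1))
  # chain D base atoms 3.4 A from chain C base atoms (N1 of C vs O2 of D)
  for (j in 1:5) rows <- c(rows, dcAtoms("D", j, -9.8, 36 + 4 * (j - 1L), -1))
  paths["pdb1"] <- .writeCorpusStructure(rows, matrix(integer(0), 0, 2),
                                         "pdb1", dir)

  # pdb2: famA domain + 6-residue peptide + bridging water at residue 16
  rows <- comb(30)
  # peptide O atoms face the domain at x = -3.0; backbone recedes to -x
  pep <- list()
  serial <- 300L
  for (j in 1:5) {
    y <- 36 + 4 * (j - 1L)
    for (a in list(c("O", -3.0, 0), c("C", -4.6, -0.6), c("CA", -5.4, 0.6),
                   c("N", -6.2, -0.4))) {
      pep[[length(pep) + 1L]] <-
        .atomRow(serial, a[1], "GLY", "P", j, as.numeric(a[2]), y,
                 as.numeric(a[3]))
      serial <- serial + 1L
    }
  }
  # residue 6: hydrogen-bonds only to the water, no direct domain contact
  for (a in list(c("O", -5.8, 0), c("C", -7.4, -0.6), c("CA", -8.2, 0.6),
                 c("N", -9.0, -0.4))) {
    pep[[length(pep) + 1L]] <-
      .atomRow(serial, a[1], "GLY", "P", 6L, as.numeric(a[2]), 60.8,
               as.numeric(a[3]))
    serial <- serial + 1L
  }
  wat <- list(.atomRow(400L, "O", "HOH", "W", 1L, -2.4, 60.8, 0,
                       recordKind = "HETATM"))
  rows <- c(rows, pep, wat)
  paths["pdb2"] <- .writeCorpusStructure(rows, matrix(integer(0), 0, 2),
                                         "pdb2", dir)

  # pdb3: famB domain (Asn at 10) + non-covalent NAG trisaccharide
  famBres <- c(rep("ALA", 9), "ASN", rep("ALA", 10))
  rows <- comb(20, resNames = famBres)
  serial <- 500L
  sugars <- list()
  sugarSerials <- integer()
  for (j in 1:3) {
    y <- 36 + 4 * (j - 1L)
    sugarSerials[j] <- serial
    for (a in list(c("O3", -3.0, 0), c("C3", -4.6, 0), c("C1", -5.4, 1.2),
                   c("O4", -4.6, -1.4), c("O5", -6.2, 0.4))) {
      sugars[[length(sugars) + 1L]] <-
        .atomRow(serial, a[1], "NAG", "S", j, as.numeric(a[2]), y,
                 as.numeric(a[3]), recordKind = "HETATM")
      serial <- serial + 1L
    }
  }
  # glycosidic CONECT links: unit1 O4 - unit2 C1, unit2 O4 - unit3 C1
  bonds <- rbind(c(sugarSerials[1] + 3L, sugarSerials[2] + 2L),
                 c(sugarSerials[2] + 3L, sugarSerials[3] + 2L))
  paths["pdb3"] <- .writeCorpusStructure(c(rows, sugars), bonds, "pdb3", dir)

  # pdb5: glycoprotein — famB domain with NAG covalent to Asn10 ND2
  rows <- comb(20, resNames = famBres)
  # Asn10 sidechain reaching +z; ND2 is the attachment point
  serial <- 600L
  asn <- list(.atomRow(600L, "CG", "ASN", "A", 10L, 1.4, 36, 3.0),
              .atomRow(601L, "OD1", "ASN", "A", 10L, 2.6, 36, 3.6),
              .atomRow(602L, "ND2", "ASN", "A", 10L, 0.0, 36, 3.6))
  nag <- list()
  serial <- 610L
  for (a in list(c("C1", 0, 5.05), c("O5", 1.6, 5.05), c("C2", 0, 6.65),
                 c("O3", 1.6, 6.65), c("O4", 0, 8.25))) {
    nag[[length(nag) + 1L]] <-
      .atomRow(serial, a[1], "NAG", "S", 1L, as.numeric(a[2]), 36,
               as.numeric(a[3]), recordKind = "HETATM")
    serial <- serial + 1L
  }
  paths["pdb5"] <- .writeCorpusStructure(c(rows, asn, nag),
                                         matrix(c(602L, 610L), 1, 2),
                                         "pdb5", dir)

  # pdb4: famA homodimer — chain B residues 13-18 facing chain A
  rows <- comb(30)
  chB <- list()
  serial <- 700L
  for (i in 13:18) {
    y <- 4 * (i - 1L)
    for (a in list(c("N", -3.0, 0), c("CA", -4.4, -0.6), c("C", -5.2, 0.6),
                   c("O", -6.0, -0.2), c("CB", -4.4, -2.0))) {
      chB[[length(chB) + 1L]] <-
        .atomRow(serial, a[1], "ALA", "B", i, as.numeric(a[2]), y,
                 as.numeric(a[3]))
      serial <- serial + 1L
    }
  }
  paths["pdb4"] <- .writeCorpusStructure(c(rows, chB),
                                         matrix(integer(0), 0, 2),
                                         "pdb4", dir)

  # pdb6: famC apo domain
  paths["pdb6"] <- .writeCorpusStructure(comb(25), matrix(integer(0), 0, 2),
                                         "pdb6", dir)

  defs <- c("domain_id\tfamily_id\tpdb_id\tchain\tstart\tend",
            "domA1\tfamA\tpdb1\tA\t1\t30",
            "domA2\tfamA\tpdb2\tA\t1\t30",
            "domA3\tfamA\tpdb4\tA\t1\t30",
            "domA4\tfamA\tpdb4\tB\t1\t30",
            "domB1\tfamB\tpdb3\tA\t1\t20",
            "domB2\tfamB\tpdb5\tA\t1\t20",
            "domC1\tfamC\tpdb6\tA\t1\t25")
  defPath <- file.path(dir, "domain_defs.tsv")
  writeLines(defs, defPath)

  famBseq <- paste(c(rep("A", 9), "N", rep("A", 10)), collapse = "")
  alnPaths <- c(
    famA = file.path(dir, "famA.fasta"),
    famB = file.path(dir, "famB.fasta"),
    famC = file.path(dir, "famC.fasta"))
  writeLines(c(">domA1", strrep("A", 30), ">domA2", strrep("A", 30),
               ">domA3", strrep("A", 30),
               ">domA4", paste0(strrep("-", 12), strrep("A", 6),
                                strrep("-", 12))),
             alnPaths[["famA"]])
  writeLines(c(">domB1", famBseq, ">domB2", famBseq), alnPaths[["famB"]])
  writeLines(c(">domC1", strrep("A", 25)), alnPaths[["famC"]])

  corr <- c(paste("family_a", "member_a", "chain_a", "seq_a", "icode_a",
                  "res_a", "family_b", "member_b", "chain_b", "seq_b",
                  "icode_b", "res_b", "source_tag", sep = "\t"),
            vapply(5:12, function(i)
              paste("famA", "domA1", "A", i, ".", "ALA",
                    "famC", "domC1", "A", i, ".", "ALA",
                    "synthetic-nonseq-align", sep = "\t"), ""))
  corrPath <- file.path(dir, "corr_famA_famC.tsv")
  writeLines(corr, corrPath)

  manifest <- list(seed = as.integer(seed), structures = as.list(basename(paths)),
                   families = c("famA", "famB", "famC"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)

  list(dir = dir, seed = as.integer(seed), structures = unname(paths),
       domainDefs = defPath, alignments = alnPaths,
       correspondence = corrPath)
}
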