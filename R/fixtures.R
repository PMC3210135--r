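# Deterministic synthetic PDB fixtures with controlled geometry. The
# geometry is schematic, not stereochemically refined: the interaction
# criteria consume heavy-atom distances only, and every generator places the
# atoms of interest at exactly the requested separations (coordinates
# written to 3 decimals).

.templateAtoms <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      f <- .buildDefaultFlags()
      env <<- split(f$atomName, f$resName)
    }
    env
  }
})

.elementOf <- function(name) .guessElement(name)

.recordKindOf <- function(resName, dict = NULL) {
  if (resName %in% .AA3 || resName %in% .nucleotideNames) "ATOM" else "HETATM"
}

.atomRow <- function(serial, name, resName, chain, seqNum, x, y, z,
                     recordKind = .recordKindOf(resName), occupancy = 1) {
  data.frame(serial = serial, name = name, altLoc = "", resName = resName,
             chain = chain, seqNum = as.integer(seqNum), insCode = "",
             x = round(x, 3), y = round(y, 3), z = round(z, 3),
             occupancy = occupancy, element = .elementOf(name),
             recordKind = recordKind, stringsAsFactors = FALSE)
}

.structureFromAtoms <- function(atomRows, pdbId = "fixt",
                                bonds = matrix(integer(0), 0L, 2L)) {
  atomRows <- do.call(rbind, atomRows)
  rownames(atomRows) <- NULL
  storage.mode(bonds) <- "integer"
  colnames(bonds) <- c("serialA", "serialB")
  new("PDBStructure", pdbId = pdbId, atoms = atomRows, bonds = bonds)
}

#' Atom-pair fixture at an exact separation
#'
#' Two single-residue chains (A and B) whose named atoms sit exactly
#' `distance` apart along x; all other atoms of each residue recede behind
#' their contact atom at 2 Angstrom spacing, so for separations of 3
#' Angstrom or more the named pair is the only atom pair within the van der
#' Waals envelope. Used to probe the interaction criteria at exact boundary
#' distances.
#'
#' @param resA,atomA,resB,atomB residue and atom names (must exist in the
#'   default chemistry dictionary).
#' @param distance requested separation in Angstrom (> 0).
#' @param pdbId structure id for the HEADER record.
#' @return PDB text lines (character vector).
#' @examples
#' pdb <- makeAtomPair("GLY", "N", "GLY", "O", 3.60)
#' @export
makeAtomPair <- function(resA, atomA, resB, atomB, distance, pdbId = "pair") {
  if (!is.numeric(distance) || distance <= 0)
    irStop("distance must be > 0")
  tmpl <- .templateAtoms()
  for (spec in list(c(resA, atomA), c(resB, atomB))) {
    av <- tmpl[[spec[1]]]
    if (is.null(av)) irStop("unknown residue: ", spec[1])
    if (!spec[2] %in% av) irStop("unknown atom ", spec[2], " for ", spec[1])
  }
  place <- function(res, atom, chain, x0, dir, serial0) {
    names_ <- setdiff(tmpl[[res]], "OXT")
    names_ <- c(atom, setdiff(names_, atom))
    rows <- list()
    for (k in seq_along(names_)) {
      rows[[k]] <- .atomRow(serial0 + k - 1L, names_[k], res, chain, 1L,
                            x0 + dir * 2.0 * (k - 1L), 0, 0)
    }
    rows
  }
  a <- place(resA, atomA, "A", 0, -1, 1L)
  b <- place(resB, atomB, "B", distance, +1, 100L)
  s <- .structureFromAtoms(c(a, b), pdbId = pdbId)
  writeStructure(s)
}

#' Poly-amino-acid chain fixture
#'
#' A schematic chain of `n` residues spaced 4 Angstrom apart along y, each
#' with backbone N/CA/C/O (and CB unless glycine). Residue i's N sits at
#' `offset + (0, 4*(i-1), 0)`; the remaining atoms extend toward +x, so a
#' ligand approached from -x sees the backbone N first.
#'
#' @param n number of residues.
#' @param chain chain id.
#' @param resNames residue name(s), recycled to length `n`.
#' @param startSeq first residue number.
#' @param offset numeric length-3 translation.
#' @param serialStart first atom serial.
#' @return data.frame of atom rows (internal layout; combine and wrap with
#'   the corpus builder or convert via [writeStructure()] after
#'   constructing a structure).
#' @keywords internal
.makeChainAtoms <- function(n, chain = "A", resNames = "ALA", startSeq = 1L,
                            offset = c(0, 0, 0), serialStart = 1L,
                            dir = +1) {
  resNames <- rep_len(resNames, n)
  rows <- list(); serial <- serialStart
  for (i in seq_len(n)) {
    y <- offset[2] + 4 * (i - 1L)
    at <- list(c("N", 0, 0), c("CA", 1.4, 0.6), c("C", 2.2, -0.6),
               c("O", 3.0, 0.2))
    if (resNames[i] != "GLY") at <- c(at, list(c("CB", 1.4, 2.0)))
    for (a in at) {
      rows[[length(rows) + 1L]] <-
        .atomRow(serial, a[1], resNames[i], chain, startSeq + i - 1L,
                 offset[1] + dir * as.numeric(a[2]), y,
                 offset[3] + as.numeric(a[3]))
      serial <- serial + 1L
    }
  }
  rows
}

#' Undomained protein chain fixture
#'
#' Writes a poly-alanine chain of `n` residues as PDB text; with no covering
#' domain definition it exercises the peptide length rule.
#'
#' @param n chain length in residues.
#' @param chain chain id.
#' @param pdbId structure id.
#' @return PDB text lines.
#' @export
makeProteinChain <- function(n, chain = "A", pdbId = "chain") {
  s <- .structureFromAtoms(.makeChainAtoms(n, chain = chain), pdbId = pdbId)
  writeStructure(s)
}

#' Nucleic-acid duplex fixture with exact minimum base-base gap
#'
#' Two antiparallel-by-construction nucleotide chains whose closest
#' base-moiety atom pair sits exactly `minBaseGap` apart; sugar atoms are
#' kept farther away. With the rna flag the nucleotides are ribonucleotides
#' carrying O2' atoms, otherwise deoxynucleotides.
#'
#' @param nBp number of nucleotides per chain (>= 1).
#' @param minBaseGap closest base-base atom distance in Angstrom.
#' @param rna include O2' ribose atoms (and use ribonucleotide residue
#'   names)?
#' @param chains two chain ids.
#' @param pdbId structure id.
#' @return PDB text lines.
#' @examples
#' pdb <- makeNaDuplex(4, 3.4)
#' @export
makeNaDuplex <- function(nBp, minBaseGap, rna = FALSE, chains = c("C", "D"),
                         pdbId = "duplex") {
  stopifnot(nBp >= 1L, minBaseGap > 0)
  res <- if (rna) "C" else "DC"
  rows <- list(); serial <- 1L
  nucleotide <- function(chain, seq, x0, dir, y) {
    # base frontier atom N3 at x0; base recedes by dir; sugar offset in z
    at <- list(c("N3", 0, 0), c("C2", 1.4, 0), c("N1", 2.8, 0),
               c("O2", 1.4, -1.4), c("C4", 1.4, 1.4),
               c("C1'", 2.8, 2.6), c("O4'", 4.2, 2.6))
    if (rna) at <- c(at, list(c("O2'", 2.8, 4.0)))
    for (a in at) {
      rows[[length(rows) + 1L]] <<-
        .atomRow(serial, a[1], res, chain, seq,
                 x0 + dir * as.numeric(a[2]), y, as.numeric(a[3]))
      serial <<- serial + 1L
    }
  }
  for (j in seq_len(nBp)) nucleotide(chains[1], j, 0, -1, 7 * (j - 1L))
  for (j in seq_len(nBp)) nucleotide(chains[2], j, minBaseGap, +1,
                                     7 * (j - 1L))
  s <- .structureFromAtoms(rows, pdbId = pdbId)
  writeStructure(s)
}
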