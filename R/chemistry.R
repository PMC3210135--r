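# Default physicochemical dictionary. Flags follow standard heavy-atom
# chemistry: backbone N donor / O,OXT acceptor; carbons (and Met SD)
# hydrophobic; His ND1/NE2 both donor and acceptor and uncharged by default;
# N-terminal protonation is unknowable from coordinates, so N stays
# donor-only unless the user edits the dictionary.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.sidechainAtoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# sidechain atoms carrying polar/charged roles; everything else in the
# sidechain is hydrophobic (C and Met SD)
.aaPolar <- list(
  ARG = list(donor = c("NE", "NH1", "NH2"), positive = c("NH1", "NH2")),
  ASN = list(donor = "ND2", acceptor = "OD1"),
  ASP = list(acceptor = c("OD1", "OD2"), negative = c("OD1", "OD2")),
  CYS = list(donor = "SG", acceptor = "SG"),
  GLN = list(donor = "NE2", acceptor = "OE1"),
  GLU = list(acceptor = c("OE1", "OE2"), negative = c("OE1", "OE2")),
  HIS = list(donor = c("ND1", "NE2"), acceptor = c("ND1", "NE2")),
  LYS = list(donor = "NZ", positive = "NZ"),
  SER = list(donor = "OG", acceptor = "OG"),
  THR = list(donor = "OG1", acceptor = "OG1"),
  TRP = list(donor = "NE1"),
  TYR = list(donor = "OH", acceptor = "OH")
)

.nucleotideNames <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "T")

# base moiety (ring + exocyclic substituents); sugar/phosphate excluded
.baseAtomSets <- local({
  pur <- c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6")
  pyr <- c("N1", "C2", "O2", "N3", "C4", "C5", "C6")
  list(A = c(pur, "N6"), DA = c(pur, "N6"),
       G = c(pur, "O6", "N2"), DG = c(pur, "O6", "N2"),
       I = c(pur, "O6"),
       C = c(pyr, "N4"), DC = c(pyr, "N4"),
       U = c(pyr, "O4"), T = c(pyr, "O4", "C7"), DT = c(pyr, "O4", "C7"))
})

.nucPolar <- list(
  A  = list(donor = "N6", acceptor = c("N1", "N3", "N7")),
  DA = list(donor = "N6", acceptor = c("N1", "N3", "N7")),
  G  = list(donor = c("N1", "N2"), acceptor = c("O6", "N3", "N7")),
  DG = list(donor = c("N1", "N2"), acceptor = c("O6", "N3", "N7")),
  I  = list(donor = "N1", acceptor = c("O6", "N3", "N7")),
  C  = list(donor = "N4", acceptor = c("O2", "N3")),
  DC = list(donor = "N4", acceptor = c("O2", "N3")),
  U  = list(donor = "N3", acceptor = c("O2", "O4")),
  T  = list(donor = "N3", acceptor = c("O2", "O4")),
  DT = list(donor = "N3", acceptor = c("O2", "O4"))
)

.flagRow <- function(resName, atomName, donor = FALSE, acceptor = FALSE,
                     positive = FALSE, negative = FALSE, hydrophobic = FALSE) {
  data.frame(resName = resName, atomName = atomName, donor = donor,
             acceptor = acceptor, positive = positive, negative = negative,
             hydrophobic = hydrophobic, stringsAsFactors = FALSE)
}

.buildDefaultFlags <- function() {
  rows <- list()
  for (aa in .AA3) {
    rows[[length(rows) + 1L]] <- .flagRow(aa, "N", donor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(aa, "CA", hydrophobic = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(aa, "C", hydrophobic = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(aa, "O", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(aa, "OXT", acceptor = TRUE)
    pol <- .aaPolar[[aa]]
    for (at in .sidechainAtoms[[aa]]) {
      d <- at %in% (pol$donor %||% character())
      a <- at %in% (pol$acceptor %||% character())
      p <- at %in% (pol$positive %||% character())
      n <- at %in% (pol$negative %||% character())
      rows[[length(rows) + 1L]] <-
        .flagRow(aa, at, donor = d, acceptor = a, positive = p, negative = n,
                 hydrophobic = !(d || a || p || n) &&
                   substr(at, 1L, 1L) %in% c("C", "S"))
    }
  }
  for (nt in .nucleotideNames) {
    pol <- .nucPolar[[nt]]
    for (at in .baseAtomSets[[nt]]) {
      d <- at %in% (pol$donor %||% character())
      a <- at %in% (pol$acceptor %||% character())
      rows[[length(rows) + 1L]] <-
        .flagRow(nt, at, donor = d, acceptor = a,
                 hydrophobic = !(d || a) && substr(at, 1L, 1L) == "C")
    }
    # sugar and phosphate
    for (at in c("C1'", "C2'", "C3'", "C4'", "C5'"))
      rows[[length(rows) + 1L]] <- .flagRow(nt, at, hydrophobic = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "O4'", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "O2'", donor = TRUE,
                                          acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "O3'", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "O5'", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "OP1", acceptor = TRUE,
                                          negative = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "OP2", acceptor = TRUE,
                                          negative = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(nt, "P", hydrophobic = FALSE)
  }
  for (w in c("HOH", "WAT", "DOD"))
    rows[[length(rows) + 1L]] <- .flagRow(w, "O", donor = TRUE,
                                          acceptor = TRUE)
  # generic pyranose atoms for the shipped saccharide codes
  for (sc in defaultSaccharideCodes()) {
    for (at in c("C1", "C2", "C3", "C4", "C5", "C6", "C7", "C8"))
      rows[[length(rows) + 1L]] <- .flagRow(sc, at, hydrophobic = TRUE)
    for (at in c("O1", "O2", "O3", "O4", "O6"))
      rows[[length(rows) + 1L]] <- .flagRow(sc, at, donor = TRUE,
                                            acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(sc, "O5", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(sc, "O7", acceptor = TRUE)
    rows[[length(rows) + 1L]] <- .flagRow(sc, "N2", donor = TRUE)
  }
  do.call(rbind, rows)
}

#' Default chemistry dictionary
#'
#' Builds the shipped [ChemistryDictionary-class]: donor/acceptor/charge/
#' hydrophobicity flags for the 20 standard amino acids, the standard
#' nucleotides (including base-moiety atom sets used for duplex merging),
#' waters (HOH/WAT/DOD) and common saccharide units. The dictionary is fully
#' editable: write it out with [writeChemistryDictionary()], modify, and
#' reload with [readChemistryDictionary()].
#'
#' @return A [ChemistryDictionary-class] object.
#' @examples
#' dict <- defaultChemistry()
#' atomRoles("LYS", "NZ", dict)
#' @export
defaultChemistry <- function() {
  new("ChemistryDictionary",
      flags = .buildDefaultFlags(),
      waterNames = c("HOH", "WAT", "DOD"),
      baseAtoms = .baseAtomSets,
      aminoAcids = .AA3)
}

#' Shipped saccharide residue codes
#'
#' Curated set of three-letter HETATM residue codes treated as monosaccharide
#' units. The full PDB-wide carbohydrate census is much larger; this default
#' covers the common units (N-glycans, blood-group sugars, glycosaminoglycan
#' building blocks) and is extensible via [readSaccharideCodes()].
#'
#' @return Uppercase character vector of residue codes.
#' @export
defaultSaccharideCodes <- function() {
  c("NAG", "NDG", "BMA", "MAN", "GAL", "GLA", "GLC", "BGC", "FUC", "FUL",
    "XYS", "XYP", "SIA", "NGA", "A2G", "RIB", "ARA", "RAM", "GCU", "BDP",
    "IDS", "GCS")
}

#' Atom physicochemical roles
#'
#' Looks up the flag set of one atom. Unknown (residue, atom) combinations
#' yield an empty set, never an error — interaction criteria then simply
#' treat the atom as apolar and uncharged (it still participates in van der
#' Waals contacts).
#'
#' @param resName three-letter residue code.
#' @param atomName PDB atom name (stripped of spaces).
#' @param dict a [ChemistryDictionary-class].
#' @return Character vector, a subset of
#'   `c("donor", "acceptor", "positive", "negative", "hydrophobic")`.
#' @examples
#' atomRoles("ASP", "OD1", defaultChemistry())
#' @export
atomRoles <- function(resName, atomName, dict) {
  stopifnot(is(dict, "ChemistryDictionary"))
  f <- dict@flags
  hit <- f[f$resName == resName & f$atomName == atomName, , drop = FALSE]
  if (nrow(hit) == 0L) return(character())
  flags <- c("donor", "acceptor", "positive", "negative", "hydrophobic")
  flags[vapply(flags, function(fl) any(hit[[fl]]), TRUE)]
}

# Vectorized role lookup used by the contact detector: returns a logical
# matrix (n x 5) aligned with `resName`/`atomName`.
atomRoleMatrix <- function(resName, atomName, dict) {
  f <- dict@flags
  key <- paste(resName, atomName)
  idx <- match(key, paste(f$resName, f$atomName))
  out <- matrix(FALSE, length(key), 5L,
                dimnames = list(NULL, c("donor", "acceptor", "positive",
                                        "negative", "hydrophobic")))
  hitrow <- which(!is.na(idx))
  for (fl in colnames(out)) out[hitrow, fl] <- f[[fl]][idx[hitrow]]
  out
}

#' Read and write the chemistry dictionary and saccharide code list
#'
#' The on-disk format is editable line-oriented text. Records are
#' tab-separated, one per line:
#' \preformatted{
#' atom<TAB>RES<TAB>NAME<TAB>donor,acceptor,positive,negative,hydrophobic (subset)
#' water<TAB>RES
#' nucleotide<TAB>RES<TAB>comma-separated base-moiety atom names
#' aminoacid<TAB>RES
#' }
#' Lines starting with `#` and blank lines are ignored. Flags may be empty
#' (`-`) for atoms with no roles. The saccharide list is one uppercase
#' three-letter code per line.
#'
#' @param path file path.
#' @param dict a [ChemistryDictionary-class] (writer).
#' @param codes character vector of codes (writer).
#' @return `readChemistryDictionary`: a [ChemistryDictionary-class];
#'   `readSaccharideCodes`: uppercase character vector; writers return the
#'   path invisibly.
#' @export
readChemistryDictionary <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list(); waters <- character(); bases <- list(); aas <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    kind <- f[1]
    if (kind == "water") {
      waters <- c(waters, f[2])
    } else if (kind == "aminoacid") {
      aas <- c(aas, f[2])
    } else if (kind == "nucleotide") {
      bases[[f[2]]] <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    } else if (kind == "atom") {
      fl <- if (length(f) >= 4L && f[4] != "-")
        strsplit(f[4], ",", fixed = TRUE)[[1]] else character()
      rows[[length(rows) + 1L]] <-
        .flagRow(f[2], f[3], donor = "donor" %in% fl,
                 acceptor = "acceptor" %in% fl,
                 positive = "positive" %in% fl,
                 negative = "negative" %in% fl,
                 hydrophobic = "hydrophobic" %in% fl)
    } else {
      irStop("unrecognized chemistry dictionary record kind: ", kind)
    }
  }
  new("ChemistryDictionary",
      flags = do.call(rbind, rows) %||% .flagRow(character(), character()),
      waterNames = unique(waters), baseAtoms = bases, aminoAcids = unique(aas))
}

#' @rdname readChemistryDictionary
#' @export
writeChemistryDictionary <- function(dict, path) {
  stopifnot(is(dict, "ChemistryDictionary"))
  out <- c("# chemistry dictionary",
           paste0("aminoacid\t", dict@aminoAcids),
           paste0("water\t", dict@waterNames),
           vapply(names(dict@baseAtoms), function(nt)
             paste0("nucleotide\t", nt, "\t",
                    paste(dict@baseAtoms[[nt]], collapse = ",")), ""))
  f <- dict@flags
  flagcols <- c("donor", "acceptor", "positive", "negative", "hydrophobic")
  fl <- apply(as.matrix(f[flagcols]), 1L, function(v) {
    s <- paste(flagcols[v], collapse = ",")
    if (nzchar(s)) s else "-"
  })
  out <- c(out, paste("atom", f$resName, f$atomName, fl, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' @rdname readChemistryDictionary
#' @export
readSaccharideCodes <- function(path) {
  codes <- trimws(readLines(path))
  codes <- codes[nzchar(codes) & !startsWith(codes, "#")]
  codes <- unique(toupper(codes))
  codes
}

#' @rdname readChemistryDictionary
#' @export
writeSaccharideCodes <- function(codes, path) {
  writeLines(unique(toupper(codes)), path)
  invisible(path)
}
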