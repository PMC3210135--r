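# Fixed-column PDB reading/writing. The reader is deliberately strict about
# the numeric fields (errors name the offending line) and implements the
# model/alt-loc policy used throughout the package: first model only,
# highest-occupancy alternate location (ties broken by the lexicographically
# smallest alt-loc id), hydrogens dropped.

.numField <- function(s, lineno, what) {
  s <- trimws(s)
  if (!nzchar(s)) return(NA_real_)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v))
    irStop(sprintf("malformed PDB line %d: bad %s field '%s'", lineno, what, s))
  v
}

.guessElement <- function(name) {
  # strip digits and primes; leading digit means a hydrogen name like 1HB2
  core <- gsub("[0-9' ]", "", name)
  if (!nzchar(core)) return("")
  two <- toupper(substr(core, 1L, 2L))
  if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")) return(two)
  toupper(substr(core, 1L, 1L))
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM/CONECT records from fixed-column PDB text into a
#' [PDBStructure-class]. For multi-model (e.g. NMR) files only the first
#' model is retained; alternate locations are resolved to the
#' highest-occupancy copy (ties to the lexicographically smallest alt-loc
#' id); hydrogen/deuterium atoms are dropped (all interaction criteria are
#' heavy-atom). CONECT pairs are deduplicated and symmetric.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param pdbId optional structure id; defaults to the HEADER id code, else
#'   the file stem, else "struct".
#' @return A [PDBStructure-class].
#' @examples
#' pdb <- makeAtomPair("GLY", "N", "GLY", "O", 3.5)
#' parseStructure(pdb, pdbId = "pair")
#' @export
parseStructure <- function(input, pdbId = NULL) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    lines <- readLines(input)
    if (is.null(pdbId))
      pdbId <- sub("\\.(pdb|ent)$", "", basename(input), ignore.case = TRUE)
  } else {
    lines <- if (length(input) == 1L) strsplit(input, "\n", fixed = TRUE)[[1]]
             else input
  }
  rec <- substr(lines, 1L, 6L)
  hdr <- which(trimws(rec) == "HEADER")
  if (is.null(pdbId)) {
    pdbId <- if (length(hdr)) trimws(substr(lines[hdr[1L]], 63L, 66L)) else ""
    if (!nzchar(pdbId)) pdbId <- "struct"
  }

  # first model only
  model_starts <- which(trimws(rec) == "MODEL")
  endmdl <- which(trimws(rec) == "ENDMDL")
  keep <- rep(TRUE, length(lines))
  if (length(model_starts) > 0L) {
    stop1 <- if (length(endmdl)) endmdl[1L] else length(lines) + 1L
    keep <- seq_along(lines) > model_starts[1L] & seq_along(lines) < stop1
    # CONECT records sit outside MODEL blocks; keep them regardless
    keep <- keep | trimws(rec) == "CONECT"
  }

  atom_idx <- which(keep & rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0L)
    irStop("empty structure: no ATOM or HETATM records found")

  al <- lines[atom_idx]
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  al <- vapply(al, pad, "", n = 80L, USE.NAMES = FALSE)
  n <- length(al)
  serial <- integer(n); x <- y <- z <- occ <- numeric(n)
  for (i in seq_len(n)) {
    ln <- atom_idx[i]
    serial[i] <- as.integer(.numField(substr(al[i], 7L, 11L), ln, "serial"))
    x[i] <- .numField(substr(al[i], 31L, 38L), ln, "x")
    y[i] <- .numField(substr(al[i], 39L, 46L), ln, "y")
    z[i] <- .numField(substr(al[i], 47L, 54L), ln, "z")
    o <- .numField(substr(al[i], 55L, 60L), ln, "occupancy")
    occ[i] <- if (is.na(o)) 1.0 else o
    if (is.na(x[i]) || is.na(y[i]) || is.na(z[i]))
      irStop(sprintf("malformed PDB line %d: missing coordinate", ln))
  }
  atoms <- data.frame(
    serial = serial,
    name = trimws(substr(al, 13L, 16L)),
    altLoc = trimws(substr(al, 17L, 17L)),
    resName = trimws(substr(al, 18L, 20L)),
    chain = trimws(substr(al, 22L, 22L)),
    seqNum = as.integer(vapply(seq_len(n), function(i)
      .numField(substr(al[i], 23L, 26L), atom_idx[i], "residue number"), 0)),
    insCode = trimws(substr(al, 27L, 27L)),
    x = x, y = y, z = z, occupancy = occ,
    element = trimws(substr(al, 77L, 78L)),
    recordKind = ifelse(rec[atom_idx] == "ATOM  ", "ATOM", "HETATM"),
    stringsAsFactors = FALSE
  )
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- vapply(atoms$name[noel], .guessElement, "")
  atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L)
    irStop("empty structure: only hydrogen atoms found")

  # alt-loc resolution: one copy per (residue, atom name)
  grp <- paste(atomResidueKeys(atoms), atoms$name)
  ord <- order(grp, -atoms$occupancy, atoms$altLoc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(grp[ord]), , drop = FALSE]
  atoms <- atoms[order(match(atoms$serial, serial)), , drop = FALSE]
  rownames(atoms) <- NULL

  # CONECT: symmetric, deduplicated, restricted to retained atoms
  con_idx <- which(trimws(rec) == "CONECT")
  pairs <- matrix(integer(0), 0L, 2L)
  if (length(con_idx)) {
    plist <- list()
    for (ln in con_idx) {
      s <- pad(lines[ln], 31L)
      base <- suppressWarnings(as.integer(trimws(substr(s, 7L, 11L))))
      if (is.na(base)) next
      for (cols in list(c(12L, 16L), c(17L, 21L), c(22L, 26L), c(27L, 31L))) {
        p <- suppressWarnings(as.integer(trimws(substr(s, cols[1], cols[2]))))
        if (!is.na(p)) plist[[length(plist) + 1L]] <- c(base, p)
      }
    }
    if (length(plist)) {
      pairs <- do.call(rbind, plist)
      pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                     pmax(pairs[, 1L], pairs[, 2L]))
      pairs <- unique(pairs)
      ok <- pairs[, 1L] %in% atoms$serial & pairs[, 2L] %in% atoms$serial &
        pairs[, 1L] != pairs[, 2L]
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  storage.mode(pairs) <- "integer"
  colnames(pairs) <- c("serialA", "serialB")
  new("PDBStructure", pdbId = pdbId, atoms = atoms, bonds = pairs)
}

#' Write a structure back to PDB format
#'
#' Emits HEADER, ATOM/HETATM (coordinates to 3 decimals) and CONECT records.
#' A structure written and re-parsed reproduces its atom table exactly.
#'
#' @param structure a [PDBStructure-class].
#' @param path output file; if NULL the lines are returned.
#' @return The PDB lines, invisibly when `path` is given.
#' @export
writeStructure <- function(structure, path = NULL) {
  a <- atoms(structure)
  nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
               sprintf(" %-3s", a$name))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(a$recordKind == "ATOM", "ATOM", "HETATM"),
    a$serial, nm, a$altLoc, a$resName, a$chain, a$seqNum, a$insCode,
    a$x, a$y, a$z, a$occupancy, 0, a$element)
  hdr <- sprintf("%-62s%4s", "HEADER    SYNTHETIC FIXTURE", structure@pdbId)
  b <- bonds(structure)
  con <- if (nrow(b)) sprintf("CONECT%5d%5d", b[, 1L], b[, 2L]) else character()
  out <- c(hdr, lines, con, "END")
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Load domain definitions
#'
#' Reads the tab-separated domain-definition table assigning protein family
#' membership and residue ranges (SCOP-like) to PDB chains. Columns:
#' `domain_id`, `family_id`, `pdb_id`, `chain`, `start`, `end` — one row per
#' segment; rows sharing a `domain_id` form one multi-segment definition.
#' Unknown columns are ignored with a warning.
#'
#' @param input path to a TSV file, or the table text.
#' @return data.frame with columns domainId, familyId, pdbId, chain, start,
#'   end (one row per segment).
#' @export
loadDomainDefinitions <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    df <- utils::read.delim(input, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(textConnection(paste(input, collapse = "\n")),
                            stringsAsFactors = FALSE)
  }
  need <- c("domain_id", "family_id", "pdb_id", "chain", "start", "end")
  extra <- setdiff(names(df), need)
  if (length(extra))
    irWarn("ignoring unknown domain-definition columns: ",
           paste(extra, collapse = ", "))
  missing <- setdiff(need, names(df))
  if (length(missing))
    irStop("domain-definition table is missing columns: ",
           paste(missing, collapse = ", "))
  df <- df[need]
  names(df) <- c("domainId", "familyId", "pdbId", "chain", "start", "end")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- which(df$start > df$end)
  if (length(bad))
    irStop("domain segment with start > end in row(s): ",
           paste(bad, collapse = ", "))
  # a domain id must be owned by a single family and structure
  for (d in unique(df$domainId)) {
    sub <- df[df$domainId == d, ]
    if (length(unique(sub$familyId)) > 1L || length(unique(sub$pdbId)) > 1L)
      irStop("domain ", d, " maps to multiple families or structures")
  }
  df$chain <- as.character(df$chain)
  df
}
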