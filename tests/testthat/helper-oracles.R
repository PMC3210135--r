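# Independent oracles and hand-built objects used across the suite. These
# deliberately avoid the package's spatial index, igraph wrapper and fixture
# writers so that equivalence tests compare two independent routes.

`%||%` <- function(a, b) if (is.null(a)) b else a

# O(n^2) all-pairs contact classifier over two atom tables (data.frames with
# x/y/z/resName/name/serial), mirroring the distance criteria directly.
bruteForceContacts <- function(atomsA, atomsB, dict, cutoffs = c(
    hbond = 3.6, salt = 4.0, vdw = 4.5, covalent = 1.9), conect = NULL) {
  roleOf <- function(at) {
    f <- dict@flags
    hit <- f[f$resName == at$resName & f$atomName == at$name, , drop = FALSE]
    if (nrow(hit) == 0L)
      return(c(donor = FALSE, acceptor = FALSE, positive = FALSE,
               negative = FALSE))
    c(donor = any(hit$donor), acceptor = any(hit$acceptor),
      positive = any(hit$positive), negative = any(hit$negative))
  }
  rolesA <- t(vapply(seq_len(nrow(atomsA)), function(i)
    roleOf(atomsA[i, ]), c(donor = TRUE, acceptor = TRUE, positive = TRUE,
                           negative = TRUE)))
  rolesB <- t(vapply(seq_len(nrow(atomsB)), function(i)
    roleOf(atomsB[i, ]), c(donor = TRUE, acceptor = TRUE, positive = TRUE,
                           negative = TRUE)))
  out <- list()
  for (i in seq_len(nrow(atomsA))) for (j in seq_len(nrow(atomsB))) {
    d <- sqrt((atomsA$x[i] - atomsB$x[j])^2 + (atomsA$y[i] - atomsB$y[j])^2 +
              (atomsA$z[i] - atomsB$z[j])^2)
    if (d > cutoffs[["vdw"]]) next
    if (d <= cutoffs[["covalent"]]) next
    if (!is.null(conect) &&
        any((conect[, 1] == atomsA$serial[i] &
             conect[, 2] == atomsB$serial[j]) |
            (conect[, 2] == atomsA$serial[i] &
             conect[, 1] == atomsB$serial[j]))) next
    hb <- ((rolesA[i, "donor"] && rolesB[j, "acceptor"]) ||
           (rolesA[i, "acceptor"] && rolesB[j, "donor"])) &&
          d <= cutoffs[["hbond"]]
    sb <- ((rolesA[i, "positive"] && rolesB[j, "negative"]) ||
           (rolesA[i, "negative"] && rolesB[j, "positive"])) &&
          d <= cutoffs[["salt"]]
    out[[length(out) + 1L]] <- data.frame(
      serialA = atomsA$serial[i], serialB = atomsB$serial[j], distance = d,
      hbond = hb, saltBridge = sb, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(serialA = integer(), serialB = integer(),
                      distance = numeric(), hbond = logical(),
                      saltBridge = logical()))
  res <- do.call(rbind, out)
  res[order(res$serialA, res$serialB), , drop = FALSE]
}

# vectorized all-pairs oracle: full distance matrix + role lookup by match;
# same criteria as bruteForceContacts but viable for many 500-atom fixtures
bruteForceContactsFast <- function(atomsA, atomsB, dict, cutoffs = c(
    hbond = 3.6, salt = 4.0, vdw = 4.5, covalent = 1.9)) {
  f <- dict@flags
  fkey <- paste(f$resName, f$atomName)
  roleTab <- function(at) {
    idx <- match(paste(at$resName, at$name), fkey)
    cbind(donor = ifelse(is.na(idx), FALSE, f$donor[idx]),
          acceptor = ifelse(is.na(idx), FALSE, f$acceptor[idx]),
          positive = ifelse(is.na(idx), FALSE, f$positive[idx]),
          negative = ifelse(is.na(idx), FALSE, f$negative[idx]))
  }
  rA <- roleTab(atomsA); rB <- roleTab(atomsB)
  D <- sqrt(outer(atomsA$x, atomsB$x, "-")^2 +
            outer(atomsA$y, atomsB$y, "-")^2 +
            outer(atomsA$z, atomsB$z, "-")^2)
  hit <- which(D <= cutoffs[["vdw"]] & D > cutoffs[["covalent"]],
               arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(serialA = integer(), serialB = integer(),
                      distance = numeric(), hbond = logical(),
                      saltBridge = logical()))
  i <- hit[, 1L]; j <- hit[, 2L]; d <- D[hit]
  res <- data.frame(
    serialA = atomsA$serial[i], serialB = atomsB$serial[j], distance = d,
    hbond = ((rA[i, "donor"] & rB[j, "acceptor"]) |
             (rA[i, "acceptor"] & rB[j, "donor"])) &
            d <= cutoffs[["hbond"]],
    saltBridge = ((rA[i, "positive"] & rB[j, "negative"]) |
                  (rA[i, "negative"] & rB[j, "positive"])) &
                 d <= cutoffs[["salt"]])
  res <- res[order(res$serialA, res$serialB), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# realize an arbitrary chain-contact graph as nucleotide geometry: each
# edge gets a dedicated far-away site where the two chains' base atoms sit
# 3 A apart; every chain also has one isolated home site
naGraphStructure <- function(nChains, edges) {
  chains <- LETTERS[seq_len(nChains)]
  lines <- character(); serial <- 1L
  addAtom <- function(chain, seq, x, y) {
    lines <<- c(lines, sprintf(
      "ATOM  %5d  N3  DC  %1s%4d    %8.3f%8.3f   0.000  1.00  0.00           N",
      serial, chain, seq, x, y))
    serial <<- serial + 1L
  }
  seqCounter <- stats::setNames(rep(1L, nChains), chains)
  for (k in seq_len(nChains)) addAtom(chains[k], 1L, 1000 + 20 * k, 0)
  if (length(edges)) for (e in seq_along(edges)) {
    i <- edges[[e]][1L]; j <- edges[[e]][2L]
    seqCounter[i] <- seqCounter[i] + 1L
    seqCounter[j] <- seqCounter[j] + 1L
    addAtom(chains[i], seqCounter[i], 100 * e, 0)
    addAtom(chains[j], seqCounter[j], 100 * e, 3)
  }
  c(lines, "END")
}

# brute-force union-find over an explicit edge list
unionFindComponents <- function(nodes, edgesA, edgesB) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(edgesA))
    parent[[find(edgesA[k])]] <- find(edgesB[k])
  roots <- vapply(nodes, find, "")
  match(roots, unique(roots[order(nodes)]))
}

# transitive-closure single-linkage oracle: repeatedly merge any two
# clusters containing a pair with similarity > cutoff
transitiveClosureClusters <- function(colSets, cutoff) {
  n <- length(colSets)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (labels[i] == labels[j]) next
      a <- colSets[[i]]; b <- colSets[[j]]
      sim <- if (length(a) == 0L || length(b) == 0L) 0 else
        length(intersect(a, b)) / min(length(a), length(b))
      if (sim > cutoff) {
        labels[labels == labels[j]] <- labels[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# random two-chain structure text (plain sprintf; independent of the
# package's writer). Residues carry full default-template atoms so donors,
# acceptors and charges all occur.
randomStructureText <- function(nResPerChain = 40L, box = 30, seed = 1L) {
  set.seed(seed)
  palette <- list(
    GLY = c("N", "CA", "C", "O"),
    ALA = c("N", "CA", "C", "O", "CB"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"))
  lines <- character(); serial <- 1L
  for (chain in c("A", "B")) {
    xoff <- if (chain == "A") 0 else 3.0   # overlapping slabs -> contacts
    for (r in seq_len(nResPerChain)) {
      res <- sample(names(palette), 1L)
      ctr <- stats::runif(3, 0, box)
      for (at in palette[[res]]) {
        xyz <- round(ctr + stats::runif(3, -1.5, 1.5) + c(xoff, 0, 0), 3)
        el <- substr(at, 1L, 1L)
        lines <- c(lines, sprintf(
          "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, sprintf(" %-3s", at), res, chain, r, xyz[1], xyz[2], xyz[3],
          1.0, 0.0, el))
        serial <- serial + 1L
      }
    }
  }
  c(lines, "END")
}

emptyContactTable <- function() {
  data.frame(entityA = character(), chainA = character(), seqA = integer(),
             icodeA = character(), resA = character(), atomA = character(),
             entityB = character(), chainB = character(), seqB = integer(),
             icodeB = character(), resB = character(), atomB = character(),
             distance = numeric(), hbond = logical(), saltBridge = logical(),
             vdw = logical(), bridgingWater = character(),
             stringsAsFactors = FALSE)
}

# hand-built Interface over residues seq numbers on chain A of a domain
mkIface <- function(id, dom, seqs, fam = "famX", ligType = "protein",
                    lig = "L1", complexClass = "hetero",
                    chainClass = "inter", covalent = FALSE, pdb = "x",
                    solvation = "dry") {
  res <- data.frame(chain = "A", seqNum = as.integer(seqs), insCode = "",
                    resName = "ALA", solvation = solvation,
                    chemistry = "hydrophilic", stringsAsFactors = FALSE)
  new("Interface", interfaceId = id, domainId = dom, familyId = fam,
      ligandEntityId = lig, ligandType = ligType, residues = res,
      complexClass = complexClass, chainClass = chainClass,
      covalent = covalent, pdbId = pdb, contacts = emptyContactTable())
}

# hand-built alignment: each member maps residue i (chain A, ALA) -> col i-1
mkAln <- function(fam, members, nRes, nCols = nRes) {
  cm <- lapply(members, function(m) {
    keys <- vapply(seq_len(nRes), function(i)
      paste("A", i, "", "ALA", sep = "|"), "")
    stats::setNames(seq_len(nRes) - 1L, keys)
  })
  names(cm) <- members
  new("FamilyAlignment", familyId = fam, members = members, columnMap = cm,
      nColumns = as.integer(nCols))
}

# fresh toy corpus in a temp dir
corpusFixture <- function(seed = 1L) {
  makeComplexCorpus(tempfile("corpus"), seed = seed)
}
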