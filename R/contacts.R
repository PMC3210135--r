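# Contact detection and classification. Criteria are heavy-atom distances,
# all inclusive (<=): hydrogen bond 3.6 A between a donor and an acceptor,
# salt bridge 4.0 A between oppositely charged atoms, van der Waals 4.5 A
# for any atom pair. A pair may carry several labels (a 3.2 A salt bridge is
# also a hydrogen bond and a vdW contact).

#' Default interaction distance cutoffs
#'
#' @return named numeric vector (Angstrom): hbond 3.6, salt 4.0, vdw 4.5,
#'   covalent 1.9 (exclusion of covalently bonded pairs).
#' @export
defaultCutoffs <- function() c(hbond = 3.6, salt = 4.0, vdw = 4.5,
                               covalent = 1.9)

.emptyContacts <- function() {
  data.frame(entityA = character(), chainA = character(), seqA = integer(),
             icodeA = character(), resA = character(), atomA = character(),
             entityB = character(), chainB = character(), seqB = integer(),
             icodeB = character(), resB = character(), atomB = character(),
             distance = numeric(), hbond = logical(), saltBridge = logical(),
             vdw = logical(), bridgingWater = character(),
             stringsAsFactors = FALSE)
}

#' Detect and classify direct atomic contacts between two entities
#'
#' Every heavy-atom pair within the van der Waals envelope produces one
#' contact record labeled `vdw`; the `hbond` label is added when one atom is
#' a donor and the other an acceptor (either orientation) within the
#' hydrogen-bond cutoff, and `saltBridge` when the atoms are oppositely
#' charged within the salt-bridge cutoff. Covalently bonded pairs (CONECT
#' record or separation within the covalent cutoff) are excluded from the
#' non-covalent contact list.
#'
#' @param structure a [PDBStructure-class] containing both entities.
#' @param entityA,entityB two distinct non-water [Entity-class] objects.
#' @param dict a [ChemistryDictionary-class].
#' @param cutoffs named vector as [defaultCutoffs()].
#' @return Contact data.frame (see [detectWaterBridges()] for the
#'   water-mediated records sharing the same layout). Empty entities give an
#'   empty table.
#' @examples
#' s <- parseStructure(makeAtomPair("LYS", "NZ", "ASP", "OD1", 3.9))
#' es <- typeEntities(s)
#' ents <- entities(es)
#' detectDirectContacts(s, ents[[1]], ents[[2]])
#' @export
detectDirectContacts <- function(structure, entityA, entityB,
                                 dict = defaultChemistry(),
                                 cutoffs = defaultCutoffs()) {
  aA <- entityAtoms(structure, entityA)
  aB <- entityAtoms(structure, entityB)
  if (nrow(aA) == 0L || nrow(aB) == 0L) return(.emptyContacts())
  pr <- neighborPairs(as.matrix(aA[c("x", "y", "z")]),
                      as.matrix(aB[c("x", "y", "z")]), cutoffs[["vdw"]])
  if (nrow(pr) == 0L) return(.emptyContacts())
  cov <- .covalentPairs(structure, aA, aB, cutoffs[["covalent"]])
  if (nrow(cov) > 0L) {
    drop <- paste(pr$i, pr$j) %in% paste(cov$i, cov$j)
    pr <- pr[!drop, , drop = FALSE]
  }
  if (nrow(pr) == 0L) return(.emptyContacts())
  rA <- atomRoleMatrix(aA$resName[pr$i], aA$name[pr$i], dict)
  rB <- atomRoleMatrix(aB$resName[pr$j], aB$name[pr$j], dict)
  hb <- ((rA[, "donor"] & rB[, "acceptor"]) |
         (rA[, "acceptor"] & rB[, "donor"])) & pr$dist <= cutoffs[["hbond"]]
  sb <- ((rA[, "positive"] & rB[, "negative"]) |
         (rA[, "negative"] & rB[, "positive"])) & pr$dist <= cutoffs[["salt"]]
  data.frame(
    entityA = entityId(entityA), chainA = aA$chain[pr$i],
    seqA = aA$seqNum[pr$i], icodeA = aA$insCode[pr$i],
    resA = aA$resName[pr$i], atomA = aA$name[pr$i],
    entityB = entityId(entityB), chainB = aB$chain[pr$j],
    seqB = aB$seqNum[pr$j], icodeB = aB$insCode[pr$j],
    resB = aB$resName[pr$j], atomB = aB$name[pr$j],
    distance = pr$dist, hbond = hb, saltBridge = sb, vdw = TRUE,
    bridgingWater = "", stringsAsFactors = FALSE)
}

# donor/acceptor atoms of an entity within `cutoff` of a point; returns
# per-residue minimum distance and the closest qualifying atom
.waterLegs <- function(atomsE, wxyz, dict, cutoff) {
  roles <- atomRoleMatrix(atomsE$resName, atomsE$name, dict)
  polar <- roles[, "donor"] | roles[, "acceptor"]
  ae <- atomsE[polar, , drop = FALSE]
  if (nrow(ae) == 0L) return(NULL)
  d <- sqrt((ae$x - wxyz[1])^2 + (ae$y - wxyz[2])^2 + (ae$z - wxyz[3])^2)
  ok <- d <= cutoff
  if (!any(ok)) return(NULL)
  ae <- ae[ok, , drop = FALSE]; d <- d[ok]
  keys <- atomResidueKeys(ae)
  best <- tapply(seq_along(d), keys, function(ii) ii[which.min(d[ii])])
  idx <- as.integer(best)
  data.frame(key = names(best), chain = ae$chain[idx], seqNum = ae$seqNum[idx],
             insCode = ae$insCode[idx], resName = ae$resName[idx],
             atom = ae$name[idx], dist = d[idx], stringsAsFactors = FALSE)
}

#' Detect water-mediated residue interactions
#'
#' Two residues on opposite sides of an interface interact through a water
#' molecule when each has at least one donor or acceptor atom within the
#' hydrogen-bond cutoff of that water's oxygen. One record is synthesized per
#' (residue A, residue B, water) triple; its distance is the longer of the
#' two residue-water legs and its `bridgingWater` field names the water
#' entity. Only single-water bridges are considered.
#'
#' @param structure a [PDBStructure-class].
#' @param entityA,entityB the two non-water entities.
#' @param waters list of water entities ([detectWaters()]).
#' @param dict a [ChemistryDictionary-class].
#' @param cutoffs named vector as [defaultCutoffs()] (uses `hbond`).
#' @return Contact data.frame with `bridgingWater` set.
#' @export
detectWaterBridges <- function(structure, entityA, entityB, waters,
                               dict = defaultChemistry(),
                               cutoffs = defaultCutoffs()) {
  aA <- entityAtoms(structure, entityA)
  aB <- entityAtoms(structure, entityB)
  out <- list()
  for (w in waters) {
    wa <- entityAtoms(structure, w)
    wa <- wa[wa$element == "O", , drop = FALSE]
    if (nrow(wa) == 0L) next
    wxyz <- c(wa$x[1L], wa$y[1L], wa$z[1L])
    legA <- .waterLegs(aA, wxyz, dict, cutoffs[["hbond"]])
    if (is.null(legA)) next
    legB <- .waterLegs(aB, wxyz, dict, cutoffs[["hbond"]])
    if (is.null(legB)) next
    for (i in seq_len(nrow(legA))) for (j in seq_len(nrow(legB))) {
      out[[length(out) + 1L]] <- data.frame(
        entityA = entityId(entityA), chainA = legA$chain[i],
        seqA = legA$seqNum[i], icodeA = legA$insCode[i],
        resA = legA$resName[i], atomA = legA$atom[i],
        entityB = entityId(entityB), chainB = legB$chain[j],
        seqB = legB$seqNum[j], icodeB = legB$insCode[j],
        resB = legB$resName[j], atomB = legB$atom[j],
        distance = max(legA$dist[i], legB$dist[j]),
        hbond = TRUE, saltBridge = FALSE, vdw = FALSE,
        bridgingWater = entityId(w), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(.emptyContacts())
  do.call(rbind, out)
}

#' Build a domain-side interface with one ligand entity
#'
#' Assembles the [Interface-class] between a protein domain and a ligand
#' entity (another domain, a peptide, a DNA/RNA unit or an
#' oligosaccharide): direct contacts plus water-mediated bridges, residue
#' solvation (dry = direct only, wet = water-mediated only, dual = both),
#' residue chemistry (hydrophobic only when every contacting atom of the
#' residue is flagged hydrophobic), the homo/hetero complex class (homo =
#' ligand is a domain of the same family), the intra/inter chain class
#' (intra = shares a chain with the ligand), and a covalency flag
#' (glycosylated saccharide ligands).
#'
#' @param structure a [PDBStructure-class].
#' @param domain a domain [Entity-class].
#' @param ligand any non-water [Entity-class].
#' @param waters water entities for bridge detection.
#' @param dict a [ChemistryDictionary-class].
#' @param cutoffs named vector as [defaultCutoffs()].
#' @param interfaceId id to assign ("IF_<n>").
#' @return An [Interface-class], or NULL when there is no contact at all.
#' @export
buildInterface <- function(structure, domain, ligand, waters = list(),
                           dict = defaultChemistry(),
                           cutoffs = defaultCutoffs(),
                           interfaceId = "IF_1") {
  stopifnot(entityType(domain) == "domain",
            entityType(ligand) != "water")
  direct <- detectDirectContacts(structure, domain, ligand, dict, cutoffs)
  bridged <- detectWaterBridges(structure, domain, ligand, waters, dict,
                                cutoffs)
  if (nrow(direct) == 0L && nrow(bridged) == 0L) return(NULL)
  all_c <- rbind(direct, bridged)

  dryKeys <- unique(residueKey(direct$chainA, direct$seqA, direct$icodeA,
                               direct$resA))
  wetKeys <- unique(residueKey(bridged$chainA, bridged$seqA, bridged$icodeA,
                               bridged$resA))
  keys <- sort(unique(c(dryKeys, wetKeys)))
  solv <- ifelse(keys %in% dryKeys & keys %in% wetKeys, "dual",
                 ifelse(keys %in% dryKeys, "dry", "wet"))
  ckeys <- residueKey(all_c$chainA, all_c$seqA, all_c$icodeA, all_c$resA)
  chem <- vapply(keys, function(k) {
    at <- all_c[ckeys == k, , drop = FALSE]
    roles <- atomRoleMatrix(at$resA, at$atomA, dict)
    if (all(roles[, "hydrophobic"])) "hydrophobic" else "hydrophilic"
  }, "")
  resTab <- residueTableFromKeys(keys)
  resTab$solvation <- solv
  resTab$chemistry <- unname(chem)
  # preserve structure residue order
  ordIdx <- order(match(keys, unique(atomResidueKeys(atoms(structure)))))
  resTab <- resTab[ordIdx, , drop = FALSE]
  rownames(resTab) <- NULL

  cov <- nrow(.covalentPairs(structure, entityAtoms(structure, domain),
                             entityAtoms(structure, ligand),
                             cutoffs[["covalent"]])) > 0L
  complexClass <- if (entityType(ligand) == "domain" &&
                      familyId(ligand) == familyId(domain)) "homo" else "hetero"
  chainClass <- if (length(intersect(domain@memberChains,
                                     ligand@memberChains)) > 0L || cov)
    "intra" else "inter"
  ligType <- if (entityType(ligand) == "domain") "protein"
             else entityType(ligand)
  new("Interface", interfaceId = interfaceId, domainId = entityId(domain),
      familyId = familyId(domain), ligandEntityId = entityId(ligand),
      ligandType = ligType, residues = resTab, complexClass = complexClass,
      chainClass = chainClass, covalent = cov, pdbId = pdbId(structure),
      contacts = all_c)
}

#' All interfaces of a typed structure
#'
#' Builds every domain-vs-ligand interface of an [EntitySet-class]: each
#' domain is paired with every other non-water entity (domains, peptides,
#' nucleic-acid units, oligosaccharides). Domain-domain pairs yield one
#' interface per side. Ids are assigned deterministically in sorted
#' (domain, ligand) order starting at `idStart`.
#'
#' @param structure a [PDBStructure-class].
#' @param entitySet the [EntitySet-class] of `structure`.
#' @param dict a [ChemistryDictionary-class].
#' @param cutoffs named vector as [defaultCutoffs()].
#' @param idStart first integer for "IF_<n>" ids.
#' @return list of [Interface-class] objects.
#' @export
structureInterfaces <- function(structure, entitySet,
                                dict = defaultChemistry(),
                                cutoffs = defaultCutoffs(), idStart = 1L) {
  ents <- entities(entitySet)
  tp <- vapply(ents, entityType, "")
  ids <- vapply(ents, entityId, "")
  ord <- order(ids)
  ents <- ents[ord]; tp <- tp[ord]; ids <- ids[ord]
  waters <- ents[tp == "water"]
  doms <- ents[tp == "domain"]
  out <- list(); n <- idStart
  for (d in doms) {
    for (k in seq_along(ents)) {
      if (tp[k] == "water" || ids[k] == entityId(d)) next
      iface <- buildInterface(structure, d, ents[[k]], waters, dict, cutoffs,
                              interfaceId = paste0("IF_", n))
      if (!is.null(iface)) {
        out[[length(out) + 1L]] <- iface
        n <- n + 1L
      }
    }
  }
  out
}

#' Filter crystal-packing interfaces
#'
#' Crystal contacts are artifacts of the lattice, not biology. With a
#' classifier hook (an external predicate returning the probability that an
#' interface is biological, e.g. an SVM such as NOXclass), interfaces below
#' `cutoff` (default 0.70) are dropped; a hook error keeps the interface and
#' logs the error. Without a hook no filtering occurs and a warning is
#' logged. The built-in `mode = "naive"` heuristic — drop protein-protein
#' interfaces with fewer than `minResidues` interface residues — is opt-in
#' and is NOT the SVM classifier; it is a crude size screen only.
#'
#' @param interfaces list of [Interface-class].
#' @param classifierHook function(interface) -> probability in `[0,1]`, or
#'   NULL.
#' @param mode "off", "hook" or "naive".
#' @param cutoff biological-probability cutoff (default 0.70).
#' @param minResidues naive-mode minimum interface size (default 5).
#' @return filtered list of interfaces.
#' @export
filterCrystalPacking <- function(interfaces, classifierHook = NULL,
                                 mode = c("hook", "off", "naive"),
                                 cutoff = 0.70, minResidues = 5L) {
  mode <- match.arg(mode)
  if (mode == "off") return(interfaces)
  if (mode == "naive") {
    keep <- vapply(interfaces, function(i)
      !(ligandType(i) == "protein" && nrow(residues(i)) < minResidues), TRUE)
    return(interfaces[keep])
  }
  if (is.null(classifierHook)) {
    irWarn("no crystal-packing classifier hook supplied; no filtering done")
    return(interfaces)
  }
  keep <- vapply(interfaces, function(i) {
    p <- tryCatch(classifierHook(i), error = function(e) {
      irWarn("packing classifier failed for ", interfaceId(i), ": ",
             conditionMessage(e), " (interface kept)")
      NA_real_
    })
    is.na(p) || p >= cutoff
  }, TRUE)
  interfaces[keep]
}

#' Write a contact table
#'
#' TSV with entity ids, residue keys, atom names, distance (2 decimals),
#' labels and bridging water.
#'
#' @param contactTable data.frame from [detectDirectContacts()] /
#'   [detectWaterBridges()], or an [Interface-class].
#' @param path output path.
#' @return path, invisibly.
#' @export
writeContactTable <- function(contactTable, path) {
  if (is(contactTable, "Interface")) contactTable <- contacts(contactTable)
  ct <- contactTable
  ct$distance <- sprintf("%.2f", ct$distance)
  utils::write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interface summary as JSON-ready list
#'
#' Mirrors the residue-residue interaction listing: per-residue
#' physicochemical and water-mediation properties plus the classified
#' contact records.
#'
#' @param interface an [Interface-class].
#' @param path optional path to write JSON.
#' @return list (invisibly the path when written).
#' @export
interfaceSummary <- function(interface, path = NULL) {
  res <- residues(interface)
  out <- list(
    interface_id = interfaceId(interface),
    pdb_id = pdbId(interface),
    domain_id = domainId(interface),
    family_id = familyId(interface),
    ligand_entity = ligandEntityId(interface),
    ligand_type = ligandType(interface),
    complex_class = complexClass(interface),
    chain_class = chainClass(interface),
    covalent = interface@covalent,
    residues = res,
    contacts = contacts(interface))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    return(invisible(path))
  }
  out
}
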