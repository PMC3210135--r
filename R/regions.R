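# Binding-region classification: interfaces of one family are expressed as
# sets of structure-based alignment columns and clustered by
# interacting-residue overlap (single linkage over a similarity graph).
# Columns are 0-based internally and 1-based in every written report.

#' Load a family structure-based alignment
#'
#' Reads a gapped FASTA multiple alignment whose sequence names are member
#' domain ids, and derives each member's residue-to-column map by ungapped
#' position counting against the member domain's ordered observed residues:
#' the i-th non-gap column of a member row corresponds to its i-th residue.
#'
#' @param input FASTA path (or character vector of FASTA text lines).
#' @param familyId family id the alignment belongs to.
#' @param domainEntities list of domain [Entity-class] objects supplying the
#'   ordered residues of each member (matched by entity id); members with no
#'   entity provided get an empty map with a warning.
#' @return A [FamilyAlignment-class].
#' @export
familyAlignment <- function(input, familyId, domainEntities = list()) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    seqs <- Biostrings::readAAStringSet(input)
  } else {
    tmp <- tempfile(fileext = ".fasta")
    writeLines(if (length(input) == 1L) strsplit(input, "\n")[[1]] else input,
               tmp)
    on.exit(unlink(tmp))
    seqs <- Biostrings::readAAStringSet(tmp)
  }
  members <- names(seqs)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) > 1L)
    irStop("alignment rows have unequal widths for family ", familyId)
  nCol <- as.integer(widths[1L])
  eIds <- vapply(domainEntities, entityId, "")
  columnMap <- stats::setNames(vector("list", length(members)), members)
  for (m in members) {
    chars <- strsplit(as.character(seqs[[m]]), "")[[1]]
    nonGap <- which(!chars %in% c("-", "."))
    ent <- domainEntities[[match(m, eIds)]]
    if (is.na(match(m, eIds)) || is.null(ent)) {
      irWarn("no domain entity supplied for alignment member ", m,
             "; its residues cannot be mapped")
      columnMap[[m]] <- stats::setNames(integer(), character())
      next
    }
    res <- residues(ent)
    keys <- residueKey(res$chain, res$seqNum, res$insCode, res$resName)
    n <- min(length(nonGap), length(keys))
    if (length(nonGap) != length(keys))
      irWarn("alignment member ", m, ": ", length(nonGap),
             " aligned positions vs ", length(keys),
             " observed residues; mapping the first ", n)
    columnMap[[m]] <- stats::setNames(as.integer(nonGap[seq_len(n)] - 1L),
                                      keys[seq_len(n)])
  }
  new("FamilyAlignment", familyId = familyId, members = members,
      columnMap = columnMap, nColumns = nCol)
}

#' Map an interface's residues to alignment columns
#'
#' @param interface an [Interface-class] whose domain is an alignment member.
#' @param alignment a [FamilyAlignment-class].
#' @return list(columns = sorted 0-based integer columns,
#'   unmapped = number of interface residues absent from the column map).
#' @export
mapInterfaceToColumns <- function(interface, alignment) {
  d <- domainId(interface)
  if (!d %in% alignmentMembers(alignment))
    irStop("domain ", d, " is not a member of the alignment of family ",
           familyId(alignment))
  cm <- alignment@columnMap[[d]]
  res <- residues(interface)
  keys <- residueKey(res$chain, res$seqNum, res$insCode, res$resName)
  hit <- cm[keys]
  list(columns = sort(unique(as.integer(hit[!is.na(hit)]))),
       unmapped = sum(is.na(hit)))
}

#' Binding-region similarity of two column sets
#'
#' Interacting-residue overlap normalized by the smaller set:
#' `|a n b| / min(|a|, |b|)`, so a sub-region fully contained in a larger
#' region scores 1. Two empty sets score 0 by convention.
#'
#' @param colsA,colsB integer column sets.
#' @return fraction in `[0, 1]`.
#' @examples
#' regionSimilarity(c(1, 2, 3), c(2, 3, 4))  # 2/3
#' @export
regionSimilarity <- function(colsA, colsB) {
  colsA <- unique(colsA); colsB <- unique(colsB)
  if (length(colsA) == 0L || length(colsB) == 0L) return(0)
  length(intersect(colsA, colsB)) / min(length(colsA), length(colsB))
}

#' Cluster a family's interfaces into binding regions
#'
#' Interfaces are nodes; an edge joins two interfaces when their mapped
#' column sets have similarity strictly greater than `cutoff`; regions are
#' the connected components (single linkage). At the default zero cutoff any
#' shared column joins two interfaces. Region ids are assigned
#' deterministically in order of each component's smallest interface id.
#'
#' @param interfaces list of [Interface-class] of one family.
#' @param alignment the family's [FamilyAlignment-class].
#' @param cutoff similarity cutoff in `[0, 1]` (default 0).
#' @param idStart first integer for "BR_<n>" ids.
#' @return list(regions = list of [BindingRegion-class],
#'   excluded = ids of interfaces whose domain is not an alignment member).
#' @export
clusterRegions <- function(interfaces, alignment, cutoff = 0, idStart = 1L) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ids <- vapply(interfaces, interfaceId, "")
  member <- vapply(interfaces, function(i)
    domainId(i) %in% alignmentMembers(alignment), TRUE)
  excluded <- ids[!member]
  if (length(excluded))
    irWarn("interface(s) excluded from clustering (domain not in alignment): ",
           paste(excluded, collapse = ", "))
  interfaces <- interfaces[member]; ids <- ids[member]
  if (length(interfaces) == 0L)
    return(list(regions = list(), excluded = excluded))
  ord <- order(ids)
  interfaces <- interfaces[ord]; ids <- ids[ord]
  cols <- lapply(interfaces, function(i)
    mapInterfaceToColumns(i, alignment)$columns)
  ea <- character(); eb <- character()
  n <- length(ids)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (regionSimilarity(cols[[i]], cols[[j]]) > cutoff) {
      ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
    }
  }
  comp <- edgeListComponents(ids, ea, eb)
  regions <- list()
  for (k in sort(unique(comp))) {
    sel <- which(comp == k)
    regions[[length(regions) + 1L]] <- new(
      "BindingRegion",
      regionId = paste0("BR_", idStart + k - 1L),
      familyId = familyId(alignment),
      columnSet = sort(unique(unlist(cols[sel]))),
      interfaceIds = ids[sel], origin = "observed", cutoffUsed = cutoff,
      coverage = NA_real_, sourceRegionIds = character(),
      sourceFamilyIds = character(),
      predictedInterfaces = data.frame(sourceInterfaceId = character(),
                                       ligandType = character(),
                                       stringsAsFactors = FALSE))
  }
  list(regions = regions, excluded = excluded)
}

#' Ligand-type / complex-type / interaction-type search filter
#'
#' @param types NULL for any, or a subset of protein, peptide, dna, rna,
#'   saccharide. Selecting several types is conjunctive: a region is kept
#'   only when it recognizes ALL selected types through the same region.
#' @param complexType "any", "homo" or "hetero".
#' @param interactionType "any", "intra" or "inter".
#' @return A validated filter object.
#' @export
ligandTypeFilter <- function(types = NULL, complexType = c("any", "homo",
                                                           "hetero"),
                             interactionType = c("any", "intra", "inter")) {
  if (!is.null(types)) {
    bad <- setdiff(types, c("protein", "peptide", "dna", "rna", "saccharide"))
    if (length(bad)) irStop("unknown ligand type(s): ",
                            paste(bad, collapse = ", "))
    if (length(types) == 0L) irStop("ligand type set must be non-empty")
  }
  structure(list(types = types, complexType = match.arg(complexType),
                 interactionType = match.arg(interactionType)),
            class = "LigandTypeFilter")
}

.regionRecord <- function(region, ifMeta) {
  # ifMeta: data.frame of interface metadata for this region's interfaces
  rec <- list(regionId = regionId(region), origin = regionOrigin(region),
              cutoff = region@cutoffUsed,
              columns = as.integer(columnSet(region)) + 1L)
  if (regionOrigin(region) == "predicted") {
    rec$coverage <- coverage(region)
    rec$sourceRegionIds <- region@sourceRegionIds
    rec$sourceFamilyIds <- region@sourceFamilyIds
    pi <- region@predictedInterfaces
    groups <- list()
    for (t in sort(unique(pi$ligandType))) {
      m <- pi[pi$ligandType == t, , drop = FALSE]
      m <- m[order(m$sourceInterfaceId), , drop = FALSE]
      rownames(m) <- NULL
      groups[[length(groups) + 1L]] <-
        list(ifId = paste0("pred:", m$sourceInterfaceId[1L]),
             ligandKey = paste0("type:", t), ligandType = t,
             predicted = TRUE, members = m)
    }
    rec$ifGroups <- groups
    return(rec)
  }
  groups <- list()
  for (gk in sort(unique(ifMeta$ligandKey))) {
    m <- ifMeta[ifMeta$ligandKey == gk, , drop = FALSE]
    m <- m[order(m$interfaceId), , drop = FALSE]
    rownames(m) <- NULL
    groups[[length(groups) + 1L]] <-
      list(ifId = m$interfaceId[1L], ligandKey = gk,
           ligandType = m$ligandType[1L], predicted = FALSE,
           members = m[setdiff(names(m), "ligandKey")])
  }
  rec$ifGroups <- groups
  rec
}

.interfaceMeta <- function(interfaces) {
  if (length(interfaces) == 0L)
    return(data.frame(interfaceId = character(), pdbId = character(),
                      domainId = character(), familyId = character(),
                      ligandEntityId = character(), ligandType = character(),
                      complexClass = character(), chainClass = character(),
                      covalent = logical(), nResidues = integer(),
                      ligandKey = character(), stringsAsFactors = FALSE))
  fam_of_entity <- stats::setNames(
    vapply(interfaces, familyId, ""), vapply(interfaces, domainId, ""))
  meta <- data.frame(
    interfaceId = vapply(interfaces, interfaceId, ""),
    pdbId = vapply(interfaces, pdbId, ""),
    domainId = vapply(interfaces, domainId, ""),
    familyId = vapply(interfaces, familyId, ""),
    ligandEntityId = vapply(interfaces, ligandEntityId, ""),
    ligandType = vapply(interfaces, ligandType, ""),
    complexClass = vapply(interfaces, complexClass, ""),
    chainClass = vapply(interfaces, chainClass, ""),
    covalent = vapply(interfaces, function(i) i@covalent, TRUE),
    nResidues = vapply(interfaces, function(i) nrow(residues(i)), 1L),
    stringsAsFactors = FALSE)
  # interfaces sharing a ligand partner family (protein ligands) or ligand
  # type (other ligands) group together at the IF level
  partnerFam <- fam_of_entity[meta$ligandEntityId]
  meta$ligandKey <- ifelse(meta$ligandType == "protein" & !is.na(partnerFam),
                           paste0("fam:", partnerFam),
                           paste0("type:", meta$ligandType))
  meta
}

#' Assemble the family / binding-region / interface hierarchy
#'
#' Orders families, their binding regions and interface groups
#' deterministically. Interfaces binding a ligand of the same partner family
#' (protein ligands) or the same ligand type (peptide/NA/saccharide ligands)
#' share one IF group within a region.
#'
#' @param regions list of [BindingRegion-class] (observed and/or predicted).
#' @param interfaces list of [Interface-class] referenced by the observed
#'   regions (supplies per-interface metadata).
#' @param cutoff clustering cutoff the regions were built at.
#' @return An [InteractionHierarchy-class].
#' @export
assembleHierarchy <- function(regions, interfaces, cutoff = 0) {
  meta <- .interfaceMeta(interfaces)
  fams <- sort(unique(vapply(regions, familyId, "")))
  families <- list()
  for (f in fams) {
    regs <- Filter(function(r) familyId(r) == f, regions)
    rid_num <- vapply(regs, function(r)
      suppressWarnings(as.integer(sub("^BR_", "", regionId(r)))), 1L)
    regs <- regs[order(rid_num, vapply(regs, regionId, ""))]
    recs <- lapply(regs, function(r)
      .regionRecord(r, meta[meta$interfaceId %in% interfaceIds(r), ,
                            drop = FALSE]))
    families[[f]] <- list(familyId = f, regions = recs)
  }
  new("InteractionHierarchy", families = families, cutoff = cutoff)
}

#' Apply search filters to a hierarchy
#'
#' Homo/hetero and intra/inter filters drop non-matching interfaces;
#' covalent (glycosylation) interfaces are dropped unless
#' `includeCovalent = TRUE`; a conjunctive ligand-type selection then keeps
#' only regions whose remaining interfaces cover all selected types, and
#' finally empty regions and families are removed.
#'
#' @param hierarchy an [InteractionHierarchy-class].
#' @param filter a [ligandTypeFilter()].
#' @param includeCovalent keep covalently linked (glycosylation) interfaces?
#' @return the filtered [InteractionHierarchy-class].
#' @export
applySearchFilters <- function(hierarchy, filter = ligandTypeFilter(),
                               includeCovalent = FALSE) {
  stopifnot(inherits(filter, "LigandTypeFilter"))
  fams <- hierarchyFamilies(hierarchy)
  out <- list()
  for (f in names(fams)) {
    regs <- list()
    for (rec in fams[[f]]$regions) {
      groups <- list()
      for (g in rec$ifGroups) {
        if (!is.null(filter$types) && !(g$ligandType %in% filter$types)) next
        if (isTRUE(g$predicted)) { groups[[length(groups) + 1L]] <- g; next }
        m <- g$members
        if (!includeCovalent) m <- m[!m$covalent, , drop = FALSE]
        if (filter$complexType != "any")
          m <- m[m$complexClass == filter$complexType, , drop = FALSE]
        if (filter$interactionType != "any")
          m <- m[m$chainClass == filter$interactionType, , drop = FALSE]
        if (nrow(m) == 0L) next
        g$members <- m
        groups[[length(groups) + 1L]] <- g
      }
      if (length(groups) == 0L) next
      have <- unique(vapply(groups, function(g) g$ligandType, ""))
      if (!is.null(filter$types) && !all(filter$types %in% have)) next
      rec$ifGroups <- groups
      regs[[length(regs) + 1L]] <- rec
    }
    if (length(regs)) out[[f]] <- list(familyId = f, regions = regs)
  }
  new("InteractionHierarchy", families = out, cutoff = hierarchy@cutoff)
}

#' Write a hierarchy as nested JSON or flat TSV
#'
#' JSON mirrors the FA -> BR -> IF nesting (columns 1-based); the flat table
#' has one row per interface with its region id and cutoff.
#'
#' @param hierarchy an [InteractionHierarchy-class].
#' @param path output path.
#' @return `hierarchyTable` returns the data.frame; writers return the path
#'   invisibly.
#' @export
writeHierarchy <- function(hierarchy, path) {
  jsonlite::write_json(
    list(cutoff = hierarchy@cutoff,
         families = unname(hierarchyFamilies(hierarchy))),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname writeHierarchy
#' @export
hierarchyTable <- function(hierarchy) {
  rows <- list()
  for (f in hierarchyFamilies(hierarchy)) for (rec in f$regions) {
    if (rec$origin == "predicted") {
      pi <- do.call(rbind, lapply(rec$ifGroups, function(g) g$members))
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = f$familyId, region_id = rec$regionId, origin = rec$origin,
        cutoff = rec$cutoff, if_id = vapply(rec$ifGroups, function(g)
          g$ifId, "")[1L],
        interface_id = paste(pi$sourceInterfaceId, collapse = ","),
        ligand_type = paste(sort(unique(pi$ligandType)), collapse = ","),
        domain_id = "", ligand_entity = "", complex_class = "",
        chain_class = "", covalent = FALSE,
        coverage = rec$coverage, stringsAsFactors = FALSE)
      next
    }
    for (g in rec$ifGroups) for (k in seq_len(nrow(g$members))) {
      m <- g$members[k, ]
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = f$familyId, region_id = rec$regionId, origin = rec$origin,
        cutoff = rec$cutoff, if_id = g$ifId, interface_id = m$interfaceId,
        ligand_type = m$ligandType, domain_id = m$domainId,
        ligand_entity = m$ligandEntityId, complex_class = m$complexClass,
        chain_class = m$chainClass, covalent = m$covalent,
        coverage = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(family_id = character(), region_id = character(),
                      origin = character(), cutoff = numeric(),
                      if_id = character(), interface_id = character(),
                      ligand_type = character(), domain_id = character(),
                      ligand_entity = character(), complex_class = character(),
                      chain_class = character(), covalent = logical(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' @rdname writeHierarchy
#' @export
writeHierarchyTable <- function(hierarchy, path) {
  utils::write.table(hierarchyTable(hierarchy), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
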