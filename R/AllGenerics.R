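#' @name accessors
#' @title Accessors for InterfaceRegions classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an object of the documented classes.
#' @return The slot value; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "PDBStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setMethod("bonds", "PDBStructure", function(x) x@bonds)

#' @rdname accessors
#' @export
setGeneric("pdbId", function(x) standardGeneric("pdbId"))
#' @rdname accessors
#' @export
setMethod("pdbId", "PDBStructure", function(x) x@pdbId)
#' @rdname accessors
#' @export
setMethod("pdbId", "EntitySet", function(x) x@pdbId)
#' @rdname accessors
#' @export
setMethod("pdbId", "Interface", function(x) x@pdbId)

#' @rdname accessors
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))
#' @rdname accessors
#' @export
setMethod("entities", "EntitySet", function(x) x@entities)

#' @rdname accessors
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))
#' @rdname accessors
#' @export
setMethod("entityId", "Entity", function(x) x@entityId)

#' @rdname accessors
#' @export
setGeneric("entityType", function(x) standardGeneric("entityType"))
#' @rdname accessors
#' @export
setMethod("entityType", "Entity", function(x) x@entityType)

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setMethod("residues", "Entity", function(x) x@residues)
#' @rdname accessors
#' @export
setMethod("residues", "Interface", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @rdname accessors
#' @export
setMethod("familyId", "Entity", function(x) x@familyId)
#' @rdname accessors
#' @export
setMethod("familyId", "Interface", function(x) x@familyId)
#' @rdname accessors
#' @export
setMethod("familyId", "FamilyAlignment", function(x) x@familyId)
#' @rdname accessors
#' @export
setMethod("familyId", "BindingRegion", function(x) x@familyId)

#' @rdname accessors
#' @export
setGeneric("covalentToProtein", function(x) standardGeneric("covalentToProtein"))
#' @rdname accessors
#' @export
setMethod("covalentToProtein", "Entity", function(x) x@covalentToProtein)

#' @rdname accessors
#' @export
setGeneric("interfaceId", function(x) standardGeneric("interfaceId"))
#' @rdname accessors
#' @export
setMethod("interfaceId", "Interface", function(x) x@interfaceId)

#' @rdname accessors
#' @export
setGeneric("domainId", function(x) standardGeneric("domainId"))
#' @rdname accessors
#' @export
setMethod("domainId", "Interface", function(x) x@domainId)

#' @rdname accessors
#' @export
setGeneric("ligandType", function(x) standardGeneric("ligandType"))
#' @rdname accessors
#' @export
setMethod("ligandType", "Interface", function(x) x@ligandType)

#' @rdname accessors
#' @export
setGeneric("ligandEntityId", function(x) standardGeneric("ligandEntityId"))
#' @rdname accessors
#' @export
setMethod("ligandEntityId", "Interface", function(x) x@ligandEntityId)

#' @rdname accessors
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))
#' @rdname accessors
#' @export
setMethod("contacts", "Interface", function(x) x@contacts)

#' @rdname accessors
#' @export
setGeneric("complexClass", function(x) standardGeneric("complexClass"))
#' @rdname accessors
#' @export
setMethod("complexClass", "Interface", function(x) x@complexClass)

#' @rdname accessors
#' @export
setGeneric("chainClass", function(x) standardGeneric("chainClass"))
#' @rdname accessors
#' @export
setMethod("chainClass", "Interface", function(x) x@chainClass)

#' @rdname accessors
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))
#' @rdname accessors
#' @export
setMethod("regionId", "BindingRegion", function(x) x@regionId)

#' @rdname accessors
#' @export
setGeneric("columnSet", function(x) standardGeneric("columnSet"))
#' @rdname accessors
#' @export
setMethod("columnSet", "BindingRegion", function(x) x@columnSet)

#' @rdname accessors
#' @export
setGeneric("regionOrigin", function(x) standardGeneric("regionOrigin"))
#' @rdname accessors
#' @export
setMethod("regionOrigin", "BindingRegion", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("interfaceIds", function(x) standardGeneric("interfaceIds"))
#' @rdname accessors
#' @export
setMethod("interfaceIds", "BindingRegion", function(x) x@interfaceIds)

#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))
#' @rdname accessors
#' @export
setMethod("coverage", "BindingRegion", function(x) x@coverage)

#' @rdname accessors
#' @export
setGeneric("alignmentMembers", function(x) standardGeneric("alignmentMembers"))
#' @rdname accessors
#' @export
setMethod("alignmentMembers", "FamilyAlignment", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("hierarchyFamilies", function(x) standardGeneric("hierarchyFamilies"))
#' @rdname accessors
#' @export
setMethod("hierarchyFamilies", "InteractionHierarchy", function(x) x@families)

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure", object@pdbId, "\n")
  cat(" ", nrow(a), "atoms,", length(unique(atomResidueKeys(a))), "residues,",
      length(unique(a$chain)), "chain(s),", nrow(object@bonds),
      "CONECT bond(s)\n")
})

setMethod("show", "Entity", function(object) {
  cat("Entity", object@entityId, sprintf("[%s]", object@entityType),
      nrow(object@residues), "residue(s), chains",
      paste(object@memberChains, collapse = ","))
  if (object@entityType == "domain") cat(" family", object@familyId)
  if (object@entityType == "saccharide" && isTRUE(object@covalentToProtein))
    cat(" (covalent to protein)")
  cat("\n")
})

setMethod("show", "EntitySet", function(object) {
  cat("EntitySet for", object@pdbId, "-", length(object@entities),
      "entities\n")
  tp <- vapply(object@entities, entityType, "")
  for (t in .entityTypes) if (any(tp == t)) cat(" ", sum(tp == t), t, "\n")
  if (nrow(object@report) > 0L)
    cat("  report:", nrow(object@report), "excluded/unassigned record(s)\n")
})

setMethod("show", "Interface", function(object) {
  cat(sprintf("Interface %s: %s (family %s) -> %s [%s], %s/%s%s\n",
              object@interfaceId, object@domainId, object@familyId,
              object@ligandEntityId, object@ligandType, object@complexClass,
              object@chainClass, if (object@covalent) "/covalent" else ""))
  s <- table(object@residues$solvation)
  cat(" ", nrow(object@residues), "interface residue(s) (",
      paste(sprintf("%s=%d", names(s), as.integer(s)), collapse = ", "),
      "),", nrow(object@contacts), "contact record(s)\n")
})

setMethod("show", "FamilyAlignment", function(object) {
  cat("FamilyAlignment", object@familyId, "-", length(object@members),
      "member(s),", object@nColumns, "columns\n")
})

setMethod("show", "BindingRegion", function(object) {
  cat(sprintf("BindingRegion %s (family %s, %s): %d alignment column(s)",
              object@regionId, object@familyId, object@origin,
              length(object@columnSet)))
  if (object@origin == "observed")
    cat(",", length(object@interfaceIds), "interface(s)")
  else cat(sprintf(", coverage %.2f from %s", object@coverage,
                   paste(object@sourceFamilyIds, collapse = ",")))
  cat("\n")
})

setMethod("show", "CorrespondenceMap", function(object) {
  cat(sprintf("CorrespondenceMap %s:%s <-> %s:%s, %d residue pair(s)\n",
              object@familyA, object@memberA, object@familyB, object@memberB,
              nrow(object@pairs)))
})

setMethod("show", "InteractionHierarchy", function(object) {
  nr <- sum(vapply(object@families, function(f) length(f$regions), 1L))
  cat("InteractionHierarchy:", length(object@families), "family(ies),",
      nr, "region(s), clustering cutoff", object@cutoff, "\n")
})
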