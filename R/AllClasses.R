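#' Parsed macromolecular structure
#'
#' Holds the atom table of one PDB-format file (first model only, alternate
#' locations resolved) together with the covalent-bond list taken from CONECT
#' records. Atoms are heavy atoms; hydrogens present in the input are dropped.
#'
#' @slot pdbId Structure identifier (HEADER id code or file stem).
#' @slot atoms data.frame with columns serial, name, altLoc, resName, chain,
#'   seqNum, insCode, x, y, z, occupancy, element, recordKind.
#' @slot bonds two-column integer matrix of bonded atom serials, one row per
#'   unordered pair (symmetric closure implied).
#' @exportClass PDBStructure
setClass("PDBStructure",
  representation(pdbId = "character", atoms = "data.frame", bonds = "matrix"))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "altLoc", "resName", "chain", "seqNum",
            "insCode", "x", "y", "z", "occupancy", "element", "recordKind")
  if (!all(need %in% names(a))) {
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (nrow(a) > 0L) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("atom coordinates must be finite")
    key <- paste(atomResidueKeys(a), a$name)
    if (anyDuplicated(key))
      return("duplicated (residue, atom name) after alt-loc resolution")
  }
  if (ncol(object@bonds) != 2L) return("bonds must have two columns")
  TRUE
})

#' Chemistry dictionary: per-atom physicochemical roles
#'
#' Editable lookup of donor/acceptor/charge/hydrophobicity flags per
#' (residue name, atom name), plus the water residue-name set, the
#' base-moiety atom-name sets per standard nucleotide, and the standard
#' amino-acid code set. All interaction criteria consult this dictionary;
#' unknown atoms simply carry no flags.
#'
#' @slot flags data.frame: resName, atomName and logical columns donor,
#'   acceptor, positive, negative, hydrophobic.
#' @slot waterNames residue names treated as water (default HOH, WAT, DOD).
#' @slot baseAtoms named list: nucleotide residue name -> base-moiety atom
#'   names (ring + exocyclic substituents; no sugar or phosphate).
#' @slot aminoAcids the 20 standard amino-acid three-letter codes.
#' @exportClass ChemistryDictionary
setClass("ChemistryDictionary",
  representation(flags = "data.frame", waterNames = "character",
                 baseAtoms = "list", aminoAcids = "character"))

setValidity("ChemistryDictionary", function(object) {
  f <- object@flags
  need <- c("resName", "atomName", "donor", "acceptor", "positive",
            "negative", "hydrophobic")
  if (!all(need %in% names(f)))
    return(paste("flags is missing columns:",
                 paste(setdiff(need, names(f)), collapse = ", ")))
  if (any(f$positive & f$negative))
    return("an atom cannot be both positive and negative")
  bbN <- f$atomName == "N" & f$resName %in% object@aminoAcids
  bbO <- f$atomName == "O" & f$resName %in% object@aminoAcids
  if (any(bbN & !f$donor) || any(bbO & !f$acceptor))
    return("every standard amino-acid backbone N must be donor and O acceptor")
  TRUE
})

#' Typed molecular entity
#'
#' One typed unit of a structure: a protein domain (SCOP-like family
#' assignment), a peptide, a merged DNA or RNA unit, an oligosaccharide, or a
#' single water molecule.
#'
#' @slot entityId Unique id within the structure.
#' @slot entityType one of domain, peptide, dna, rna, saccharide, water.
#' @slot residues ordered data.frame: chain, seqNum, insCode, resName.
#' @slot familyId protein family id (domains only, otherwise "").
#' @slot memberChains chain ids contributing residues.
#' @slot covalentToProtein saccharides: covalently attached to a protein
#'   entity (glycosylation)?
#' @exportClass Entity
setClass("Entity",
  representation(entityId = "character", entityType = "character",
                 residues = "data.frame", familyId = "character",
                 memberChains = "character", covalentToProtein = "logical"))

.entityTypes <- c("domain", "peptide", "dna", "rna", "saccharide", "water")

setValidity("Entity", function(object) {
  if (!object@entityType %in% .entityTypes)
    return(paste("unknown entity type:", object@entityType))
  if (nrow(object@residues) == 0L) return("entity has no residues")
  if (object@entityType == "domain" && !nzchar(object@familyId))
    return("domain entity requires a family id")
  TRUE
})

#' Entity decomposition of one structure
#'
#' The result of typing a parsed structure: the entity list plus a report of
#' residues recognized by no rule (other-het) or excluded by one
#' (unassigned-protein chains longer than the peptide limit).
#'
#' @slot pdbId structure id.
#' @slot entities list of [Entity-class] objects.
#' @slot report data.frame: category, chain, nResidues, detail.
#' @exportClass EntitySet
setClass("EntitySet",
  representation(pdbId = "character", entities = "list", report = "data.frame"))

setValidity("EntitySet", function(object) {
  if (!all(vapply(object@entities, is, TRUE, class2 = "Entity")))
    return("entities must all be Entity objects")
  # a residue belongs to exactly one non-water entity
  nw <- Filter(function(e) entityType(e) != "water", object@entities)
  keys <- unlist(lapply(nw, function(e)
    residueKey(e@residues$chain, e@residues$seqNum,
               e@residues$insCode, e@residues$resName)))
  if (anyDuplicated(keys))
    return("a residue is assigned to more than one non-water entity")
  TRUE
})

#' One domain-side interface with a ligand entity
#'
#' The set of a domain's residues in contact (directly or through a bridging
#' water) with one ligand entity, annotated per residue with solvation
#' (dry/wet/dual) and chemistry (hydrophobic/hydrophilic), plus the complex
#' (homo/hetero) and interaction (intra/inter) classes and the full contact
#' table.
#'
#' @slot interfaceId "IF_<n>" identifier.
#' @slot domainId,familyId the domain side.
#' @slot ligandEntityId,ligandType the ligand side (protein, peptide, dna,
#'   rna, saccharide).
#' @slot residues data.frame: chain, seqNum, insCode, resName, solvation,
#'   chemistry.
#' @slot complexClass "homo" (ligand is a domain of the same family) or
#'   "hetero".
#' @slot chainClass "intra" (shares a chain with the ligand) or "inter".
#' @slot covalent TRUE when domain and ligand are covalently bonded
#'   (glycosylation); such interfaces are excluded by default search filters.
#' @slot pdbId source structure.
#' @slot contacts classified contact table (see [detectDirectContacts()]).
#' @exportClass Interface
setClass("Interface",
  representation(interfaceId = "character", domainId = "character",
                 familyId = "character", ligandEntityId = "character",
                 ligandType = "character", residues = "data.frame",
                 complexClass = "character", chainClass = "character",
                 covalent = "logical", pdbId = "character",
                 contacts = "data.frame"))

setValidity("Interface", function(object) {
  if (nrow(object@residues) == 0L) return("interface has no residues")
  if (!all(object@residues$solvation %in% c("dry", "wet", "dual")))
    return("solvation must be dry, wet or dual")
  if (!all(object@residues$chemistry %in% c("hydrophobic", "hydrophilic")))
    return("chemistry must be hydrophobic or hydrophilic")
  if (!object@complexClass %in% c("homo", "hetero")) return("bad complexClass")
  if (!object@chainClass %in% c("intra", "inter")) return("bad chainClass")
  TRUE
})

#' Structure-based family alignment with residue-to-column maps
#'
#' A family's structure-based multiple sequence alignment. Each member
#' domain's observed residues are mapped to alignment columns by ungapped
#' position counting; columns are 0-based internally and 1-based in all
#' written reports.
#'
#' @slot familyId family id.
#' @slot members member domain ids.
#' @slot columnMap named list (per member): named integer vector, residue key
#'   string -> 0-based column.
#' @slot nColumns alignment width.
#' @exportClass FamilyAlignment
setClass("FamilyAlignment",
  representation(familyId = "character", members = "character",
                 columnMap = "list", nColumns = "integer"))

setValidity("FamilyAlignment", function(object) {
  if (!setequal(names(object@columnMap), object@members))
    return("columnMap names must equal members")
  for (m in object@members) {
    cm <- object@columnMap[[m]]
    if (anyDuplicated(cm)) return(paste("column map not injective for", m))
    if (length(cm) && max(cm) >= object@nColumns)
      return(paste("mapped column beyond alignment width for", m))
  }
  TRUE
})

#' Family binding region
#'
#' A cluster of a family's interfaces expressed as a set of alignment
#' columns — either observed (clustered from real interfaces by
#' interacting-residue overlap) or predicted (transferred from a structurally
#' similar family through a non-sequential alignment correspondence).
#'
#' @slot regionId "BR_<n>".
#' @slot familyId owning family.
#' @slot columnSet 0-based alignment columns.
#' @slot interfaceIds member interface ids (observed regions).
#' @slot origin "observed" or "predicted".
#' @slot cutoffUsed similarity cutoff used for clustering.
#' @slot coverage predicted regions: fraction of source-region residues with a
#'   structural counterpart (NA for observed).
#' @slot sourceRegionIds,sourceFamilyIds predicted regions: provenance.
#' @slot predictedInterfaces data.frame(sourceInterfaceId, ligandType)
#'   inherited from the source region (predicted regions).
#' @exportClass BindingRegion
setClass("BindingRegion",
  representation(regionId = "character", familyId = "character",
                 columnSet = "integer", interfaceIds = "character",
                 origin = "character", cutoffUsed = "numeric",
                 coverage = "numeric", sourceRegionIds = "character",
                 sourceFamilyIds = "character",
                 predictedInterfaces = "data.frame"))

setValidity("BindingRegion", function(object) {
  if (!object@origin %in% c("observed", "predicted")) return("bad origin")
  if (object@origin == "predicted") {
    if (!is.finite(object@coverage) || object@coverage <= 0 ||
        object@coverage > 1)
      return("predicted region coverage must be in (0, 1]")
  }
  TRUE
})

#' Residue correspondence between two families
#'
#' One-to-one residue pairs between a member of family A and a member of
#' family B, derived from a non-sequential structural alignment (computed
#' externally; this package consumes the pair list).
#'
#' @slot familyA,familyB family ids.
#' @slot memberA,memberB the aligned member domain ids.
#' @slot pairs data.frame(keyA, keyB) of residue key strings.
#' @slot sourceTag free-text aligner provenance.
#' @exportClass CorrespondenceMap
setClass("CorrespondenceMap",
  representation(familyA = "character", familyB = "character",
                 memberA = "character", memberB = "character",
                 pairs = "data.frame", sourceTag = "character"))

setValidity("CorrespondenceMap", function(object) {
  p <- object@pairs
  if (!all(c("keyA", "keyB") %in% names(p))) return("pairs needs keyA, keyB")
  if (anyDuplicated(p$keyA) || anyDuplicated(p$keyB))
    return("correspondence pairs must be one-to-one")
  TRUE
})

#' Family / binding-region / interface hierarchy
#'
#' The three interaction levels: each family (FA) lists its binding regions
#' (BR); each region lists interface groups (IF) keyed by ligand partner
#' family (protein ligands) or ligand type, with the member interfaces and
#' their homo/hetero, intra/inter and covalency annotations.
#'
#' @slot families named list (family id, sorted): list(familyId, regions);
#'   each region: list(regionId, origin, cutoff, columns (1-based), coverage,
#'   sourceRegionIds, sourceFamilyIds, ifGroups); each IF group:
#'   list(ifId, ligandKey, ligandType, members data.frame).
#' @slot cutoff clustering cutoff the hierarchy was built at.
#' @exportClass InteractionHierarchy
setClass("InteractionHierarchy",
  representation(families = "list", cutoff = "numeric"))
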