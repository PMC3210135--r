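# Pipeline entry points: scan structures into entities/contacts/interfaces,
# classify interfaces into family binding regions, infer predicted regions
# across families. Each wraps the module functions; the shell tool in
# inst/scripts/interface-tool.R is a thin veneer over these.

#' Run configuration
#'
#' Collects every numeric parameter of the pipeline in one validated object.
#'
#' @param cutoffs named distance cutoffs as [defaultCutoffs()] (Angstrom,
#'   all > 0).
#' @param peptideMaxLen maximum peptide length in residues (default 89:
#'   undomained all-ATOM chains shorter than 90 residues are peptides).
#' @param clusterCutoffs clustering similarity cutoffs; a hierarchy is built
#'   per value (default 0, 0.2, 0.4, 0.6; the zero cutoff is the primary
#'   classification).
#' @param inferenceThreshold conservation-coverage threshold in (0, 1] for
#'   cross-family transfer (default 0.5).
#' @param filter a [ligandTypeFilter()].
#' @param packingMode crystal-packing filter mode: "off", "hook" or "naive".
#' @param packingHook optional classifier hook (see
#'   [filterCrystalPacking()]).
#' @param packingCutoff biological-probability cutoff for the hook (0.70).
#' @param includeCovalent keep covalent (glycosylation) interfaces in
#'   filtered hierarchies?
#' @return validated config list.
#' @export
runConfig <- function(cutoffs = defaultCutoffs(), peptideMaxLen = 89L,
                      clusterCutoffs = c(0, 0.2, 0.4, 0.6),
                      inferenceThreshold = 0.5,
                      filter = ligandTypeFilter(),
                      packingMode = c("off", "hook", "naive"),
                      packingHook = NULL, packingCutoff = 0.70,
                      includeCovalent = FALSE) {
  packingMode <- match.arg(packingMode)
  if (any(cutoffs <= 0)) irStop("all distance cutoffs must be > 0")
  if (peptideMaxLen < 1L) irStop("peptideMaxLen must be >= 1")
  if (any(clusterCutoffs < 0 | clusterCutoffs > 1))
    irStop("clustering cutoffs must be in [0, 1]")
  if (inferenceThreshold <= 0 || inferenceThreshold > 1)
    irStop("inference threshold must be in (0, 1]")
  list(cutoffs = cutoffs, peptideMaxLen = as.integer(peptideMaxLen),
       clusterCutoffs = clusterCutoffs,
       inferenceThreshold = inferenceThreshold, filter = filter,
       packingMode = packingMode, packingHook = packingHook,
       packingCutoff = packingCutoff, includeCovalent = includeCovalent)
}

#' Scan structures: entities, contacts, interfaces
#'
#' Parses each structure, types its entities, builds every domain-ligand
#' interface and applies the crystal-packing filter. Unreadable files
#' produce a per-file error record and the run continues. With `outDir`,
#' per-structure entity tables, contact tables and interface summaries are
#' written.
#'
#' @param structureFiles paths to PDB files.
#' @param domainDefs path to a domain-definition TSV, or the data.frame from
#'   [loadDomainDefinitions()].
#' @param config a [runConfig()].
#' @param dict a [ChemistryDictionary-class].
#' @param sacCodes saccharide residue codes.
#' @param outDir optional output directory for tables.
#' @return list(entitySets, interfaces, errors, structures).
#' @export
runScan <- function(structureFiles, domainDefs = NULL, config = runConfig(),
                    dict = defaultChemistry(),
                    sacCodes = defaultSaccharideCodes(), outDir = NULL) {
  if (length(structureFiles) == 0L)
    irStop("no inputs: no structure files given")
  if (!is.null(domainDefs) && !is.data.frame(domainDefs))
    domainDefs <- loadDomainDefinitions(domainDefs)
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)
  structureFiles <- sort(structureFiles)
  entitySets <- list(); interfaces <- list(); structures <- list()
  errors <- data.frame(file = character(), error = character(),
                       stringsAsFactors = FALSE)
  nextId <- 1L
  for (f in structureFiles) {
    res <- tryCatch({
      s <- parseStructure(f)
      es <- typeEntities(s, domainDefs, dict, sacCodes,
                         peptideMaxLen = config$peptideMaxLen)
      ifs <- structureInterfaces(s, es, dict, config$cutoffs,
                                 idStart = nextId)
      list(s = s, es = es, ifs = ifs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      irWarn("failed to scan ", f, ": ", conditionMessage(res))
      errors <- rbind(errors, data.frame(file = f,
                                         error = conditionMessage(res),
                                         stringsAsFactors = FALSE))
      next
    }
    nextId <- nextId + length(res$ifs)
    structures[[pdbId(res$s)]] <- res$s
    entitySets[[pdbId(res$s)]] <- res$es
    interfaces <- c(interfaces, res$ifs)
    if (!is.null(outDir)) {
      writeEntityTable(res$es, file.path(outDir, paste0(pdbId(res$s),
                                                        "_entities.tsv")))
      ct <- do.call(rbind, c(list(.emptyContacts()),
                             lapply(res$ifs, contacts)))
      writeContactTable(ct, file.path(outDir, paste0(pdbId(res$s),
                                                     "_contacts.tsv")))
      jsonlite::write_json(lapply(res$ifs, interfaceSummary),
                           file.path(outDir, paste0(pdbId(res$s),
                                                    "_interfaces.json")),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
  }
  if (length(structures) == 0L)
    irStop("no inputs: no structure file could be read")
  interfaces <- filterCrystalPacking(interfaces,
                                     classifierHook = config$packingHook,
                                     mode = if (config$packingMode == "hook" &&
                                                is.null(config$packingHook))
                                       "off" else config$packingMode,
                                     cutoff = config$packingCutoff)
  list(entitySets = entitySets, interfaces = interfaces, errors = errors,
       structures = structures)
}

.scanDomainEntities <- function(scan) {
  doms <- list()
  for (es in scan$entitySets) for (e in entities(es))
    if (entityType(e) == "domain") doms[[entityId(e)]] <- e
  doms
}

#' Classify interfaces into family binding regions
#'
#' Loads the family alignments, maps every interface onto its family
#' alignment and clusters per family at each configured cutoff, assembling
#' one FA/BR/IF hierarchy per cutoff with globally sequential, deterministic
#' region ids.
#'
#' @param scan result of [runScan()].
#' @param alignmentFiles named character vector (family id -> gapped FASTA
#'   path), or a list of prebuilt [FamilyAlignment-class] objects.
#' @param config a [runConfig()].
#' @return named list (one element per clustering cutoff):
#'   list(cutoff, regions, interfaces, excluded, hierarchy, alignments).
#' @export
runClassify <- function(scan, alignmentFiles, config = runConfig()) {
  doms <- .scanDomainEntities(scan)
  interfaces <- scan$interfaces
  fams <- sort(unique(vapply(interfaces, familyId, "")))
  if (is.list(alignmentFiles) &&
      all(vapply(alignmentFiles, is, TRUE, class2 = "FamilyAlignment"))) {
    alns <- alignmentFiles
    names(alns) <- vapply(alns, familyId, "")
  } else {
    missing <- setdiff(fams, names(alignmentFiles))
    if (length(missing))
      irStop("no alignment supplied for family(ies): ",
             paste(missing, collapse = ", "))
    alns <- lapply(fams, function(f)
      familyAlignment(alignmentFiles[[f]], f,
                      Filter(function(d) familyId(d) == f, doms)))
    names(alns) <- fams
  }
  out <- list()
  for (cut in config$clusterCutoffs) {
    regions <- list(); excluded <- character(); nextBR <- 1L
    for (f in fams) {
      fIfs <- Filter(function(i) familyId(i) == f, interfaces)
      cl <- clusterRegions(fIfs, alns[[f]], cutoff = cut, idStart = nextBR)
      regions <- c(regions, cl$regions)
      excluded <- c(excluded, cl$excluded)
      nextBR <- nextBR + length(cl$regions)
    }
    h <- assembleHierarchy(regions, interfaces, cutoff = cut)
    out[[as.character(cut)]] <- list(cutoff = cut, regions = regions,
                                     interfaces = interfaces,
                                     excluded = excluded, hierarchy = h,
                                     alignments = alns)
  }
  out
}

#' Infer predicted binding regions across families
#'
#' Transfers each observed region through every applicable correspondence
#' map, deduplicates predictions per target family, separates predictions
#' that merely corroborate an observed region, and appends the novel ones to
#' the hierarchy with `origin = "predicted"`.
#'
#' @param classified one element of the [runClassify()] result (one cutoff).
#' @param corrMaps list of [CorrespondenceMap-class] (or paths to
#'   correspondence TSVs).
#' @param targetAlignments named list/vector of target family alignments
#'   ([FamilyAlignment-class] objects or FASTA paths) for families not
#'   already aligned in `classified`; domain entities for FASTA paths are
#'   taken from `scan`.
#' @param config a [runConfig()].
#' @param scan the [runScan()] result (needed to build alignments from FASTA
#'   paths).
#' @param onlyPredicted restrict the returned hierarchy to families having
#'   no observed regions (the "only predicted" search)?
#' @return list(hierarchy, predictions, corroborating,
#'   familiesOnlyPredicted).
#' @export
runInfer <- function(classified, corrMaps, targetAlignments = list(),
                     config = runConfig(), scan = NULL,
                     onlyPredicted = FALSE) {
  doms <- if (!is.null(scan)) .scanDomainEntities(scan) else list()
  alns <- classified$alignments
  if (length(targetAlignments)) {
    for (f in names(targetAlignments)) {
      ta <- targetAlignments[[f]]
      alns[[f]] <- if (is(ta, "FamilyAlignment")) ta
        else familyAlignment(ta, f,
                             Filter(function(d) familyId(d) == f, doms))
    }
  }
  corrMaps <- lapply(corrMaps, function(cm)
    if (is(cm, "CorrespondenceMap")) cm else readCorrespondenceMap(cm))
  predictions <- list(); nPred <- 1L
  for (cm in corrMaps) {
    if (!cm@familyB %in% names(alns)) {
      irWarn("correspondence targets unknown family ", cm@familyB,
             "; skipped")
      next
    }
    src <- Filter(function(r) familyId(r) == cm@familyA &&
                    regionOrigin(r) == "observed", classified$regions)
    if (length(src) == 0L) {
      irWarn("correspondence from family ", cm@familyA,
             " has no observed source regions; skipped")
      next
    }
    for (r in src) {
      p <- tryCatch(
        transferRegion(r, classified$interfaces, cm, alns[[cm@familyB]],
                       threshold = config$inferenceThreshold,
                       regionId = paste0("BR_pred_", nPred)),
        error = function(e) { irWarn(conditionMessage(e)); NULL })
      if (!is.null(p)) {
        predictions[[length(predictions) + 1L]] <- p
        nPred <- nPred + 1L
      }
    }
  }
  # per-target-family dedup, then corroboration split against observed
  novel <- list(); corro <- list()
  for (f in sort(unique(vapply(predictions, familyId, "")))) {
    fp <- Filter(function(p) familyId(p) == f, predictions)
    fp <- deduplicatePredictions(fp, cutoff = classified$cutoff)
    obs <- Filter(function(r) familyId(r) == f, classified$regions)
    sp <- splitCorroborating(fp, obs, cutoff = classified$cutoff)
    novel <- c(novel, sp$novel)
    corro[[length(corro) + 1L]] <- sp$corroborating
  }
  corro <- if (length(corro)) do.call(rbind, corro)
    else data.frame(predictionId = character(),
                    observedRegionId = character(), stringsAsFactors = FALSE)
  # renumber novel predictions after the observed regions
  nObs <- length(classified$regions)
  novel <- novel[order(vapply(novel, regionId, ""))]
  for (k in seq_along(novel))
    novel[[k]]@regionId <- paste0("BR_", nObs + k)
  h <- assembleHierarchy(c(classified$regions, novel),
                         classified$interfaces, cutoff = classified$cutoff)
  fams <- familiesWithOnlyPredictions(h)
  if (onlyPredicted)
    h <- new("InteractionHierarchy",
             families = hierarchyFamilies(h)[
               names(hierarchyFamilies(h)) %in% fams],
             cutoff = h@cutoff)
  list(hierarchy = h, predictions = novel, corroborating = corro,
       familiesOnlyPredicted = fams)
}
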