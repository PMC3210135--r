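# Cross-family binding-region inference: observed regions are transferred
# through residue correspondences derived from non-sequential structural
# alignments (computed externally). Conservation is operationalized as
# coverage — the fraction of source interface residues with a structural
# counterpart — against a named threshold (default 0.5).

#' Read an inter-family residue correspondence map
#'
#' TSV with columns family_a, member_a, chain_a, seq_a, icode_a, res_a,
#' family_b, member_b, chain_b, seq_b, icode_b, res_b and optionally
#' source_tag. Pairs must be one-to-one. Insertion codes may be given as
#' "." or left empty.
#'
#' @param input TSV path or table text.
#' @return A [CorrespondenceMap-class].
#' @export
readCorrespondenceMap <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input)) {
    df <- utils::read.delim(input, stringsAsFactors = FALSE,
                            colClasses = "character")
  } else {
    df <- utils::read.delim(textConnection(paste(input, collapse = "\n")),
                            stringsAsFactors = FALSE,
                            colClasses = "character")
  }
  need <- c("family_a", "member_a", "chain_a", "seq_a", "icode_a", "res_a",
            "family_b", "member_b", "chain_b", "seq_b", "icode_b", "res_b")
  missing <- setdiff(need, names(df))
  if (length(missing))
    irStop("correspondence table is missing columns: ",
           paste(missing, collapse = ", "))
  fixIcode <- function(x) ifelse(is.na(x) | x == ".", "", x)
  keyA <- residueKey(df$chain_a, as.integer(df$seq_a), fixIcode(df$icode_a),
                     df$res_a)
  keyB <- residueKey(df$chain_b, as.integer(df$seq_b), fixIcode(df$icode_b),
                     df$res_b)
  new("CorrespondenceMap",
      familyA = unique(df$family_a), familyB = unique(df$family_b),
      memberA = unique(df$member_a), memberB = unique(df$member_b),
      pairs = data.frame(keyA = keyA, keyB = keyB, stringsAsFactors = FALSE),
      sourceTag = if ("source_tag" %in% names(df))
        paste(unique(df$source_tag), collapse = ";") else "")
}

#' Transfer an observed binding region to another family
#'
#' Maps the source region's interface residues (those of the correspondence
#' map's source member) through the residue pairs. Coverage is the mapped
#' fraction; when it reaches `threshold` a predicted [BindingRegion-class]
#' is emitted on the target family's alignment columns, inheriting the
#' source region's ligands as predicted interfaces (the target family could
#' recognize the same ligands through this region in a similar binding
#' mode). Below threshold nothing is emitted.
#'
#' @param sourceRegion an observed [BindingRegion-class].
#' @param sourceInterfaces the interfaces backing the source region.
#' @param corr a [CorrespondenceMap-class] with
#'   `familyA == familyId(sourceRegion)`.
#' @param targetAlignment the target family's [FamilyAlignment-class]
#'   (must contain the correspondence's target member).
#' @param threshold coverage threshold in (0, 1], default 0.5.
#' @param regionId id for the emitted region.
#' @return A predicted [BindingRegion-class], or NULL below threshold.
#' @export
transferRegion <- function(sourceRegion, sourceInterfaces, corr,
                           targetAlignment, threshold = 0.5,
                           regionId = "BR_pred_1") {
  stopifnot(is(corr, "CorrespondenceMap"))
  if (threshold <= 0 || threshold > 1)
    irStop("inference threshold must be in (0, 1]")
  if (familyId(sourceRegion) != corr@familyA)
    irStop("source region family ", familyId(sourceRegion),
           " does not match correspondence family ", corr@familyA)
  if (!corr@memberB %in% alignmentMembers(targetAlignment))
    irStop("correspondence target member ", corr@memberB,
           " is not in the alignment of family ",
           familyId(targetAlignment))
  srcIfaces <- Filter(function(i)
    interfaceId(i) %in% interfaceIds(sourceRegion) &&
      domainId(i) == corr@memberA, sourceInterfaces)
  srcKeys <- unique(unlist(lapply(srcIfaces, function(i) {
    r <- residues(i)
    residueKey(r$chain, r$seqNum, r$insCode, r$resName)
  })))
  if (length(srcKeys) == 0L)
    irStop("source region ", regionId(sourceRegion),
           " has no residues on correspondence member ", corr@memberA)
  mapped <- corr@pairs$keyB[match(srcKeys, corr@pairs$keyA)]
  cov <- sum(!is.na(mapped)) / length(srcKeys)
  if (cov < threshold) return(NULL)
  cmB <- targetAlignment@columnMap[[corr@memberB]]
  cols <- cmB[mapped[!is.na(mapped)]]
  cols <- sort(unique(as.integer(cols[!is.na(cols)])))
  ligTypes <- vapply(srcIfaces, ligandType, "")
  new("BindingRegion", regionId = regionId,
      familyId = familyId(targetAlignment),
      columnSet = cols,
      interfaceIds = character(), origin = "predicted",
      cutoffUsed = NA_real_, coverage = cov,
      sourceRegionIds = regionId(sourceRegion),
      sourceFamilyIds = familyId(sourceRegion),
      predictedInterfaces = data.frame(
        sourceInterfaceId = vapply(srcIfaces, interfaceId, ""),
        ligandType = ligTypes, stringsAsFactors = FALSE))
}

#' Merge redundant predictions on one target family
#'
#' Several source families may imply the same target region. Predictions
#' whose target column sets overlap with similarity greater than `cutoff`
#' (same measure as observed-region clustering) merge into one record whose
#' column set is the union, retaining all source provenance and the best
#' coverage.
#'
#' @param predictions list of predicted [BindingRegion-class] on one family.
#' @param cutoff similarity cutoff (default 0).
#' @return deduplicated list of predicted regions.
#' @export
deduplicatePredictions <- function(predictions, cutoff = 0) {
  if (length(predictions) <= 1L) return(predictions)
  fams <- unique(vapply(predictions, familyId, ""))
  if (length(fams) > 1L)
    irStop("predictions span multiple target families: ",
           paste(fams, collapse = ", "))
  ids <- vapply(predictions, regionId, "")
  ord <- order(ids)
  predictions <- predictions[ord]; ids <- ids[ord]
  n <- length(predictions)
  ea <- character(); eb <- character()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (regionSimilarity(columnSet(predictions[[i]]),
                         columnSet(predictions[[j]])) > cutoff) {
      ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
    }
  }
  comp <- edgeListComponents(ids, ea, eb)
  out <- list()
  for (k in sort(unique(comp))) {
    sel <- which(comp == k)
    base <- predictions[[sel[1L]]]
    if (length(sel) > 1L) {
      base@columnSet <- sort(unique(unlist(lapply(predictions[sel],
                                                  columnSet))))
      base@coverage <- max(vapply(predictions[sel], coverage, 1))
      base@sourceRegionIds <- unique(unlist(lapply(predictions[sel],
                                                   function(p)
                                                     p@sourceRegionIds)))
      base@sourceFamilyIds <- unique(unlist(lapply(predictions[sel],
                                                   function(p)
                                                     p@sourceFamilyIds)))
      base@predictedInterfaces <- unique(do.call(rbind,
        lapply(predictions[sel], function(p) p@predictedInterfaces)))
    }
    out[[length(out) + 1L]] <- base
  }
  out
}

#' Split predictions into novel and corroborating
#'
#' A prediction overlapping (similarity greater than `cutoff`) any observed
#' region of its target family corroborates that region rather than adding a
#' new one; only novel predictions should enter the hierarchy as regions.
#'
#' @param predictions list of predicted [BindingRegion-class].
#' @param observedRegions list of observed regions of the same family.
#' @param cutoff similarity cutoff (default 0).
#' @return list(novel = predictions, corroborating = data.frame(
#'   predictionId, observedRegionId)).
#' @export
splitCorroborating <- function(predictions, observedRegions, cutoff = 0) {
  novel <- list()
  cor_rows <- list()
  for (p in predictions) {
    hit <- NULL
    for (o in observedRegions) {
      if (familyId(o) != familyId(p)) next
      if (regionSimilarity(columnSet(p), columnSet(o)) > cutoff) {
        hit <- regionId(o); break
      }
    }
    if (is.null(hit)) novel[[length(novel) + 1L]] <- p
    else cor_rows[[length(cor_rows) + 1L]] <-
      data.frame(predictionId = regionId(p), observedRegionId = hit,
                 stringsAsFactors = FALSE)
  }
  list(novel = novel,
       corroborating = if (length(cor_rows)) do.call(rbind, cor_rows)
       else data.frame(predictionId = character(),
                       observedRegionId = character(),
                       stringsAsFactors = FALSE))
}

#' Families having only predicted binding regions
#'
#' Returns families that present at least one predicted region and no
#' observed one — i.e. families with no binding information among the input
#' structures, for which the inferred regions are the only binding
#' hypotheses.
#'
#' @param hierarchy an [InteractionHierarchy-class] containing observed and
#'   predicted regions.
#' @return character vector of family ids.
#' @export
familiesWithOnlyPredictions <- function(hierarchy) {
  out <- character()
  for (f in hierarchyFamilies(hierarchy)) {
    origins <- vapply(f$regions, function(r) r$origin, "")
    if (length(origins) && all(origins == "predicted") &&
        any(origins == "predicted"))
      out <- c(out, f$familyId)
  }
  sort(out)
}
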