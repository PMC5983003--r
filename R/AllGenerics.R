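#' @describeIn CoarseStructure-class number of residue sites
#' @param x,object a `CoarseStructure`
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn CoarseStructure-class one-letter residue types, in flat order
#' @export
setGeneric("residueTypes", function(x) standardGeneric("residueTypes"))

#' @describeIn CoarseStructure-class n x 3 C-alpha coordinate matrix (Angstrom)
#' @export
setGeneric("siteCoords", function(x) standardGeneric("siteCoords"))

#' @describeIn CoarseStructure-class "chain:resnum" site labels, flat order
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @describeIn Tessellation-class retained tetrahedra (flat indices, n x 4)
#' @param x a `Tessellation`
#' @export
setGeneric("tetrahedra", function(x) standardGeneric("tetrahedra"))

#' @describeIn Tessellation-class retained-edge matrix (m x 2)
#' @export
setGeneric("tessEdges", function(x) standardGeneric("tessEdges"))

#' @describeIn Tessellation-class edge filter cutoff (Angstrom)
#' @export
setGeneric("edgeCutoff", function(x) standardGeneric("edgeCutoff"))

#' @describeIn FourBodyPotential-class named score vector over all keys
#'   (NA marks unscored quadruplets)
#' @param x a `FourBodyPotential`
#' @export
setGeneric("potentialScores", function(x) standardGeneric("potentialScores"))

setMethod("nSites", "CoarseStructure", function(x) nrow(x@sites))
setMethod("residueTypes", "CoarseStructure", function(x) x@sites$resType)
setMethod("siteCoords", "CoarseStructure", function(x) x@coords)
setMethod("siteLabels", "CoarseStructure",
          function(x) paste0(x@sites$chain, ":", x@sites$resnum))

setMethod("tetrahedra", "Tessellation", function(x) x@tetrahedra)
setMethod("tessEdges", "Tessellation", function(x) x@edges)
setMethod("edgeCutoff", "Tessellation", function(x) x@edgeCutoff)

setMethod("potentialScores", "FourBodyPotential",
          function(x) setNames(x@s, x@keys))

setMethod("show", "CoarseStructure", function(object) {
  cat(sprintf("CoarseStructure '%s': %d sites, chain(s) %s\n",
              object@sourceId, nSites(object),
              paste(object@chainOrder, collapse = ",")))
  for (ch in object@chainOrder) {
    rn <- object@sites$resnum[object@sites$chain == ch]
    cat(sprintf("  chain %s: %d residues (%d..%d)\n", ch, length(rn),
                min(rn), max(rn)))
  }
})

setMethod("show", "Tessellation", function(object) {
  cat(sprintf(paste0("Tessellation of '%s': %d tetrahedra, %d retained edges",
                     " (cutoff %.1f A)%s\n"),
              object@structure@sourceId, nrow(object@tetrahedra),
              nrow(object@edges), object@edgeCutoff,
              if (object@joggled) ", joggled" else ""))
})

setMethod("show", "FourBodyPotential", function(object) {
  scored <- sum(!is.na(object@s))
  cat(sprintf("FourBodyPotential: %d-letter alphabet, %d keys (%d scored)\n",
              length(object@alphabet), length(object@keys), scored))
  if (length(object@counts))
    cat(sprintf("  derived from %d tetrahedra; log base %.4g, pseudocount %g\n",
                as.integer(sum(object@counts)), object@logBase,
                object@pseudocount))
})

setMethod("show", "PotentialProfile", function(object) {
  cat(sprintf("PotentialProfile: %d positions, total potential %.4f\n",
              length(object@res), object@totalPotential))
})

setMethod("show", "ResidualProfile", function(object) {
  cat(sprintf("ResidualProfile %s: residual score %.4f, %d nonzero EP\n",
              object@variant, object@residualScore,
              sum(object@ep != 0)))
})

setMethod("show", "CmpProfile", function(object) {
  cat(sprintf("CmpProfile: %d positions, mean CMP %.4f\n",
              length(object@cmp), mean(object@cmp)))
})

setMethod("show", "VariantDataset", function(object) {
  cat(sprintf("VariantDataset [%s, %s]: %d rows x %d input attributes (%d excluded)\n",
              object@encoding, object@task, nrow(object@features),
              sum(!startsWith(names(object@features), ".")) - 1L,
              nrow(object@excluded)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult (%s, %s):\n", object@scheme, object@task))
  print(round(object@metrics, 3))
})
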