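#' CoarseStructure: a C-alpha coarse-grained protein chain set
#'
#' Ordered set of residue sites, one per residue with a C-alpha atom. Sites
#' are indexed by a continuous 1-based flat index running across the selected
#' chains in order; the original (chain, author residue number) labels are
#' retained for reporting.
#'
#' @slot sites data.frame with columns `chain` (character), `resnum`
#'   (integer, author numbering), `resType` (one-letter amino-acid code).
#' @slot coords numeric matrix, one row per site, columns x/y/z in Angstrom.
#' @slot sourceId character label for provenance.
#' @slot chainOrder character vector giving the chain concatenation order.
#' @export
setClass("CoarseStructure",
  representation(sites = "data.frame", coords = "matrix",
                 sourceId = "character", chainOrder = "character"))

setValidity("CoarseStructure", function(object) {
  s <- object@sites
  msg <- character()
  if (!all(c("chain", "resnum", "resType") %in% names(s)))
    msg <- c(msg, "sites must have columns chain, resnum, resType")
  else {
    if (nrow(s) != nrow(object@coords) || ncol(object@coords) != 3)
      msg <- c(msg, "coords must be an n x 3 matrix matching sites")
    if (!all(s$resType %in% AMINO_ACIDS))
      msg <- c(msg, "resType must use the 20-letter amino-acid alphabet")
    if (nrow(object@coords) && !all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (!identical(unique(s$chain), object@chainOrder))
      msg <- c(msg, "chains must appear as contiguous blocks in chainOrder order")
    for (ch in unique(s$chain)) {
      rn <- s$resnum[s$chain == ch]
      if (any(diff(rn) <= 0)) {
        msg <- c(msg, sprintf("author residue numbers not strictly increasing in chain %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Tessellation: filtered Delaunay tessellation of a CoarseStructure
#'
#' Delaunay tetrahedra of the C-alpha point set after discarding every
#' tetrahedron containing an edge longer than `edgeCutoff` (default 12
#' Angstrom), together with the retained-edge graph, per-tetrahedron
#' geometry, and the incidence map from positions to tetrahedra.
#'
#' @slot structure the tessellated [CoarseStructure-class].
#' @slot tetrahedra integer matrix (n x 4) of flat position indices, each row
#'   sorted ascending.
#' @slot geometry data.frame with per-tetrahedron `volume` (A^3),
#'   `tetrahedrality` (dimensionless) and `maxEdge` (A).
#' @slot edges integer matrix (m x 2) of retained unordered edges, i < j.
#' @slot edgeCutoff numeric, Angstrom.
#' @slot incident list mapping each flat index to the row indices of
#'   `tetrahedra` containing it.
#' @slot joggled logical; TRUE when a deterministic joggle was applied to
#'   resolve cospherical degeneracies.
#' @export
setClass("Tessellation",
  representation(structure = "CoarseStructure", tetrahedra = "matrix",
                 geometry = "data.frame", edges = "matrix",
                 edgeCutoff = "numeric", incident = "list",
                 joggled = "logical"))

setValidity("Tessellation", function(object) {
  msg <- character()
  nt <- nrow(object@tetrahedra)
  n <- nSites(object@structure)
  if (nt && ncol(object@tetrahedra) != 4)
    msg <- c(msg, "tetrahedra must have 4 columns")
  if (nt && (min(object@tetrahedra) < 1 || max(object@tetrahedra) > n))
    msg <- c(msg, "tetrahedron vertex index out of range")
  if (nt && any(apply(object@tetrahedra, 1, function(r) any(diff(r) <= 0))))
    msg <- c(msg, "tetrahedron rows must be sorted with distinct vertices")
  if (nt && nrow(object@geometry) != nt)
    msg <- c(msg, "geometry must have one row per tetrahedron")
  if (nt && any(object@geometry$maxEdge > object@edgeCutoff + 1e-9))
    msg <- c(msg, "retained tetrahedron exceeds the edge cutoff")
  if (length(object@incident) != n)
    msg <- c(msg, "incident map must cover every position")
  if (nt && sum(lengths(object@incident)) != 4L * nt)
    msg <- c(msg, "incident-map degrees must sum to 4 x number of tetrahedra")
  if (length(msg)) msg else TRUE
})

#' FourBodyPotential: the quadruplet score table
#'
#' Scores s = -log(f/p) over unordered residue quadruplets, where f is the
#' observed relative frequency of the quadruplet at tetrahedron vertices
#' across a training set of tessellations and p its multinomial chance rate
#' given the pooled residue composition. For the 20-letter alphabet the key
#' set has exactly 8855 entries. Quadruplets never observed (at pseudocount
#' 0) are explicitly unscored (NA), never silently zero.
#'
#' @slot alphabet residue letters.
#' @slot keys character vector of sorted 4-letter keys, lexicographic order.
#' @slot counts,f,p,s numeric vectors parallel to `keys` (may be empty for
#'   tables loaded from text, which carry scores only).
#' @slot composition named per-letter proportions a_n (sums to 1).
#' @slot logBase base of the logarithm in s.
#' @slot pseudocount added to every count before forming f.
#' @export
setClass("FourBodyPotential",
  representation(alphabet = "character", keys = "character",
                 counts = "numeric", f = "numeric", p = "numeric",
                 s = "numeric", composition = "numeric",
                 logBase = "numeric", pseudocount = "numeric"))

setValidity("FourBodyPotential", function(object) {
  msg <- character()
  nk <- length(object@keys)
  a <- length(object@alphabet)
  if (a && nk != choose(a + 3, 4))
    msg <- c(msg, "key set must enumerate all multisets of size 4")
  if (length(object@s) && length(object@s) != nk)
    msg <- c(msg, "scores must be parallel to keys")
  if (length(object@p) == nk && abs(sum(object@p) - 1) > 1e-9)
    msg <- c(msg, "multinomial rates must sum to 1")
  if (length(object@composition) &&
      abs(sum(object@composition) - 1) > 1e-9)
    msg <- c(msg, "composition must sum to 1")
  if (length(msg)) msg else TRUE
})

#' PotentialProfile: per-position residue environment scores
#'
#' The 3D-1D potential profile: for each position, the sum of the scores of
#' all retained tetrahedra sharing its C-alpha vertex (RES), together with
#' the total potential of the structure. Since each tetrahedron contributes
#' its score at each of its four vertices, sum(RES) = 4 x total potential.
#'
#' @slot res named numeric vector of RES scores (names are chain:resnum labels).
#' @slot totalPotential numeric scalar.
#' @export
setClass("PotentialProfile",
  representation(res = "numeric", totalPotential = "numeric"))

#' ResidualProfile: environmental perturbation profile of one variant
#'
#' Per-position EP scores (mutant RES minus native RES) and the scalar
#' residual score (mutant total potential minus native total potential).
#' EP is nonzero only at mutated sites and their tessellation neighbors,
#' and sum(EP) = 4 x residual score.
#'
#' @slot ep named numeric vector of EP scores.
#' @slot residualScore numeric scalar.
#' @slot variant character, e.g. "C14E".
#' @slot mutatedSites integer flat indices relabelled by the variant.
#' @export
setClass("ResidualProfile",
  representation(ep = "numeric", residualScore = "numeric",
                 variant = "character", mutatedSites = "integer"))

#' CmpProfile: comprehensive mutational profile
#'
#' Per-position CMP score: the mean of the residual scores of all 19
#' possible substitutions at that position, with conservative (C) and
#' non-conservative (NC) submeans and the full position x replacement
#' residual matrix retained for group summaries.
#'
#' @slot cmp,cCmp,ncCmp named numeric vectors per position.
#' @slot residuals numeric matrix, positions x 19 replacements.
#' @slot classes character matrix ("C"/"NC") parallel to `residuals`.
#' @export
setClass("CmpProfile",
  representation(cmp = "numeric", cCmp = "numeric", ncCmp = "numeric",
                 residuals = "matrix", classes = "matrix"))

#' VariantDataset: labelled feature vectors for model training
#'
#' Feature rows under one of the encodings (27-attribute monomer or dimer,
#' or per-chain EP-vector profiles with optional variant-ID attributes),
#' plus the activity output and a manifest of excluded variants.
#'
#' @slot features data.frame; metadata columns are prefixed with ".",
#'   the final column `output` is a factor (classification) or numeric
#'   (regression).
#' @slot encoding one of "monomer-27", "dimer-27", "profile-EP",
#'   "profile-EP+ID".
#' @slot task "classification" or "regression".
#' @slot excluded data.frame manifest of dropped variants and reasons.
#' @export
setClass("VariantDataset",
  representation(features = "data.frame", encoding = "character",
                 task = "character", excluded = "data.frame"))

#' EvaluationResult: cross-validated model performance
#'
#' Row-level out-of-fold predictions plus the derived confusion counts and
#' performance metrics (Se, Sp, PPV, BAR, MCC, AUC, and r for regression).
#'
#' @slot predictions data.frame with truth and out-of-fold predictions.
#' @slot metrics named numeric vector.
#' @slot confusion named numeric (TP, FP, TN, FN).
#' @slot scheme character descriptor (e.g. "10-fold", "loocv").
#' @slot task "classification" or "regression".
#' @slot seed integer seed used for fold assignment.
#' @export
setClass("EvaluationResult",
  representation(predictions = "data.frame", metrics = "numeric",
                 confusion = "numeric", scheme = "character",
                 task = "character", seed = "integer"))
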