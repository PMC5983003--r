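#' Parse a variant string
#'
#' Syntax: native letter + author residue number + replacement letter,
#' e.g. "C14E".
#'
#' @param variant character like "C14E", or a list with elements `native`,
#'   `position`, `replacement` (returned unchanged).
#' @return List with `native`, `position` (integer author residue number)
#'   and `replacement`.
#' @export
parseVariant <- function(variant) {
  if (is.list(variant)) {
    stopifnot(all(c("native", "position", "replacement") %in% names(variant)))
    variant$position <- as.integer(variant$position)
    return(variant)
  }
  m <- regmatches(variant, regexec("^([A-Y])([0-9]+)([A-Y])$", variant))[[1]]
  if (length(m) != 4 || !(m[2] %in% AMINO_ACIDS) || !(m[4] %in% AMINO_ACIDS))
    stop("malformed variant string: ", variant)
  list(native = m[2], position = as.integer(m[3]), replacement = m[4])
}

# flat indices targeted by a variant: every chain copy of the residue label,
# or a single chain's copy when `chain` is given
variantSites <- function(structure, v, chain = NULL) {
  s <- structure@sites
  hit <- s$resnum == v$position
  if (!is.null(chain)) hit <- hit & s$chain %in% chain
  sites <- which(hit)
  if (!length(sites))
    stop(sprintf("unknown position %d%s", v$position,
                 if (is.null(chain)) "" else paste0(" in chain ", chain)))
  mism <- s$resType[sites] != v$native
  if (any(mism))
    stop(sprintf("native mismatch at %s: structure has %s, variant says %s",
                 paste(siteLabels(structure)[sites[mism]], collapse = ","),
                 paste(s$resType[sites[mism]], collapse = ","), v$native))
  sites
}

# residue-letter matrix of the retained tetrahedra (one row per tetrahedron)
tetraLetters <- function(tess) {
  matrix(residueTypes(tess@structure)[tess@tetrahedra], ncol = 4)
}

keysFromLetters <- function(m) {
  if (!nrow(m)) return(character())
  vapply(seq_len(nrow(m)),
         function(i) paste(sort(m[i, ]), collapse = ""), "")
}

scoresOrStop <- function(potential, keys, context) {
  s <- lookupScores(potential, keys)
  if (anyNA(s))
    stop(sprintf("unscored quadruplet(s) %s encountered while %s",
                 paste(unique(keys[is.na(s)]), collapse = ", "), context))
  s
}

#' Total four-body potential of a structure tessellation
#'
#' Sum of the quadruplet scores of all retained tetrahedra.
#'
#' @param tess a [Tessellation-class].
#' @param potential a [FourBodyPotential-class]; every retained quadruplet
#'   must be scored.
#' @return Numeric scalar.
#' @export
totalPotential <- function(tess, potential) {
  if (!nrow(tess@tetrahedra))
    stop("tessellation has zero retained tetrahedra")
  sum(scoresOrStop(potential, tessellationKeys(tess),
                   "computing the total potential"))
}

#' Residue environment scores (3D-1D potential profile)
#'
#' RES at each position is the sum of the scores of all retained tetrahedra
#' sharing its C-alpha vertex; positions in no tetrahedron score 0. Since
#' each tetrahedron contributes at four vertices, sum(RES) equals 4 x the
#' total potential.
#'
#' @inheritParams totalPotential
#' @return A [PotentialProfile-class].
#' @export
residueEnvironmentProfile <- function(tess, potential) {
  if (!nrow(tess@tetrahedra))
    stop("tessellation has zero retained tetrahedra")
  s <- scoresOrStop(potential, tessellationKeys(tess),
                    "computing the potential profile")
  n <- nSites(tess@structure)
  res <- numeric(n)
  acc <- rowsum(rep(s, 4), as.vector(tess@tetrahedra))
  res[as.integer(rownames(acc))] <- acc
  new("PotentialProfile", res = setNames(res, siteLabels(tess@structure)),
      totalPotential = sum(s))
}

# delta scores of the tetrahedra incident to `sites` after relabelling those
# sites with `replacement`; the workhorse behind residual and CMP profiles
rescoreDelta <- function(tess, potential, sites, replacement,
                         nativeScores, context) {
  affected <- sort(unique(unlist(tess@incident[sites])))
  if (!length(affected))
    return(list(affected = integer(), delta = numeric()))
  tets <- tess@tetrahedra[affected, , drop = FALSE]
  mut <- residueTypes(tess@structure)
  mut[sites] <- replacement
  newKeys <- keysFromLetters(matrix(mut[tets], ncol = 4))
  sNew <- scoresOrStop(potential, newKeys, context)
  list(affected = affected, delta = sNew - nativeScores[affected])
}

#' Residual profile of a single-residue variant
#'
#' The variant relabels the residue at the target author position -- at
#' every chain copy of that label by default (the multimer convention), or
#' at one chain's copy when `chain` is given. Coordinates never move; only
#' the tetrahedra incident to the mutated site(s) are rescored. The EP
#' vector is the per-position difference mutant RES - native RES and the
#' residual score is the difference in total potentials; sum(EP) = 4 x
#' residual score, and in a single-chain tessellation EP at the mutated
#' position equals the residual score exactly.
#'
#' @inheritParams totalPotential
#' @param variant variant string or list (see [parseVariant()]). Identity
#'   replacements are tolerated (zero profile) for verification purposes.
#' @param chain optional chain restriction for single-site mutation.
#' @return A [ResidualProfile-class].
#' @export
residualProfile <- function(tess, potential, variant, chain = NULL) {
  v <- parseVariant(variant)
  sites <- variantSites(tess@structure, v, chain)
  nat <- scoresOrStop(potential, tessellationKeys(tess),
                      "scoring the native structure")
  rd <- rescoreDelta(tess, potential, sites, v$replacement, nat,
                     sprintf("scoring variant %s%d%s", v$native, v$position,
                             v$replacement))
  n <- nSites(tess@structure)
  ep <- numeric(n)
  if (length(rd$affected)) {
    tets <- tess@tetrahedra[rd$affected, , drop = FALSE]
    acc <- rowsum(rep(rd$delta, 4), as.vector(tets))
    ep[as.integer(rownames(acc))] <- acc
  }
  new("ResidualProfile", ep = setNames(ep, siteLabels(tess@structure)),
      residualScore = sum(rd$delta),
      variant = paste0(v$native, v$position, v$replacement),
      mutatedSites = as.integer(sites))
}

#' Conservative versus non-conservative substitution class
#'
#' Residues are clustered by physicochemical similarity as (A,S,T,G,P),
#' (D,E,N,Q), (R,K,H), (F,Y,W), (V,L,I,M) and (C); a substitution within a
#' cluster is conservative ("C"), across clusters non-conservative ("NC").
#' Cysteine is a singleton cluster, so every substitution involving C is NC.
#'
#' @param native,replacement one-letter residue codes (vectorised).
#' @return Character vector of "C"/"NC".
#' @export
substitutionClass <- function(native, replacement) {
  if (any(native == replacement))
    stop("identical native and replacement residue: not a variant")
  clusterOf <- function(x) {
    vapply(x, function(r) {
      hit <- which(vapply(RESIDUE_CLUSTERS, function(cl) r %in% cl, TRUE))
      if (!length(hit)) stop("unknown residue letter: ", r)
      hit[1]
    }, 1L)
  }
  unname(ifelse(clusterOf(native) == clusterOf(replacement), "C", "NC"))
}

#' Comprehensive mutational profile
#'
#' CMP at each flat position is the mean of the residual scores of all 19
#' substitutions at that position (mutating that site alone), with
#' conservative and non-conservative submeans. The full position x
#' replacement residual matrix is retained for group summaries.
#'
#' @inheritParams totalPotential
#' @param positions flat indices to profile (default: all).
#' @return A [CmpProfile-class].
#' @export
cmpProfile <- function(tess, potential, positions = NULL) {
  st <- tess@structure
  n <- nSites(st)
  if (is.null(positions)) positions <- seq_len(n)
  nat <- scoresOrStop(potential, tessellationKeys(tess),
                      "scoring the native structure")
  native <- residueTypes(st)
  residuals <- matrix(NA_real_, length(positions), 20,
                      dimnames = list(siteLabels(st)[positions], AMINO_ACIDS))
  for (i in seq_along(positions)) {
    pos <- positions[i]
    for (repl in setdiff(AMINO_ACIDS, native[pos])) {
      rd <- rescoreDelta(tess, potential, pos, repl, nat,
                         sprintf("computing CMP at position %s",
                                 siteLabels(st)[pos]))
      residuals[i, repl] <- sum(rd$delta)
    }
  }
  classes <- matrix(NA_character_, length(positions), 20,
                    dimnames = dimnames(residuals))
  for (i in seq_along(positions)) {
    others <- setdiff(AMINO_ACIDS, native[positions[i]])
    classes[i, others] <- substitutionClass(rep(native[positions[i]],
                                                length(others)), others)
  }
  repMeans <- function(keep) {
    vals <- residuals
    vals[!keep | is.na(classes)] <- NA
    rowMeans(vals, na.rm = TRUE)
  }
  labels <- siteLabels(st)[positions]
  new("CmpProfile",
      cmp = setNames(rowMeans(residuals, na.rm = TRUE), labels),
      cCmp = setNames(repMeans(classes == "C"), labels),
      ncCmp = setNames(repMeans(classes == "NC"), labels),
      residuals = residuals, classes = classes)
}
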