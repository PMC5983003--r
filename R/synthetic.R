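#' Generate a protein-like synthetic C-alpha trace
#'
#' Self-avoiding random walk with a fixed ~3.8 Angstrom step, biased toward
#' a sphere whose radius scales as n^(1/3) at typical protein C-alpha
#' density, so that tessellations of the result have protein-like local
#' topology. Homodimer mode adds a second chain with an identical sequence
#' across a configurable interface gap: by default an independently
#' sampled conformation (real crystal chains are never exactly congruent,
#' so the per-chain structural environments differ), or an exact two-fold
#' (C2) rotated copy with `symmetric = TRUE`. Coordinates are rounded to
#' 0.001 Angstrom (PDB fixed-width precision). These fixtures are
#' geometric stand-ins, not folded proteins: they exercise tessellation
#' topology, scoring algebra and model plumbing.
#'
#' All randomness flows from `seed` through an isolated RNG stream;
#' identical arguments always give identical structures.
#'
#' @param nResidues residues per chain (>= 10).
#' @param chains 1 (monomer) or 2 (homodimer).
#' @param step consecutive C-alpha spacing in Angstrom.
#' @param compactness 0..1 strength of the pull toward the target sphere.
#' @param composition optional named residue-sampling weights; by default
#'   near-uniform with every letter represented at least once (for
#'   nResidues >= 20).
#' @param interfaceGap closest-approach distance between the two chains
#'   (Angstrom), homodimer mode.
#' @param symmetric homodimer mode: exact C2-rotated copy (TRUE) or an
#'   independently sampled second conformation (default).
#' @param seed integer seed.
#' @param sourceId provenance label.
#' @return A [CoarseStructure-class].
#' @export
syntheticStructure <- function(nResidues, chains = 1, step = 3.8,
                               compactness = 0.5, composition = NULL,
                               interfaceGap = 5.5, symmetric = FALSE,
                               seed = 1, sourceId = NULL) {
  stopifnot(nResidues >= 10, chains %in% c(1, 2))
  if (is.null(sourceId))
    sourceId <- sprintf("synthetic-n%d-c%d-seed%d", nResidues, chains, seed)
  withr::with_seed(seed, {
    pts <- selfAvoidingWalk(nResidues, step, compactness)
    seqLetters <- if (is.null(composition) && nResidues >= 20)
      sample(c(AMINO_ACIDS, sample(AMINO_ACIDS, nResidues - 20,
                                   replace = TRUE)))
    else sample(AMINO_ACIDS, nResidues, replace = TRUE,
                prob = composition)
    ptsB <- if (chains == 2 && !symmetric)
      selfAvoidingWalk(nResidues, step, compactness)
    else NULL
  })
  pts <- round(pts, 3)
  if (chains == 1)
    return(CoarseStructure(rep("A", nResidues), seq_len(nResidues),
                           seqLetters, pts, sourceId))
  if (symmetric) {
    # C2 copy: rotate 180 degrees about a z-parallel axis beyond the chain
    x0 <- max(pts[, 1]) + interfaceGap / 2
    y0 <- mean(pts[, 2])
    ptsB <- cbind(2 * x0 - pts[, 1], 2 * y0 - pts[, 2], pts[, 3])
  } else {
    ptsB <- placeAtInterface(pts, ptsB, interfaceGap)
  }
  CoarseStructure(rep(c("A", "B"), each = nResidues),
                  rep(seq_len(nResidues), 2),
                  rep(seqLetters, 2), round(rbind(pts, ptsB), 3), sourceId)
}

# slide chain B along x until its closest approach to chain A is within
# [gap, gap + 0.25]; the minimum pair distance is 1-Lipschitz in the shift,
# so the fixed-point iterations below converge deterministically
placeAtInterface <- function(ptsA, ptsB, gap, maxIter = 200) {
  shiftB <- function(t) cbind(ptsB[, 1] + t, ptsB[, 2], ptsB[, 3])
  minDist <- function(t) {
    b <- shiftB(t)
    min(vapply(seq_len(nrow(b)), function(i)
      min(sqrt(rowSums((ptsA - matrix(b[i, ], nrow(ptsA), 3,
                                      byrow = TRUE))^2))), numeric(1)))
  }
  t <- max(ptsA[, 1]) - min(ptsB[, 1])  # bounding boxes touching
  for (iter in seq_len(maxIter)) {
    d <- minDist(t)
    if (d >= gap && d <= gap + 0.25) break
    t <- t + (gap - d) * if (d < gap) 1 else 0.9
  }
  shiftB(t)
}

# biased self-avoiding walk; restarts on dead ends, errors when the
# compactness makes self-avoidance infeasible
selfAvoidingWalk <- function(n, step, compactness, hardCore = 3.4,
                             maxTries = 300, maxRestarts = 25) {
  r0 <- (3 * n * 120 / (4 * pi))^(1 / 3)  # ~protein C-alpha density
  randUnit <- function() {
    v <- rnorm(3)
    v / sqrt(sum(v^2))
  }
  for (restart in seq_len(maxRestarts)) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- c(0, 0, 0)
    pts[2, ] <- step * randUnit()
    dead <- FALSE
    for (i in 3:n) {
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        u <- randUnit()
        pull <- -pts[i - 1, ]
        nrm <- sqrt(sum(pull^2))
        w <- if (nrm > 0) compactness * min(1, (nrm / r0)^2) else 0
        d <- (1 - w) * u + if (nrm > 0) w * pull / nrm else 0
        d <- d / sqrt(sum(d^2))
        cand <- pts[i - 1, ] + step * d
        prev <- pts[seq_len(i - 2), , drop = FALSE]
        if (min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3,
                                            byrow = TRUE))^2))) >= hardCore) {
          pts[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        dead <- TRUE
        break
      }
    }
    if (!dead) return(pts)
  }
  stop("self-avoidance failed repeatedly; lower the compactness")
}

#' Generate activity labels coupled to residual scores
#'
#' log2(effect size) = slope * residual + Gaussian(0, noiseSd) noise, with
#' the three-way and binary activity categories derived at the standard
#' thresholds (0.0 and -2.0). Emulates the empirical coupling in which
#' increasingly detrimental structural scores accompany diminishing
#' variant function.
#'
#' @param residuals named numeric vector of residual scores (names are
#'   variant strings).
#' @param slope linear coupling coefficient.
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed (isolated RNG stream).
#' @return data.frame with `variant`, `log2_effect`, `category3`,
#'   `category2`.
#' @export
syntheticActivity <- function(residuals, slope = 1, noiseSd = 0.5,
                              seed = 1) {
  stopifnot(noiseSd >= 0)
  log2e <- withr::with_seed(seed,
    slope * unname(residuals) + rnorm(length(residuals), 0, noiseSd))
  cbind(data.frame(variant = names(residuals), log2_effect = log2e,
                   stringsAsFactors = FALSE),
        activityCategories(log2e))
}

#' Sample a panel of single-residue variants
#'
#' Unique (position, replacement) pairs drawn over the first chain's
#' residue labels, replacement never equal to the native residue.
#'
#' @param structure a [CoarseStructure-class].
#' @param nVariants number of variants to draw.
#' @param seed integer seed.
#' @return Character vector of variant strings like "C14E".
#' @export
syntheticVariantPanel <- function(structure, nVariants, seed = 1) {
  s <- structure@sites[structure@sites$chain == structure@chainOrder[1], ]
  all <- do.call(rbind, lapply(seq_len(nrow(s)), function(i)
    data.frame(native = s$resType[i], position = s$resnum[i],
               replacement = setdiff(AMINO_ACIDS, s$resType[i]),
               stringsAsFactors = FALSE)))
  if (nVariants > nrow(all))
    stop("at most ", nrow(all), " distinct variants available")
  pick <- withr::with_seed(seed, sample.int(nrow(all), nVariants))
  pick <- sort(pick)
  paste0(all$native[pick], all$position[pick], all$replacement[pick])
}

#' Generate a complete synthetic mutagenesis study
#'
#' End-to-end fixture: a training set of monomer globules tessellated to
#' derive a four-body potential; a study structure (homodimer by default);
#' a variant panel with residual scores from the computational
#' mutagenesis; and activity labels linearly coupled to the residual
#' scores. The coupling slope is calibrated once so that the 40th
#' percentile of the noise-free activities sits at the -2 threshold,
#' giving roughly a 40/60 affected/unaffected class balance: the synthetic
#' potential yields a residual-score distribution roughly symmetric about
#' zero, so a purely linear coupling cannot push a majority of variants
#' below the threshold the way a destabilisation-dominated experimental
#' panel does.
#'
#' @param seed integer master seed; all stages draw from seeds derived
#'   from it.
#' @param nResidues residues per chain of the study structure.
#' @param chains 1 or 2 chains for the study structure.
#' @param nTraining number of training globules.
#' @param trainingSize residues per training globule.
#' @param nVariants size of the variant panel.
#' @param noiseSd activity noise standard deviation; by default half the
#'   standard deviation of the noise-free activities, so the structural
#'   signal dominates but is visibly degraded.
#' @param pseudocount pseudocount for the derived potential.
#' @return List: `potential`, `structure`, `tess`, `variants`,
#'   `residuals`, `activities`, `slope`, `secondaryStructure`.
#' @export
syntheticStudy <- function(seed = 1, nResidues = 89, chains = 2,
                           nTraining = 6, trainingSize = 110,
                           nVariants = 250, noiseSd = NULL,
                           pseudocount = 1) {
  training <- lapply(seq_len(nTraining), function(i)
    tessellate(syntheticStructure(trainingSize, chains = 1,
                                  seed = seed + 1000L + i)))
  potential <- derivePotential(training, pseudocount = pseudocount)
  structure <- syntheticStructure(nResidues, chains = chains,
                                  seed = seed + 2000L)
  tess <- tessellate(structure)
  variants <- syntheticVariantPanel(structure, nVariants,
                                    seed = seed + 3000L)
  residuals <- vapply(variants, function(v)
    residualProfile(tess, potential, v)@residualScore, numeric(1))
  # under s = -log(f/p), structurally disruptive substitutions carry
  # positive residuals, so the activity coupling slope is negative; its
  # magnitude puts the 40th percentile of the noise-free activities at -2
  qHi <- quantile(residuals, 0.60, names = FALSE)
  qLo <- quantile(residuals, 0.40, names = FALSE)
  slope <- if (qHi > 0) -2 / qHi else if (qLo < 0) 2 / qLo else -1
  if (is.null(noiseSd)) noiseSd <- 0.5 * sd(slope * residuals)
  activities <- syntheticActivity(residuals, slope = slope,
                                  noiseSd = noiseSd, seed = seed + 4000L)
  # deterministic helix/coil blocks of ~11 residues for the 27-attribute
  # secondary-structure feature
  perChain <- rep(rep(c("helix", "coil"), length.out = ceiling(nResidues / 11)),
                  each = 11)[seq_len(nResidues)]
  list(potential = potential, structure = structure, tess = tess,
       variants = variants, residuals = residuals,
       activities = activities, slope = slope,
       secondaryStructure = rep(perChain, chains))
}
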