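# Independent oracles and shared fixtures for the test suite.

# Brute-force Delaunay-with-cutoff oracle: a 4-subset is retained iff its
# circumsphere is empty of all other points and all 6 edges are within the
# cutoff. Pure R, independent of the compiled enumeration.
bruteDelaunay <- function(xyz, cutoff = Inf) {
  n <- nrow(xyz)
  keep <- character()
  for (sub in asplit(combn(n, 4), 2)) {
    p <- xyz[sub, , drop = FALSE]
    d <- as.vector(dist(p))
    if (max(d) > cutoff) next
    A <- 2 * sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    if (abs(det(A)) < 1e-9) next  # coplanar
    b <- rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2)
    ctr <- solve(A, b)
    r2 <- sum((p[1, ] - ctr)^2)
    others <- setdiff(seq_len(n), sub)
    d2 <- colSums((t(xyz[others, , drop = FALSE]) - ctr)^2)
    if (all(d2 > r2 * (1 + 1e-9)))
      keep <- c(keep, paste(sort(sub), collapse = "-"))
  }
  sort(keep)
}

tetraKeySet <- function(tess) {
  t <- tetrahedra(tess)
  sort(apply(t, 1, paste, collapse = "-"))
}

# Cayley-Menger determinant volume oracle: 288 V^2 = |CM|
cayleyMengerVolume <- function(p) {
  d2 <- as.matrix(dist(p))^2
  cm <- rbind(c(0, 1, 1, 1, 1), cbind(1, d2))
  sqrt(abs(det(cm)) / 288)
}

directMCC <- function(TP, FP, TN, FN) {
  (TP * TN - FP * FN) /
    sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
}

directChiSq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# tiny hand-positioned structures ------------------------------------------

regularTetraCoords <- function(edge = 1) {
  v <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
              4, 3, byrow = TRUE)
  v * edge / (2 * sqrt(2))  # pairwise distances of v are 2*sqrt(2)
}

tetraStructure <- function(letters = c("A", "A", "C", "C"), scale = 5) {
  coords <- scale * matrix(c(0, 0, 0, 1, 0, 0, 0.5, 0.9, 0,
                             0.5, 0.45, 0.8), 4, 3, byrow = TRUE)
  CoarseStructure(rep("A", 4), 1:4, letters, coords, "toy-tetra")
}

# a potential in which every quadruplet scores the same constant
flatPotential <- function(value = 2) {
  keys <- enumerateQuadruplets()
  new("FourBodyPotential", alphabet = AMINO_ACIDS, keys = keys,
      counts = numeric(), f = numeric(), p = numeric(),
      s = rep(value, length(keys)), composition = numeric(),
      logBase = NA_real_, pseudocount = NA_real_)
}

# small linearly separable classification dataset wrapped as VariantDataset
separableDataset <- function(n = 160, gap = 4, seed = 11) {
  stopifnot(n %% 2 == 0)
  feat <- withr::with_seed(seed, {
    half <- n / 2
    data.frame(
      x1 = c(rnorm(half, -gap / 2), rnorm(half, gap / 2)),
      x2 = c(rnorm(half, gap / 2), rnorm(half, -gap / 2)),
      output = factor(rep(c("unaffected", "affected"), each = half),
                      levels = c("unaffected", "affected")))
  })
  feat <- feat[withr::with_seed(seed + 1, sample.int(n)), ]
  rownames(feat) <- NULL
  new("VariantDataset", features = feat, encoding = "monomer-27",
      task = "classification",
      excluded = data.frame(variant = character(), reason = character()))
}

# memoised end-to-end synthetic study shared by feature/model tests
studyFixture <- local({
  cache <- new.env()
  function(seed = 1) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) cache[[key]] <- syntheticStudy(seed = seed)
    cache[[key]]
  }
})

classificationDataset <- function(study, encoding = "dimer-27") {
  assembleDataset(study$activities[, c("variant", "log2_effect")],
                  study$tess, study$potential, encoding = encoding,
                  task = "classification",
                  secondaryStructure = study$secondaryStructure)
}
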