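#' Delaunay-tessellate a coarse-grained structure with an edge filter
#'
#' Computes the Delaunay tessellation of the C-alpha point set (empty
#' circumsphere property) and discards every tetrahedron containing an edge
#' longer than `edgeCutoff`, the convention under which each retained
#' tetrahedron remains scoreable as a residue quadruplet. Exactly
#' cospherical point subsets are resolved by a deterministic symbolic
#' perturbation (joggle), recorded on the returned object.
#'
#' @param structure a [CoarseStructure-class] with at least 4 non-coplanar
#'   sites.
#' @param edgeCutoff edge filter length in Angstrom (default 12).
#' @param tieTol tolerance, as a fraction of the bounding-box diagonal,
#'   that flags a point as lying on a circumsphere (triggering the joggle).
#' @return A [Tessellation-class].
#' @export
tessellate <- function(structure, edgeCutoff = 12, tieTol = 1e-9) {
  xyz <- siteCoords(structure)
  if (nrow(xyz) < 4)
    stop("tessellation undefined: fewer than 4 sites")
  if (qr(scale(xyz, scale = FALSE))$rank < 3)
    stop("tessellation undefined: all sites coplanar")
  raw <- cppDelaunayCutoff(xyz, edgeCutoff, tieTol, 8L, 1e-6)
  tets <- raw$tetrahedra
  if (raw$joggled)
    message(sprintf("cospherical degeneracy: applied deterministic joggle (%d round(s))",
                    raw$joggleRounds))
  geom <- tetraGeometryMatrix(xyz, tets)
  edges <- tetraEdgeSet(tets)
  incident <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) incident[[i]] <- integer()
  if (nrow(tets)) {
    idx <- rep(seq_len(nrow(tets)), each = 4)
    incident <- unname(split(idx, factor(as.vector(t(tets)),
                                         levels = seq_len(nrow(xyz)))))
  }
  new("Tessellation", structure = structure, tetrahedra = tets,
      geometry = geom, edges = edges, edgeCutoff = edgeCutoff,
      incident = incident, joggled = raw$joggled)
}

# all unordered vertex pairs appearing in at least one retained tetrahedron
tetraEdgeSet <- function(tets) {
  if (!nrow(tets))
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("i", "j"))))
  pairs <- combn(4, 2)
  e <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k)
    cbind(tets[, pairs[1, k]], tets[, pairs[2, k]])))
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  dimnames(e) <- list(NULL, c("i", "j"))
  e
}

#' Volume and tetrahedrality of a tetrahedron
#'
#' Volume is |det of the three edge vectors| / 6. Tetrahedrality is the
#' standard edge-length-variance measure
#' sum over edge pairs (l_i - l_j)^2 / (15 * mean(l)^2): zero exactly for a
#' regular tetrahedron, positive otherwise. A coplanar quadruple is
#' reported with volume 0 and flagged degenerate.
#'
#' @param coords 4 x 3 numeric matrix of vertex coordinates.
#' @return List with `volume` (A^3), `tetrahedrality`, `maxEdge` (A) and
#'   `degenerate`.
#' @export
tetraGeometry <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4, ncol(coords) == 3)
  v <- abs(det(rbind(coords[2, ] - coords[1, ],
                     coords[3, ] - coords[1, ],
                     coords[4, ] - coords[1, ]))) / 6
  d <- as.vector(dist(coords))
  lbar <- mean(d)
  tet <- sum(outer(d, d, "-")[upper.tri(diag(6))]^2) / (15 * lbar^2)
  degenerate <- v < 1e-9 * lbar^3
  list(volume = if (degenerate) 0 else v, tetrahedrality = tet,
       maxEdge = max(d), degenerate = degenerate)
}

# vectorised per-tetrahedron geometry for a whole tessellation
tetraGeometryMatrix <- function(xyz, tets) {
  n <- nrow(tets)
  if (!n)
    return(data.frame(volume = numeric(), tetrahedrality = numeric(),
                      maxEdge = numeric()))
  g <- t(vapply(seq_len(n), function(t) {
    gm <- tetraGeometry(xyz[tets[t, ], , drop = FALSE])
    c(gm$volume, gm$tetrahedrality, gm$maxEdge)
  }, numeric(3)))
  data.frame(volume = g[, 1], tetrahedrality = g[, 2], maxEdge = g[, 3])
}

#' Positions sharing a retained edge with a given position
#'
#' @param tess a [Tessellation-class].
#' @param pos flat position index.
#' @return Integer vector of neighboring flat indices (never contains
#'   `pos`), ascending.
#' @export
neighborPositions <- function(tess, pos) {
  n <- nSites(tess@structure)
  if (!(length(pos) == 1 && pos >= 1 && pos <= n))
    stop("unknown position: ", pos)
  e <- tess@edges
  sort(unique(c(e[e[, 1] == pos, 2], e[e[, 2] == pos, 1])))
}

#' Depth classification of tessellation positions
#'
#' Surface positions are vertices of the convex hull of the full point set;
#' undersurface positions are non-surface positions sharing at least one
#' retained edge with a surface position; the remainder are buried. The
#' surface-contact count is the number of retained edges a position has to
#' surface positions. The classifier is a documented, pluggable default.
#'
#' @param tess a [Tessellation-class].
#' @return data.frame with `position`, `label`, `depth` (factor with levels
#'   surface/undersurface/buried) and `surfaceContacts`.
#' @export
classifyDepth <- function(tess) {
  xyz <- siteCoords(tess@structure)
  n <- nrow(xyz)
  onHull <- cppHullVertices(xyz)
  e <- tess@edges
  contacts <- integer(n)
  touchesSurface <- logical(n)
  if (nrow(e)) {
    surfEnd1 <- onHull[e[, 1]]
    surfEnd2 <- onHull[e[, 2]]
    contacts <- tabulate(c(e[surfEnd2, 1], e[surfEnd1, 2]), nbins = n)
    touchesSurface <- tabulate(c(e[surfEnd2, 1], e[surfEnd1, 2]), nbins = n) > 0
  }
  depth <- ifelse(onHull, "surface",
                  ifelse(touchesSurface, "undersurface", "buried"))
  data.frame(position = seq_len(n), label = siteLabels(tess@structure),
             depth = factor(depth,
                            levels = c("surface", "undersurface", "buried")),
             surfaceContacts = contacts, stringsAsFactors = FALSE)
}
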