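test_that("single tetrahedron and bipyramid match the circumsphere definition", {
  st <- tetraStructure()
  tess <- tessellate(st, edgeCutoff = 100)
  expect_equal(nrow(tetrahedra(tess)), 1)
  expect_equal(unname(tetrahedra(tess)[1, ]), 1:4)

  # triangular bipyramid: equatorial triangle plus two apexes -> exactly the
  # two face-sharing tetrahedra found by the brute-force oracle
  pts <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0),
               c(0, 0, 1.2), c(0, 0, -1.2)) * 4
  bp <- CoarseStructure(rep("A", 5), 1:5, rep("G", 5), pts, "bipyramid")
  tess2 <- tessellate(bp, edgeCutoff = 100)
  expect_equal(nrow(tetrahedra(tess2)), 2)
  expect_equal(tetraKeySet(tess2), bruteDelaunay(pts))
  shared <- intersect(tetrahedra(tess2)[1, ], tetrahedra(tess2)[2, ])
  expect_length(shared, 3)  # common face

  expect_error(tessellate(CoarseStructure("A", 1, "A",
                                          matrix(0, 1, 3), "x")),
               "fewer than 4")
  flat <- CoarseStructure(rep("A", 5), 1:5, rep("A", 5),
                          cbind(matrix(rnorm(10), 5), 0), "flat")
  expect_error(tessellate(flat), "coplanar")
})

test_that("retained tetrahedra equal the brute-force oracle on random clouds", {
  for (seed in 1:6) {
    xyz <- withr::with_seed(seed, matrix(runif(24, 0, 10), 8, 3))
    st <- CoarseStructure(rep("A", 8), 1:8,
                          rep_len(c("A", "C", "D"), 8), xyz, "cloud")
    for (cutoff in c(7, 12, 1e6)) {
      tess <- tessellate(st, edgeCutoff = cutoff)
      expect_equal(tetraKeySet(tess), bruteDelaunay(xyz, cutoff),
                   info = sprintf("seed %d cutoff %g", seed, cutoff))
    }
  }
})

test_that("tessellation is invariant under global translation", {
  st <- syntheticStructure(40, seed = 9)
  t1 <- tessellate(st)
  shifted <- CoarseStructure(st@sites$chain, st@sites$resnum,
                             st@sites$resType,
                             sweep(siteCoords(st), 2, c(-100, 50, 7.3), "+"),
                             "shifted")
  t2 <- tessellate(shifted)
  expect_equal(tetraKeySet(t1), tetraKeySet(t2))
})

test_that("tetrahedron geometry matches symmetry and Cayley-Menger oracles", {
  g <- tetraGeometry(regularTetraCoords(1))
  expect_equal(g$volume, 1 / (6 * sqrt(2)), tolerance = 1e-12)
  expect_equal(g$tetrahedrality, 0, tolerance = 1e-12)

  square <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3,
                   byrow = TRUE)
  gs <- tetraGeometry(square)
  expect_equal(gs$volume, 0)
  expect_true(gs$degenerate)

  for (seed in 1:10) {
    p <- withr::with_seed(seed, matrix(rnorm(12, sd = 4), 4, 3))
    expect_equal(tetraGeometry(p)$volume, cayleyMengerVolume(p),
                 tolerance = 1e-8)
  }
})

test_that("neighbor sets come from retained edges and reject unknown positions", {
  st <- tetraStructure()
  tess <- tessellate(st, edgeCutoff = 100)
  expect_equal(neighborPositions(tess, 2), c(1L, 3L, 4L))
  expect_error(neighborPositions(tess, 9), "unknown position")

  glob <- tessellate(syntheticStructure(60, seed = 5))
  e <- tessEdges(glob)
  # symmetry and self-exclusion of the neighbor relation
  for (pos in c(1, 17, 60)) {
    nb <- neighborPositions(glob, pos)
    expect_false(pos %in% nb)
    expect_true(all(vapply(nb, function(q)
      pos %in% neighborPositions(glob, q), TRUE)))
  }
  # every retained edge appears in >= 1 retained tetrahedron (and vice versa)
  fromTets <- TessMut:::tetraEdgeSet(tetrahedra(glob))
  expect_equal(e, fromTets)
  # incident-map degrees sum to 4 x number of tetrahedra
  expect_equal(sum(lengths(glob@incident)), 4 * nrow(tetrahedra(glob)))
})

test_that("depth classes: hull is surface, shell center is undersurface", {
  st <- tetraStructure()
  tess <- tessellate(st, edgeCutoff = 100)
  d <- classifyDepth(tess)
  expect_true(all(d$depth == "surface"))
  expect_true(all(d$surfaceContacts == 3))

  # icosahedral shell around a central vertex (cospherical by construction,
  # exercising the deterministic joggle)
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
  ico <- ico / sqrt(1 + phi^2) * 7
  pts <- rbind(ico, c(0, 0, 0))
  shell <- CoarseStructure(rep("A", 13), 1:13, rep_len(AMINO_ACIDS, 13),
                           pts, "shell")
  tessS <- suppressMessages(tessellate(shell, edgeCutoff = 100))
  dS <- classifyDepth(tessS)
  expect_equal(as.character(dS$depth[13]), "undersurface")
  expect_true(all(dS$depth[-13] == "surface"))
  expect_equal(dS$surfaceContacts[13], length(neighborPositions(tessS, 13)))

  # the three classes partition a larger globule
  glob <- tessellate(syntheticStructure(150, seed = 8))
  dG <- classifyDepth(glob)
  expect_false(anyNA(dG$depth))
  expect_equal(nrow(dG), 150)
})

test_that("compiled tessellation agrees with an external Qhull implementation", {
  xyz <- withr::with_seed(33, matrix(runif(120, 0, 20), 40, 3))
  st <- CoarseStructure(rep("A", 40), 1:40, rep_len(AMINO_ACIDS, 40),
                        xyz, "cloud40")
  tess <- tessellate(st, edgeCutoff = 1e6)  # unfiltered Delaunay
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- withr::local_tempfile(fileext = ".txt")
  write.table(xyz, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- paste(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    "pts = np.loadtxt(sys.argv[1], delimiter=',')",
    "tri = Delaunay(pts)",
    "rows = sorted(tuple(sorted(s + 1)) for s in tri.simplices)",
    "open(sys.argv[2], 'w').write('\\n'.join('-'.join(map(str, r)) for r in rows))",
    sep = "\n")
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(code, py)
  status <- system2("python", c(py, csv, out), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out) && file.size(out) > 0,
              info = paste(status, collapse = "\n"))
  expect_equal(tetraKeySet(tess), sort(readLines(out)))
})
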