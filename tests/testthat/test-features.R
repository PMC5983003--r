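test_that("six nearest neighbors are the distance-sorted edge neighbors", {
  study <- studyFixture()
  tess <- tessellate(study$structure)  # same geometry as the study dimer
  xyz <- siteCoords(tess@structure)
  checked <- 0
  for (pos in seq_len(nSites(tess@structure))) {
    nbrs <- neighborPositions(tess, pos)
    if (length(nbrs) < 6) {
      expect_error(sixNearestNeighbors(tess, pos), "insufficient neighbors")
      next
    }
    got <- sixNearestNeighbors(tess, pos)
    d <- sqrt(colSums((t(xyz[nbrs, , drop = FALSE]) - xyz[pos, ])^2))
    expect_equal(got, nbrs[order(d, nbrs)][1:6])
    checked <- checked + 1
  }
  expect_gt(checked, 100)

  single <- tessellate(tetraStructure(), edgeCutoff = 100)
  expect_error(sixNearestNeighbors(single, 1), "insufficient neighbors")
})

test_that("activity thresholds place boundaries exactly as defined", {
  cats <- activityCategories(c(0.5, 0, -2, -2.0001, 3))
  expect_equal(as.character(cats$category3),
               c("Superior", "Similar", "Similar", "Inferior", "Superior"))
  expect_equal(as.character(cats$category2),
               c("unaffected", "unaffected", "unaffected", "affected",
                 "unaffected"))
})

test_that("the 27-attribute vector is assembled field by field", {
  study <- studyFixture()
  tess <- study$tess
  pot <- study$potential
  ss <- study$secondaryStructure
  v <- study$variants[10]
  pv <- parseVariant(v)
  row <- buildFeatureVector27(v, tess, pot, secondaryStructure = ss)
  inputCols <- setdiff(names(row), "output")
  expect_length(inputCols, 27)

  # independent assembly from module outputs
  st <- tess@structure
  site <- which(st@sites$resnum == pv$position &
                  st@sites$chain == "A")
  prof <- residualProfile(tess, pot, v)
  nn <- sixNearestNeighbors(tess, site)
  d <- classifyDepth(tess)
  expect_equal(row$pos_number, pv$position)
  expect_equal(as.character(row$native), pv$native)
  expect_equal(as.character(row$replacement), pv$replacement)
  expect_equal(row$ep_mut, unname(prof@ep[site]))
  for (k in 1:6) {
    expect_equal(row[[paste0("sep_", k)]],
                 st@sites$resnum[nn[k]] - st@sites$resnum[site])
    expect_equal(as.character(row[[paste0("nbr_res_", k)]]),
                 st@sites$resType[nn[k]])
    expect_equal(row[[paste0("nbr_ep_", k)]], unname(prof@ep[nn[k]]))
  }
  inc <- tess@incident[[site]]
  expect_equal(row$mean_volume, mean(tess@geometry$volume[inc]))
  expect_equal(row$mean_tetrahedrality,
               mean(tess@geometry$tetrahedrality[inc]))
  expect_equal(as.character(row$depth), as.character(d$depth[site]))
  expect_equal(row$surface_contacts, d$surfaceContacts[site])
  expect_equal(as.character(row$sec_struct), ss[site])

  # a flat potential zeroes all seven EP attributes
  rowFlat <- buildFeatureVector27(v, tess, flatPotential(1),
                                  secondaryStructure = ss)
  epCols <- c("ep_mut", paste0("nbr_ep_", 1:6))
  expect_equal(unname(unlist(rowFlat[epCols])), rep(0, 7))
})

test_that("profile vectors split the dimeric residual profile by chain", {
  study <- studyFixture()
  v <- study$variants[4]
  pvs <- buildProfileFeatureVectors(v, study$tess, study$potential)
  expect_length(pvs, 2)
  expect_equal(ncol(pvs[[1]]), 89)
  full <- residualProfile(study$tess, study$potential, v)@ep
  expect_equal(c(unlist(pvs[[1]]), unlist(pvs[[2]])), unname(full),
               ignore_attr = TRUE)
  withId <- buildProfileFeatureVectors(v, study$tess, study$potential,
                                       includeId = TRUE)
  expect_equal(ncol(withId[[1]]), 92)

  unequal <- concatenateChains(list(
    syntheticStructure(12, seed = 1),
    local({
      s <- syntheticStructure(13, seed = 2)
      CoarseStructure(rep("B", 13), s@sites$resnum, s@sites$resType,
                      siteCoords(s) + 40, "b")
    })))
  tessU <- tessellate(unequal)
  expect_error(
    buildProfileFeatureVectors(paste0(residueTypes(unequal)[1], 1, "W"),
                               tessU, flatPotential(1)),
    "unequal")
})

test_that("dataset assembly applies encodings, outputs and the dropping rule", {
  study <- studyFixture()
  act <- study$activities[, c("variant", "log2_effect")]
  ds2 <- classificationDataset(study, "dimer-27")
  # two rows per retained variant, same output, generally different inputs
  counts <- table(ds2@features$.variant)
  expect_true(all(counts == 2))
  byVar <- split(ds2@features, ds2@features$.variant)
  sameOut <- vapply(byVar, function(b)
    length(unique(b$output)) == 1, TRUE)
  expect_true(all(sameOut))
  differInputs <- vapply(byVar, function(b)
    !isTRUE(all.equal(b[1, featureColumns(ds2)], b[2, featureColumns(ds2)],
                      check.attributes = FALSE)), TRUE)
  expect_gt(mean(differInputs), 0.9)

  # dropping rule: a variant appears iff its position has >= 6 neighbors
  sparseTess <- tessellate(study$structure, edgeCutoff = 7)
  dsSparse <- assembleDataset(act, sparseTess, study$potential,
                              encoding = "monomer-27",
                              task = "classification")
  nbrCount <- vapply(seq_len(nSites(study$structure)), function(p)
    length(neighborPositions(sparseTess, p)), 1L)
  sitesA <- study$structure@sites[study$structure@sites$chain == "A", ]
  eligible <- vapply(act$variant, function(v)
    nbrCount[which(sitesA$resnum == parseVariant(v)$position)] >= 6, TRUE)
  expect_setequal(unique(dsSparse@features$.variant),
                  act$variant[eligible])
  expect_setequal(dsSparse@excluded$variant, act$variant[!eligible])
  expect_gt(nrow(dsSparse@excluded), 0)

  # profile encodings keep under-connected positions
  dsProf <- assembleDataset(act[1:20, ], study$tess, study$potential,
                            encoding = "profile-EP+ID",
                            task = "regression")
  expect_equal(nrow(dsProf@features), 40)
  expect_length(featureColumns(dsProf), 92)
  expect_true(is.numeric(dsProf@features$output))

  dup <- rbind(act[1:3, ], act[2, ])
  expect_error(assembleDataset(dup, study$tess, study$potential,
                               encoding = "dimer-27",
                               task = "classification"),
               "duplicate variant")
})
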