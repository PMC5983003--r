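#' Six nearest structural neighbors of a position
#'
#' Among the positions sharing a retained tessellation edge with `pos`, the
#' six with the smallest C-alpha Euclidean distance, ascending; ties broken
#' deterministically by lower flat index. Positions with fewer than six
#' retained-edge neighbors cannot supply the full local attribute set and
#' raise an error, so their variants are excluded from 27-attribute
#' datasets.
#'
#' @param tess a [Tessellation-class].
#' @param pos flat position index.
#' @return Integer vector of 6 flat indices.
#' @export
sixNearestNeighbors <- function(tess, pos) {
  nbrs <- neighborPositions(tess, pos)
  if (length(nbrs) < 6)
    stop(sprintf("insufficient neighbors at position %s: %d < 6",
                 siteLabels(tess@structure)[pos], length(nbrs)))
  xyz <- siteCoords(tess@structure)
  d <- sqrt(colSums((t(xyz[nbrs, , drop = FALSE]) - xyz[pos, ])^2))
  nbrs[order(d, nbrs)][1:6]
}

#' Activity categories from log2(effect size)
#'
#' Three-way: Superior (> 0), Similar ([-2, 0]), Inferior (< -2); binary:
#' unaffected (>= -2) versus affected (< -2). The -2 boundary belongs to
#' unaffected/Similar.
#'
#' @param log2effect numeric vector.
#' @return data.frame with factors `category3` and `category2`.
#' @export
activityCategories <- function(log2effect) {
  data.frame(
    category3 = factor(ifelse(log2effect > 0, "Superior",
                              ifelse(log2effect >= -2, "Similar", "Inferior")),
                       levels = c("Superior", "Similar", "Inferior")),
    category2 = factor(ifelse(log2effect >= -2, "unaffected", "affected"),
                       levels = c("unaffected", "affected")))
}

# single 27-attribute row for one mutated site (flat index) of a variant,
# given the variant's (possibly multimeric) residual profile
featureRow27 <- function(tess, potential, v, site, profile, depthTable,
                         secondaryStructure) {
  st <- tess@structure
  nn <- sixNearestNeighbors(tess, site)
  ep <- profile@ep
  geom <- tess@geometry[tess@incident[[site]], , drop = FALSE]
  row <- data.frame(
    pos_number = st@sites$resnum[site],
    native = factor(v$native, levels = AMINO_ACIDS),
    replacement = factor(v$replacement, levels = AMINO_ACIDS),
    ep_mut = unname(ep[site]),
    stringsAsFactors = FALSE)
  for (k in 1:6)
    row[[paste0("sep_", k)]] <-
      st@sites$resnum[nn[k]] - st@sites$resnum[site]
  for (k in 1:6)
    row[[paste0("nbr_res_", k)]] <- factor(st@sites$resType[nn[k]],
                                           levels = AMINO_ACIDS)
  for (k in 1:6) row[[paste0("nbr_ep_", k)]] <- unname(ep[nn[k]])
  row$mean_volume <- mean(geom$volume)
  row$mean_tetrahedrality <- mean(geom$tetrahedrality)
  row$depth <- depthTable$depth[site]
  row$surface_contacts <- depthTable$surfaceContacts[site]
  row$sec_struct <- factor(secondaryStructure[site],
                           levels = c("helix", "strand", "coil"))
  row
}

#' Build the 27-attribute feature vector of a variant
#'
#' Attributes, in order: position number; native and replacement residue;
#' EP score at the mutated position; signed primary-sequence separations to
#' the six closest structural neighbors; the neighbors' residue identities
#' and EP scores; mean tetrahedron volume and mean tetrahedrality over the
#' tetrahedra incident to the mutated vertex; depth class and
#' surface-contact count; secondary structure at the mutated position.
#' The mutation is applied at every chain copy of the residue label; the
#' local attributes describe the copy in `chain` (default: the first).
#'
#' @param variant variant string or list.
#' @param tess a [Tessellation-class].
#' @param potential a [FourBodyPotential-class].
#' @param secondaryStructure character vector per flat position
#'   (helix/strand/coil); all-coil when NULL.
#' @param chain chain whose copy of the mutated label the local attributes
#'   describe.
#' @return One-row data.frame with 27 input attributes.
#' @export
buildFeatureVector27 <- function(variant, tess, potential,
                                 secondaryStructure = NULL, chain = NULL) {
  v <- parseVariant(variant)
  st <- tess@structure
  if (is.null(secondaryStructure))
    secondaryStructure <- rep("coil", nSites(st))
  if (is.null(chain)) chain <- st@chainOrder[1]
  sites <- variantSites(st, v)
  site <- sites[st@sites$chain[sites] == chain]
  if (length(site) != 1) stop("no copy of position ", v$position,
                              " in chain ", chain)
  prof <- residualProfile(tess, potential, v)
  featureRow27(tess, potential, v, site, prof, classifyDepth(tess),
               secondaryStructure)
}

#' Per-chain residual-profile (EP-vector) feature encodings
#'
#' The variant's full residual profile over the multimer is split by chain
#' into one EP vector per chain (89 components per chain for the Gal4
#' dimer); their concatenation is the full profile. With `includeId`, three
#' variant-ID attributes (wild-type residue, position number, replacement
#' residue) are appended. Chains must have equal lengths. Positions with
#' too few neighbors for the 27-attribute encoding are representable here.
#'
#' @inheritParams buildFeatureVector27
#' @param includeId append the 3 variant-ID attributes.
#' @return List of one-row data.frames, one per chain.
#' @export
buildProfileFeatureVectors <- function(variant, tess, potential,
                                       includeId = FALSE) {
  v <- parseVariant(variant)
  st <- tess@structure
  lens <- vapply(st@chainOrder, function(ch) sum(st@sites$chain == ch), 1L)
  if (length(unique(lens)) != 1)
    stop("chains have unequal lengths: ", paste(lens, collapse = ", "))
  prof <- residualProfile(tess, potential, v)
  lapply(st@chainOrder, function(ch) {
    ep <- unname(prof@ep[st@sites$chain == ch])
    row <- as.data.frame(as.list(setNames(ep, paste0("ep_", seq_along(ep)))))
    if (includeId) {
      row$id_native <- factor(v$native, levels = AMINO_ACIDS)
      row$id_position <- v$position
      row$id_replacement <- factor(v$replacement, levels = AMINO_ACIDS)
    }
    row
  })
}

#' Read a variant activity table
#'
#' Tab-separated `variant<TAB>log2_effect` with variant syntax like "C14E".
#'
#' @param file path.
#' @return data.frame with columns `variant` and `log2_effect`.
#' @export
readActivityTable <- function(file) {
  tab <- read.table(file, sep = "\t", header = FALSE,
                    col.names = c("variant", "log2_effect"),
                    stringsAsFactors = FALSE)
  if (!is.numeric(tab$log2_effect)) stop("non-numeric activity column")
  tab
}

#' Assemble a labelled variant dataset for model training
#'
#' Builds one feature row per variant (monomer-27), per variant x chain
#' (dimer-27, profile encodings), labels rows with the activity output
#' (binary category for classification, log2 effect for regression), and
#' drops 27-attribute variants whose mutated position has fewer than six
#' neighbors, recording them in the exclusion manifest.
#'
#' @param activities data.frame with columns `variant` (e.g. "C14E") and
#'   `log2_effect`.
#' @param tess a [Tessellation-class].
#' @param potential a [FourBodyPotential-class].
#' @param encoding one of "monomer-27", "dimer-27", "profile-EP",
#'   "profile-EP+ID".
#' @param task "classification" or "regression".
#' @param secondaryStructure per-position map for the 27-attribute
#'   encodings; all-coil when NULL.
#' @return A [VariantDataset-class].
#' @export
assembleDataset <- function(activities, tess, potential,
                            encoding = c("monomer-27", "dimer-27",
                                         "profile-EP", "profile-EP+ID"),
                            task = c("classification", "regression"),
                            secondaryStructure = NULL) {
  encoding <- match.arg(encoding)
  task <- match.arg(task)
  if (anyDuplicated(activities$variant))
    stop("duplicate variant(s): ",
         paste(unique(activities$variant[duplicated(activities$variant)]),
               collapse = ", "))
  st <- tess@structure
  if (is.null(secondaryStructure))
    secondaryStructure <- rep("coil", nSites(st))
  depthTable <- if (grepl("27", encoding)) classifyDepth(tess) else NULL

  rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(activities))) {
    vstr <- activities$variant[i]
    v <- parseVariant(vstr)
    out <- activities$log2_effect[i]
    built <- tryCatch({
      if (encoding %in% c("profile-EP", "profile-EP+ID")) {
        fr <- buildProfileFeatureVectors(vstr, tess, potential,
                                         includeId = endsWith(encoding, "ID"))
        chains <- st@chainOrder
      } else {
        sites <- variantSites(st, v)
        chains <- st@sites$chain[sites]
        if (encoding == "monomer-27") {
          sites <- sites[1]
          chains <- chains[1]
        }
        prof <- residualProfile(tess, potential, v)
        fr <- lapply(sites, function(sIdx)
          featureRow27(tess, potential, v, sIdx, prof, depthTable,
                       secondaryStructure))
      }
      list(fr = fr, chains = chains)
    }, error = function(e) e)
    if (inherits(built, "error")) {
      if (!grepl("insufficient neighbors", conditionMessage(built)))
        stop("variant ", vstr, ": ", conditionMessage(built))
      excluded[[length(excluded) + 1L]] <-
        data.frame(variant = vstr, reason = conditionMessage(built),
                   stringsAsFactors = FALSE)
      next
    }
    for (k in seq_along(built$fr)) {
      r <- built$fr[[k]]
      meta <- data.frame(.variant = vstr, .chain = built$chains[k],
                         .position = v$position, .native = v$native,
                         .replacement = v$replacement,
                         .log2_effect = out, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(meta, r)
    }
  }
  if (!length(rows)) stop("no feature rows could be assembled")
  feat <- do.call(rbind, rows)
  feat$output <- if (task == "classification")
    activityCategories(feat$.log2_effect)$category2
  else feat$.log2_effect
  rownames(feat) <- NULL
  new("VariantDataset", features = feat, encoding = encoding, task = task,
      excluded = if (length(excluded)) do.call(rbind, excluded)
                 else data.frame(variant = character(),
                                 reason = character()))
}

#' Input-attribute column names of a dataset
#'
#' @param dataset a [VariantDataset-class].
#' @return Character vector of feature column names (metadata and output
#'   excluded).
#' @export
featureColumns <- function(dataset) {
  nm <- names(dataset@features)
  nm[!startsWith(nm, ".") & nm != "output"]
}

#' Export a dataset as CSV (header, one row per feature vector)
#'
#' @param dataset a [VariantDataset-class].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeDatasetCsv <- function(dataset, file) {
  cols <- c(featureColumns(dataset), "output")
  write.table(dataset@features[, cols], file, sep = ",", row.names = FALSE,
              quote = TRUE)
  invisible(file)
}
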