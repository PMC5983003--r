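#' Mean residual scores by activity category and substitution class
#'
#' Averages variant residual scores within the three activity categories
#' (Superior/Similar/Inferior), overall and split into conservative (C)
#' and non-conservative (NC) substitutions, with per-cell counts and
#' two-sample t-tests between category pairs on the overall scores.
#'
#' @param activities data.frame with columns `variant` and `log2_effect`.
#' @param residuals named numeric vector of residual scores, names matching
#'   `activities$variant`.
#' @return List with `means` (category x subset data.frame) and `tests`
#'   (pairwise t-test p-values).
#' @export
categoryMeans <- function(activities, residuals) {
  stopifnot(all(activities$variant %in% names(residuals)))
  r <- residuals[activities$variant]
  v <- lapply(activities$variant, parseVariant)
  cls <- substitutionClass(vapply(v, `[[`, "", "native"),
                           vapply(v, `[[`, "", "replacement"))
  cat3 <- activityCategories(activities$log2_effect)$category3
  cells <- expand.grid(category = levels(cat3), subset = c("All", "C", "NC"),
                       stringsAsFactors = FALSE)
  means <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- cat3 == cells$category[i] &
      (cells$subset[i] == "All" | cls == cells$subset[i])
    data.frame(category = cells$category[i], subset = cells$subset[i],
               mean = if (any(sel)) mean(r[sel]) else NA_real_,
               n = sum(sel))
  }))
  pairs <- combn(levels(cat3), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- r[cat3 == pairs[1, j]]
    b <- r[cat3 == pairs[2, j]]
    p <- if (length(a) > 1 && length(b) > 1)
      tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(pair = paste(pairs[, j], collapse = "/"), p = p)
  }))
  list(means = means, tests = tests)
}

#' Quadrant of a position in the CMP-versus-RES plane
#'
#' Q1: RES > 0, CMP > 0; Q2: RES < 0, CMP > 0; Q3: both < 0; Q4: RES > 0,
#' CMP < 0. Exact zeros are assigned to the positive half-plane (a
#' deterministic boundary convention).
#'
#' @param res,cmp numeric vectors of equal length.
#' @return Factor with levels Q1..Q4.
#' @export
quadrantAssignment <- function(res, cmp) {
  stopifnot(length(res) == length(cmp))
  factor(ifelse(res >= 0, ifelse(cmp >= 0, "Q1", "Q4"),
                ifelse(cmp >= 0, "Q2", "Q3")),
         levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Pearson chi-square test of a contingency table
#'
#' Expected counts from the margins, no continuity correction,
#' df = (r-1)(c-1). Fisher's exact test is reported alongside when it can
#' be computed (delegated to the standard routine).
#'
#' @param counts matrix of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p.value`, `expected`, `fisher.p`.
#' @export
contingencyChiSquare <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table")
  if (any(counts < 0) || sum(counts) == 0)
    stop("counts must be non-negative with a positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  fp <- tryCatch(fisher.test(counts, workspace = 2e7)$p.value,
                 error = function(e) NA_real_)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, expected = ct$expected, fisher.p = fp)
}

#' Least-squares relation between CMP and RES profiles
#'
#' Ordinary least squares of CMP on RES with the coefficient of
#' determination; `subset` selects the overall CMP or the conservative /
#' non-conservative submeans when a [CmpProfile-class] is supplied.
#'
#' @param res numeric RES vector or a [PotentialProfile-class].
#' @param cmp numeric CMP vector or a [CmpProfile-class].
#' @param subset "All", "C" or "NC" (used when `cmp` is a profile object).
#' @return List with `slope`, `intercept`, `r.squared`, `n`.
#' @export
cmpResCorrelation <- function(res, cmp, subset = c("All", "C", "NC")) {
  subset <- match.arg(subset)
  if (is(res, "PotentialProfile")) res <- res@res
  if (is(cmp, "CmpProfile"))
    cmp <- switch(subset, All = cmp@cmp, C = cmp@cCmp, NC = cmp@ncCmp)
  keep <- is.finite(res) & is.finite(cmp)
  res <- res[keep]
  cmp <- cmp[keep]
  if (length(res) < 3) stop("need at least 3 positions")
  if (var(res) == 0) stop("zero variance in RES")
  fit <- lm(cmp ~ res)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = summary(fit)$r.squared, n = length(res))
}

#' Summaries of annotated residue-position groups
#'
#' For each named group of author residue positions (resolved in the first
#' chain): the mean residue environment score (M.R.E.S.), the mean residual
#' score over all 19 x N substitutions in the group ("All") with
#' conservative/non-conservative submeans and counts, and the group's
#' quadrant distribution in the CMP-versus-RES plane.
#'
#' @param groups named list of author residue-number vectors.
#' @param profile a [PotentialProfile-class] for the structure.
#' @param cmpProf the matching [CmpProfile-class].
#' @param structure the [CoarseStructure-class] the profiles describe.
#' @return List with `summary` (one row per group) and `quadrants`
#'   (group x quadrant count table).
#' @export
annotatedGroupSummary <- function(groups, profile, cmpProf, structure) {
  firstChain <- structure@chainOrder[1]
  s <- structure@sites
  resolve <- function(posNums, groupName) {
    idx <- match(posNums, ifelse(s$chain == firstChain, s$resnum, NA))
    if (anyNA(idx))
      stop(sprintf("group '%s': unknown position(s) %s", groupName,
                   paste(posNums[is.na(idx)], collapse = ", ")))
    idx
  }
  quad <- quadrantAssignment(profile@res, cmpProf@cmp)
  rows <- list()
  qrows <- list()
  for (g in names(groups)) {
    idx <- resolve(groups[[g]], g)
    rmat <- cmpProf@residuals[idx, , drop = FALSE]
    cmat <- cmpProf@classes[idx, , drop = FALSE]
    rows[[g]] <- data.frame(
      group = g, n_positions = length(idx),
      mres = mean(profile@res[idx]),
      all_mean = mean(rmat, na.rm = TRUE),
      all_n = sum(!is.na(rmat)),
      c_mean = mean(rmat[cmat == "C"], na.rm = TRUE),
      c_n = sum(cmat == "C", na.rm = TRUE),
      nc_mean = mean(rmat[cmat == "NC"], na.rm = TRUE),
      nc_n = sum(cmat == "NC", na.rm = TRUE))
    qrows[[g]] <- table(quad[idx])
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       quadrants = do.call(rbind, qrows))
}

#' Residue-polarity classification table in the CMP-versus-RES plane
#'
#' Cross-tabulates positions by quadrant and by the polarity of the native
#' residue (charged/polar/apolar; the class lists are configurable and
#' echoed in the result).
#'
#' @param profile a [PotentialProfile-class].
#' @param cmpProf the matching [CmpProfile-class].
#' @param structure the [CoarseStructure-class].
#' @param polarity named list of residue-letter vectors defining the
#'   classes.
#' @return List with `table` (quadrant x polarity counts) and `polarity`.
#' @export
polarityQuadrantTable <- function(profile, cmpProf, structure,
                                  polarity = POLARITY_CLASSES) {
  quad <- quadrantAssignment(profile@res, cmpProf@cmp)
  pol <- factor(residuePolarity(residueTypes(structure), polarity),
                levels = names(polarity))
  list(table = table(quadrant = quad, polarity = pol), polarity = polarity)
}
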