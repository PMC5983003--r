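#' Canonical key for an unordered residue quadruplet
#'
#' @param letters character vector of 4 one-letter residue codes (any order).
#' @return Single string: the four letters in ascending alphabetical order.
#' @export
quadrupletKey <- function(letters) {
  stopifnot(length(letters) == 4)
  paste(sort(letters), collapse = "")
}

#' Enumerate all unordered residue quadruplets
#'
#' All multisets of size 4 over the alphabet, each represented once by its
#' ascending-alphabetical key, in lexicographic order. For the 20-letter
#' amino-acid alphabet this gives 8855 keys (versus 160,000 ordered
#' 4-words).
#'
#' @param alphabet character vector of residue letters.
#' @return Character vector of keys.
#' @export
enumerateQuadruplets <- function(alphabet = AMINO_ACIDS) {
  if (!length(alphabet)) stop("empty alphabet")
  alphabet <- sort(alphabet)
  a <- length(alphabet)
  # multisets of size 4 == strictly increasing 4-subsets of 1..(a+3)
  comb <- combn(a + 3L, 4L)
  idx <- comb - (0:3)
  apply(idx, 2, function(i) paste(alphabet[i], collapse = ""))
}

#' Multinomial chance rate of a residue quadruplet
#'
#' p = 4! / prod(t_n!) * prod(a_n^t_n), where a_n is the composition
#' proportion of letter n and t_n its multiplicity in the quadruplet.
#' Summed over all unordered quadruplets, the rates total 1.
#'
#' @param key quadruplet key (see [quadrupletKey()]).
#' @param composition named numeric vector of per-letter proportions,
#'   summing to 1 within 1e-9.
#' @return Numeric probability.
#' @export
multinomialRate <- function(key, composition) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  letters <- strsplit(key, "")[[1]]
  if (!all(letters %in% names(composition)))
    stop("key letters not covered by composition: ", key)
  t_n <- table(letters)
  factorial(4) / prod(factorial(t_n)) *
    prod(composition[names(t_n)]^as.vector(t_n))
}

# vectorised rates for all keys at once
multinomialRates <- function(keys, composition) {
  vapply(keys, multinomialRate, numeric(1), composition = composition,
         USE.NAMES = FALSE)
}

# quadruplet keys of every retained tetrahedron in a tessellation
tessellationKeys <- function(tess) {
  tets <- tetrahedra(tess)
  if (!nrow(tets)) return(character())
  res <- residueTypes(tess@structure)
  m <- matrix(res[tets], ncol = 4)
  m <- t(apply(m, 1, sort))
  paste0(m[, 1], m[, 2], m[, 3], m[, 4])
}

#' Derive a four-body potential from training tessellations
#'
#' Counts one occurrence per retained tetrahedron per tessellation, forms
#' observed relative frequencies f (after adding `pseudocount` to every
#' key), computes multinomial chance rates p from the pooled residue
#' composition of the training structures, and scores each quadruplet as
#' s = -log(f/p). With `pseudocount = 0`, never-observed quadruplets are
#' explicitly unscored (NA score) rather than silently assigned an energy.
#'
#' @param tessellations list of [Tessellation-class] objects.
#' @param logBase base of the logarithm (default natural log).
#' @param pseudocount non-negative count added to every quadruplet.
#' @param alphabet residue alphabet.
#' @return A [FourBodyPotential-class].
#' @export
derivePotential <- function(tessellations, logBase = exp(1), pseudocount = 0,
                            alphabet = AMINO_ACIDS) {
  if (is(tessellations, "Tessellation")) tessellations <- list(tessellations)
  if (!length(tessellations)) stop("no training tessellations")
  keys <- enumerateQuadruplets(alphabet)
  obs <- unlist(lapply(tessellations, tessellationKeys))
  if (!length(obs)) stop("zero retained tetrahedra in the training set")
  bad <- setdiff(unique(unlist(lapply(tessellations, function(t)
    residueTypes(t@structure)))), alphabet)
  if (length(bad)) stop("residue type(s) outside alphabet: ",
                        paste(bad, collapse = ", "))
  counts <- setNames(numeric(length(keys)), keys)
  tab <- table(obs)
  counts[names(tab)] <- as.numeric(tab)

  pooled <- unlist(lapply(tessellations, function(t)
    residueTypes(t@structure)))
  composition <- setNames(numeric(length(alphabet)), sort(alphabet))
  ptab <- table(pooled)
  composition[names(ptab)] <- as.numeric(ptab) / length(pooled)

  p <- multinomialRates(keys, composition)
  fnum <- counts + pseudocount
  f <- fnum / sum(fnum)
  s <- unname(ifelse(fnum > 0 & p > 0, -log(f / p) / log(logBase),
                     NA_real_))
  new("FourBodyPotential", alphabet = sort(alphabet), keys = keys,
      counts = unname(counts), f = unname(f), p = p, s = s,
      composition = composition, logBase = logBase,
      pseudocount = pseudocount)
}

# score lookup for a character vector of keys; NA for unscored
lookupScores <- function(potential, keys) {
  idx <- match(keys, potential@keys)
  if (anyNA(idx))
    stop("unknown quadruplet key(s): ",
         paste(unique(keys[is.na(idx)]), collapse = ", "))
  potential@s[idx]
}

#' Read a four-body potential table
#'
#' Two-column whitespace-delimited text: the sorted 4-letter quadruplet key
#' followed by its score (or NA for an unscored quadruplet). Compatible
#' with the potential1417cut12.txt dialect. Keys must be sorted 4-letter
#' words over the 20-letter alphabet, each appearing once; malformed input
#' is rejected with the offending line number.
#'
#' @param file path to the table.
#' @param alphabet residue alphabet the keys must use.
#' @return A [FourBodyPotential-class] carrying scores only (no counts).
#' @export
readPotential <- function(file, alphabet = AMINO_ACIDS) {
  lines <- readLines(file)
  keep <- which(nzchar(trimws(lines)))
  keys <- enumerateQuadruplets(alphabet)
  s <- setNames(rep(NA_real_, length(keys)), keys)
  seen <- character()
  for (ln in keep) {
    parts <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("line %d: expected 'KEY score', got '%s'", ln, lines[ln]))
    key <- parts[1]
    letters <- strsplit(key, "")[[1]]
    if (length(letters) != 4 || !all(letters %in% alphabet))
      stop(sprintf("line %d: unknown or malformed key '%s'", ln, key))
    if (is.unsorted(letters))
      stop(sprintf("line %d: key '%s' not in ascending order", ln, key))
    if (key %in% seen)
      stop(sprintf("line %d: duplicate key '%s'", ln, key))
    seen <- c(seen, key)
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val) && parts[2] != "NA")
      stop(sprintf("line %d: malformed score '%s'", ln, parts[2]))
    s[key] <- val
  }
  new("FourBodyPotential", alphabet = sort(alphabet), keys = keys,
      counts = numeric(), f = numeric(), p = numeric(),
      s = unname(s[keys]), composition = numeric(), logBase = NA_real_,
      pseudocount = NA_real_)
}

#' Write a four-body potential table
#'
#' @param potential a [FourBodyPotential-class].
#' @param file output path.
#' @param digits significant digits for scores (default 10, preserving
#'   well beyond 6 significant digits on round trip).
#' @return Invisibly, the file path.
#' @export
writePotential <- function(potential, file, digits = 10) {
  sc <- potential@s
  txt <- ifelse(is.na(sc), "NA", formatC(sc, digits = digits, format = "g"))
  writeLines(paste(potential@keys, txt), file)
  invisible(file)
}
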