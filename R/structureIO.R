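#' Construct a CoarseStructure from raw site data
#'
#' Low-level constructor used by the PDB reader and the synthetic-structure
#' generator. Sites must be supplied in flat order (chains as contiguous
#' blocks, author residue numbers strictly increasing within each chain).
#'
#' @param chain character vector of chain identifiers, one per site.
#' @param resnum integer author residue numbers.
#' @param resType one-letter residue codes.
#' @param coords n x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @param sourceId provenance label.
#' @return A [CoarseStructure-class].
#' @export
CoarseStructure <- function(chain, resnum, resType, coords,
                            sourceId = "structure") {
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("CoarseStructure",
      sites = data.frame(chain = as.character(chain),
                         resnum = as.integer(resnum),
                         resType = as.character(resType),
                         stringsAsFactors = FALSE),
      coords = coords, sourceId = as.character(sourceId),
      chainOrder = unique(as.character(chain)))
}

#' Read a C-alpha trace from a PDB file
#'
#' Extracts one site per residue having a C-alpha atom from the requested
#' chains, in file order, and renumbers the selected chains into a single
#' continuous flat index (chains in the order given). Alternate locations
#' are resolved to the blank/'A' conformer; selenomethionine and other
#' common modified residues are mapped to their parent amino acid; residues
#' that cannot be mapped to the 20-letter alphabet are skipped with a
#' warning, as are residues lacking a C-alpha record.
#'
#' @param pdbFile path to a PDB-format file.
#' @param chains character vector of chain identifiers to keep, in the
#'   desired concatenation order. Default: all chains, file order.
#' @param sourceId provenance label; defaults to the file name.
#' @return A [CoarseStructure-class].
#' @export
readCalphaStructure <- function(pdbFile, chains = NULL,
                                sourceId = basename(pdbFile)) {
  pdb <- bio3d::read.pdb(pdbFile)
  at <- pdb$atom
  if (is.null(chains)) chains <- unique(at$chain)
  missing <- setdiff(chains, unique(at$chain))
  if (length(missing))
    stop("chain(s) not present in ", pdbFile, ": ",
         paste(missing, collapse = ", "))

  perChain <- lapply(chains, function(ch) {
    sub <- at[at$chain %in% ch, , drop = FALSE]
    ca <- sub[sub$elety == "CA" &
                (is.na(sub$alt) | sub$alt %in% c("", " ", "A")), ,
              drop = FALSE]
    noCA <- setdiff(unique(sub$resno), unique(ca$resno))
    if (length(noCA))
      warning(sprintf("chain %s: residue(s) %s lack a CA record and were skipped",
                      ch, paste(noCA, collapse = ", ")), call. = FALSE)
    if (anyDuplicated(ca$resno))
      stop(sprintf("chain %s: duplicate residue number(s) %s", ch,
                   paste(unique(ca$resno[duplicated(ca$resno)]),
                         collapse = ", ")))
    aa1 <- suppressWarnings(bio3d::aa321(ca$resid))
    bad <- is.na(aa1) | !(aa1 %in% AMINO_ACIDS)
    if (any(bad)) {
      warning(sprintf("chain %s: skipping unmappable residue(s) %s", ch,
                      paste(unique(ca$resid[bad]), collapse = ", ")),
              call. = FALSE)
      ca <- ca[!bad, , drop = FALSE]
      aa1 <- aa1[!bad]
    }
    list(chain = rep(ch, nrow(ca)), resnum = ca$resno, resType = aa1,
         coords = as.matrix(ca[, c("x", "y", "z")]))
  })
  if (!sum(vapply(perChain, function(p) length(p$resnum), 1L)))
    stop("no CA atoms found in ", pdbFile)
  CoarseStructure(
    chain   = unlist(lapply(perChain, `[[`, "chain")),
    resnum  = unlist(lapply(perChain, `[[`, "resnum")),
    resType = unlist(lapply(perChain, `[[`, "resType")),
    coords  = do.call(rbind, lapply(perChain, `[[`, "coords")),
    sourceId = sourceId)
}

#' Concatenate per-chain structures into one flat-indexed structure
#'
#' Renumbers the flat index continuously across the input structures in the
#' given order (the multimer convention: positions of later chains follow
#' those of earlier chains), preserving the original chain and author
#' residue-number labels. Applying it to a single structure is the identity.
#'
#' @param structures list of [CoarseStructure-class] objects with pairwise
#'   distinct chain identifiers.
#' @param sourceId provenance label for the result.
#' @return A [CoarseStructure-class].
#' @export
concatenateChains <- function(structures, sourceId = NULL) {
  if (is(structures, "CoarseStructure")) structures <- list(structures)
  if (!length(structures)) stop("no structures to concatenate")
  allChains <- unlist(lapply(structures, function(s) s@chainOrder))
  if (anyDuplicated(allChains))
    stop("duplicate chain identifier(s): ",
         paste(unique(allChains[duplicated(allChains)]), collapse = ", "))
  if (is.null(sourceId))
    sourceId <- paste(vapply(structures, function(s) s@sourceId, ""),
                      collapse = "+")
  CoarseStructure(
    chain   = unlist(lapply(structures, function(s) s@sites$chain)),
    resnum  = unlist(lapply(structures, function(s) s@sites$resnum)),
    resType = unlist(lapply(structures, function(s) s@sites$resType)),
    coords  = do.call(rbind, lapply(structures, siteCoords)),
    sourceId = sourceId)
}

#' Write a CoarseStructure as PDB-format C-alpha ATOM records
#'
#' @param structure a [CoarseStructure-class].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writePdbFile <- function(structure, file) {
  s <- structure@sites
  xyz <- siteCoords(structure)
  aa3 <- bio3d::aa123(s$resType)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(s)), aa3, s$chain, s$resnum, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Per-position secondary structure from PDB header records
#'
#' Three-state (helix/strand/coil) assignment parsed from the HELIX and
#' SHEET records of a PDB file, mapped onto the flat positions of a
#' structure. Positions not covered by either record are coil. This source
#' is pluggable: any named character vector of the same shape can be passed
#' wherever a secondary-structure map is accepted.
#'
#' @param pdbFile path to the PDB file carrying the header records.
#' @param structure the [CoarseStructure-class] to annotate.
#' @return Character vector ("helix"/"strand"/"coil"), one per flat position.
#' @export
secondaryStructureFromPdb <- function(pdbFile, structure) {
  pdb <- bio3d::read.pdb(pdbFile)
  s <- structure@sites
  ss <- rep("coil", nrow(s))
  mark <- function(rec, label) {
    if (is.null(rec) || !length(rec$start)) return()
    for (i in seq_along(rec$start)) {
      hit <- s$chain == rec$chain[i] &
        s$resnum >= as.integer(rec$start[i]) &
        s$resnum <= as.integer(rec$end[i])
      ss[hit] <<- label
    }
  }
  mark(pdb$helix, "helix")
  mark(pdb$sheet, "strand")
  ss
}

#' Read a training-list file of PDB chain selections
#'
#' Each line holds a 4-character PDB code followed by '@' (single-chain
#' file) or one capital chain letter (the chain to select from a multimer).
#'
#' @param file path to the list file.
#' @return data.frame with columns `pdbId` and `chain` (NA for '@' entries).
#' @export
readTrainingList <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines)]
  ok <- grepl("^[0-9A-Za-z]{4}(@|[A-Z])$", lines)
  if (any(!ok))
    stop("malformed training-list line(s): ",
         paste(head(lines[!ok], 3), collapse = ", "))
  data.frame(pdbId = substr(lines, 1, 4),
             chain = ifelse(substr(lines, 5, 5) == "@", NA_character_,
                            substr(lines, 5, 5)),
             stringsAsFactors = FALSE)
}
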