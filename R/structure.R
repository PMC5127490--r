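#' Construct a Structure from a moiety table
#'
#' @param atoms data.frame with columns `moiety_id`, `resno`, `role`,
#'   `x`, `y`, `z` (nm).
#' @param resolution `"heavy-atom"` or `"Ca"`.
#' @return A [Structure-class] object.
#' @export
Structure <- function(atoms, resolution = c("heavy-atom", "Ca")) {
  resolution <- match.arg(resolution)
  atoms$resno <- as.integer(atoms$resno)
  atoms$moiety_id <- as.character(atoms$moiety_id)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, resolution = resolution)
}

#' Read a protein structure from a PDB file
#'
#' Reads one chain of a PDB file at heavy-atom resolution (hydrogens are
#' dropped).  Alternate locations are resolved to the highest-occupancy
#' record, ties broken by altloc label order; insertion codes are rejected.
#' Coordinates are converted from Angstrom to nm.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier (single letter).
#' @return A heavy-atom [Structure-class].
#' @examples
#' pdb <- system.file("extdata", "toy3.pdb", package = "pullscope")
#' s <- readStructure(pdb, chain = "A")
#' nResidues(s)
#' @export
readStructure <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!chain %in% a$chain)
    stop("chain '", chain, "' not present in ", path)
  a <- a[a$chain == chain, , drop = FALSE]
  if (any(!is.na(a$insert) & nzchar(a$insert)))
    stop("insertion codes are not supported; renumber the PDB file first")
  # drop hydrogens by element symbol when present, else by atom-name heuristic
  elem <- a$elesy
  if (all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    isH <- grepl("^[0-9]*H", trimws(a$elety))
  } else {
    isH <- trimws(elem) %in% c("H", "D")
  }
  a <- a[!isH, , drop = FALSE]
  # altloc resolution: highest occupancy, ties by label order (A first)
  alt <- ifelse(is.na(a$alt) | !nzchar(a$alt), "", a$alt)
  key <- paste(a$resno, trimws(a$elety))
  keep <- rep(TRUE, nrow(a))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    occ <- a$o[idx]
    occ[is.na(occ)] <- 1
    best <- idx[order(-occ, alt[idx])][1]
    keep[setdiff(idx, best)] <- FALSE
  }
  a <- a[keep, , drop = FALSE]
  a <- a[order(a$resno, a$eleno), , drop = FALSE]
  resnos <- unique(a$resno)
  missing_ca <- resnos[!resnos %in% a$resno[trimws(a$elety) == "CA"]]
  if (length(missing_ca))
    stop("residues without a CA atom: ", paste(missing_ca, collapse = ", "))
  Structure(
    data.frame(moiety_id = paste0(a$resno, ":", trimws(a$elety)),
               resno = a$resno, role = "heavy-atom",
               x = a$x / 10, y = a$y / 10, z = a$z / 10,
               stringsAsFactors = FALSE),
    resolution = "heavy-atom")
}

#' Coarse-grain a structure
#'
#' `"Ca"` keeps one bead per residue at the C-alpha position; `"heavy-atom"`
#' keeps all non-hydrogen atoms (the identity for structures read with
#' [readStructure()]).
#'
#' @param structure a [Structure-class].
#' @param resolution target resolution.
#' @return A [Structure-class] at the requested resolution.
#' @export
coarseGrain <- function(structure, resolution = c("Ca", "heavy-atom")) {
  resolution <- match.arg(resolution)
  a <- structure@atoms
  if (resolution == "heavy-atom") {
    if (structure@resolution == "Ca")
      stop("cannot refine a Ca structure to heavy-atom resolution")
    return(structure)
  }
  if (structure@resolution == "Ca") return(structure)
  isCA <- sub("^[0-9]+:", "", a$moiety_id) == "CA"
  resnos <- unique(a$resno)
  got <- a$resno[isCA]
  missing <- resnos[!resnos %in% got]
  if (length(missing))
    stop("residues without a CA atom: ", paste(missing, collapse = ", "))
  ca <- a[isCA, , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  ca$role <- "Ca"
  Structure(ca, resolution = "Ca")
}

#' Write a structure to a (single-model) PDB file
#'
#' Only C-alpha/backbone-bead structures are supported; used for exporting
#' toy structures and trajectory frames for external viewers.
#'
#' @param structure a C-alpha [Structure-class].
#' @param path output file path.
#' @export
writeStructure <- function(structure, path) {
  a <- structure@atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")]) * 10))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = "GLY", elety = "CA", chain = "A")
  invisible(path)
}
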