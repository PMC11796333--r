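## Structure I/O and ligand extraction. Parsing and writing of the
## fixed-column PDB dialect are delegated to bio3d; this layer normalises
## records into the canonical atom table and enforces the package's
## altloc/hydrogen/mass policies.

.WATER_CODES <- c("HOH", "WAT", "H2O", "DOD", "D2O")

## Normalise an element symbol: first letter upper-case, rest lower-case.
.normalize_element <- function(el) {
  el <- trimws(el)
  out <- paste0(toupper(substr(el, 1L, 1L)), tolower(substring(el, 2L)))
  out[!nzchar(el)] <- ""
  out
}

## Standard atomic masses from bio3d's periodic table. Unknown elements are
## a hard error rather than a silent default mass.
.element_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      cache <<- e$elements
    }
    cache
  }
})

.element_masses <- function(elements) {
  tab <- .element_table()
  m <- tab$mass[match(.normalize_element(elements), tab$symb)]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "),
         "; cannot assign atomic masses", call. = FALSE)
  m
}

#' Read a PDB structure
#'
#' Parses all ATOM and HETATM records of a PDB file into a
#' [PDBStructure-class]. Author residue numbering and insertion codes are
#' preserved. When alternate locations are present, the lowest-sorting
#' altloc identifier (usually \code{"A"}, or blank) is kept per atom site.
#' Hydrogens are retained but flagged, and excluded from all geometry
#' operations downstream.
#'
#' @param path Path to a PDB file.
#' @param id Structure identifier; defaults to the file stem.
#' @return A [PDBStructure-class].
#' @examples
#' toy <- generateToyComplex(seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(toy$structure, f)
#' s <- readStructure(f)
#' nrow(atomTable(s))
#' @export
readStructure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  rec_lines <- grep("^(ATOM  |HETATM)", raw)
  if (!length(rec_lines))
    stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)),
    error = function(e)
      stop("parse error in ", path, " near line ", rec_lines[1], ": ",
           conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad))
    stop("parse error in ", path, " at line ", rec_lines[bad[1]],
         ": non-numeric coordinates", call. = FALSE)

  blank <- function(v) ifelse(is.na(v), "", trimws(v))
  elesy <- blank(a$elesy)
  element <- .normalize_element(elesy)
  need <- !nzchar(element)
  if (any(need)) {
    element[need] <- vapply(a$elety[need], function(nm) {
      tryCatch(bio3d::atom2ele(nm, rescue = FALSE),
               error = function(e)
                 stop("unknown element for atom name '", nm, "' in ", path,
                      call. = FALSE),
               warning = function(w) suppressWarnings(bio3d::atom2ele(nm)))
    }, character(1))
    element[need] <- .normalize_element(element[need])
  }

  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = blank(a$alt),
    resname = trimws(a$resid),
    chain = blank(a$chain),
    resno = as.integer(a$resno),
    icode = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = element,
    stringsAsFactors = FALSE)
  atoms$mass <- .element_masses(atoms$element)
  atoms$hetero <- a$type == "HETATM"
  atoms$hydrogen <- atoms$element %in% c("H", "D")

  ## altloc policy: one atom per site, lowest-sorting altloc identifier
  site <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
                atoms$name, sep = "\r")
  keep <- !duplicated(site)
  if (any(!keep)) {
    ord <- order(site, atoms$altloc)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(site[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  new("PDBStructure", id = id, atoms = atoms)
}

#' Write a structure as fixed-column PDB
#'
#' @param s A [PDBStructure-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeStructure <- function(s, path) {
  stopifnot(is(s, "PDBStructure"))
  a <- s@atoms
  suppressWarnings(bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    resno = a$resno,
    resid = a$resname,
    eleno = a$serial,
    elety = a$name,
    chain = ifelse(nzchar(a$chain), a$chain, " "),
    insert = ifelse(nzchar(a$icode), a$icode, ""),
    alt = ifelse(nzchar(a$altloc), a$altloc, ""),
    o = a$occupancy,
    b = rep(0, nrow(a)),
    elesy = toupper(a$element)))
  invisible(path)
}

## Residue-level grouping key used throughout (author numbering).
.residue_key <- function(atoms)
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")

#' Extract a bound ligand from a structure
#'
#' Returns the heavy atoms of the heterogen residue with the requested
#' three-letter code. Waters are never matched. If several copies of the
#' code exist (e.g. one per protomer), the chain must be given.
#'
#' @param s A [PDBStructure-class].
#' @param code Heterogen residue name (e.g. \code{"B12"} for cobalamin).
#'   The code is taken from the user; it is never guessed.
#' @param chain Optional chain identifier to disambiguate multiple copies.
#' @return A [Ligand-class] of heavy atoms.
#' @examples
#' toy <- generateToyComplex(seed = 1)
#' lig <- extractLigand(toy$structure, "LIG")
#' ligandCode(lig)
#' @export
extractLigand <- function(s, code, chain = NULL) {
  stopifnot(is(s, "PDBStructure"))
  if (toupper(code) %in% .WATER_CODES)
    stop("'", code, "' is water and is never extracted as a ligand",
         call. = FALSE)
  het <- s@atoms[s@atoms$hetero & !s@atoms$resname %in% .WATER_CODES, ,
                 drop = FALSE]
  hit <- het[het$resname == code, , drop = FALSE]
  if (!nrow(hit)) {
    avail <- sort(unique(het$resname))
    stop("het code '", code, "' not found in ", s@id,
         if (length(avail)) paste0("; available: ",
                                   paste(avail, collapse = ", "))
         else "; structure has no (non-water) het groups",
         call. = FALSE)
  }
  if (!is.null(chain)) {
    hit <- hit[hit$chain == chain, , drop = FALSE]
    if (!nrow(hit))
      stop("het code '", code, "' not present in chain ", chain,
           call. = FALSE)
  }
  groups <- unique(.residue_key(hit))
  if (length(groups) > 1L)
    stop("het code '", code, "' is ambiguous (", length(groups),
         " copies in chains ", paste(sort(unique(hit$chain)), collapse = ","),
         "); specify 'chain'", call. = FALSE)
  heavy <- hit[!hit$hydrogen, , drop = FALSE]
  rownames(heavy) <- NULL
  new("Ligand", source = s@id, code = code, atoms = heavy)
}

## Heavy (non-hydrogen) atom coordinates as an n x 3 matrix.
.heavy_coords <- function(obj) {
  a <- if (is.data.frame(obj)) obj else atomTable(obj)
  a <- a[!a$hydrogen, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
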