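## Docking-box geometry from the reference ligand, plus ingestion of
## externally produced docked poses. No docking engine is invoked
## in-process: the box is written as an engine-neutral key=value block and
## poses come back as ligand-only PDB files.

#' Centre of mass of a ligand
#'
#' Mass-weighted mean of the heavy-atom coordinates, using standard atomic
#' masses by element. This is the docking-box centre.
#'
#' @param l A [Ligand-class].
#' @return Length-3 numeric vector (Angstrom).
#' @export
centerOfMass <- function(l) {
  stopifnot(is(l, "Ligand"))
  a <- l@atoms[!l@atoms$hydrogen, , drop = FALSE]
  if (!nrow(a)) stop("ligand has no heavy atoms", call. = FALSE)
  w <- a$mass
  if (sum(w) <= 0) stop("zero total mass", call. = FALSE)
  as.numeric(colSums(as.matrix(a[, c("x", "y", "z")]) * w) / sum(w))
}

#' Radius of gyration of a ligand
#'
#' Unweighted (coordinate-only) root-mean-square distance of the heavy
#' atoms from their geometric centre. A single atom has Rg 0. The
#' mass-weighted alternative (about the centre of mass) is available via
#' \code{weighted = TRUE}; the unweighted form is the default used for
#' docking-box sizing.
#'
#' @param l A [Ligand-class].
#' @param weighted Use mass weighting (default \code{FALSE}).
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(l, weighted = FALSE) {
  stopifnot(is(l, "Ligand"))
  xyz <- .heavy_coords(l)
  if (!nrow(xyz)) stop("ligand has no heavy atoms", call. = FALSE)
  if (weighted) {
    w <- l@atoms$mass[!l@atoms$hydrogen]
    ctr <- colSums(xyz * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(xyz, 2L, ctr)^2)) / sum(w))
  } else {
    ctr <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2)))
  }
}

#' Cubic docking box from a ligand
#'
#' The box is centred on the ligand centre of mass and its edge is
#' \code{ratio} times the ligand radius of gyration, giving an
#' Rg x Rg x Rg cube at the default ratio of 1.0.
#'
#' @param l A [Ligand-class].
#' @param ratio Positive edge multiplier (default 1.0).
#' @param weighted_rg Use the mass-weighted radius of gyration.
#' @return A [Box-class].
#' @examples
#' toy <- generateToyComplex(seed = 1)
#' dockingBox(extractLigand(toy$structure, "LIG"))
#' @export
dockingBox <- function(l, ratio = 1.0, weighted_rg = FALSE) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stop("ratio must be a positive number", call. = FALSE)
  rg <- radiusOfGyration(l, weighted = weighted_rg)
  if (rg <= 0)
    stop("degenerate box: ligand radius of gyration is zero ",
         "(single-atom ligand?)", call. = FALSE)
  new("Box", center = centerOfMass(l), edge = ratio * rg, ratio = ratio)
}

#' Write box parameters as an engine-neutral key=value block
#'
#' @param box A [Box-class].
#' @param path Optional output file; when \code{NULL} the lines are
#'   returned (and printed at the console by the CLI).
#' @return Character vector of \code{key = value} lines, invisibly when
#'   written to a file.
#' @export
writeBoxParams <- function(box, path = NULL) {
  stopifnot(is(box, "Box"))
  lines <- c(
    sprintf("center_x = %.3f", box@center[1]),
    sprintf("center_y = %.3f", box@center[2]),
    sprintf("center_z = %.3f", box@center[3]),
    sprintf("size_x = %.3f", box@edge),
    sprintf("size_y = %.3f", box@edge),
    sprintf("size_z = %.3f", box@edge))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

## Composition fingerprint used to verify poses are the same molecule.
.composition_key <- function(atoms) {
  a <- atoms[!atoms$hydrogen, , drop = FALSE]
  paste(sort(paste(a$name, a$element, sep = "/")), collapse = ";")
}

#' Ingest externally docked poses
#'
#' Reads ligand-only PDB files produced by a third-party docking engine,
#' verifies that every pose has the same heavy-atom composition, and orders
#' them best score first (lower score = better, the binding-affinity
#' convention). Engine name and settings are recorded as metadata only.
#'
#' @param paths Character vector of pose PDB files.
#' @param scores Optional numeric vector of engine scores aligned with
#'   \code{paths} (or a data.frame with columns \code{file}, \code{score}).
#' @param engine_meta Free-text engine provenance recorded in the set. The
#'   default records the conventional adapter settings (AutoDock
#'   Vina-style search, exhaustiveness 10); the metadata is informational
#'   and never enforced.
#' @return A [PoseSet-class].
#' @export
ingestPoses <- function(paths, scores = NULL,
                        engine_meta = "AutoDock Vina-style adapter; exhaustiveness=10") {
  if (!length(paths)) stop("no pose files given", call. = FALSE)
  if (is.data.frame(scores)) {
    idx <- match(basename(paths), basename(scores$file))
    if (anyNA(idx))
      stop("scores table lacks entries for: ",
           paste(basename(paths)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    scores <- scores$score[idx]
  }
  if (is.null(scores)) scores <- rep(NA_real_, length(paths))
  if (length(scores) != length(paths))
    stop("scores must align with pose files", call. = FALSE)
  ligs <- lapply(paths, function(p) {
    s <- readStructure(p)
    a <- s@atoms[!s@atoms$hydrogen, , drop = FALSE]
    rownames(a) <- NULL
    new("Ligand", source = s@id, code = unique(a$resname)[1], atoms = a)
  })
  keys <- vapply(ligs, function(l) .composition_key(l@atoms), character(1))
  if (length(unique(keys)) > 1L) {
    off <- which(keys != keys[1])[1]
    stop("pose atom composition mismatch in file: ", paths[off],
         call. = FALSE)
  }
  ord <- order(scores, seq_along(scores), na.last = TRUE)
  new("PoseSet", poses = ligs[ord], scores = scores[ord],
      engine_meta = engine_meta)
}
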