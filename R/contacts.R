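## Ligand-contact residue detection, including the lower axial metal ligand
## characteristic of cobalamin photoreceptors.

.MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

## All pairwise distances between two coordinate matrices (rows = atoms).
.cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Find protein residues in contact with a ligand
#'
#' A residue is a contact when any of its heavy atoms lies within
#' \code{cutoff} of any heavy ligand atom. The default 4.0 Angstrom
#' heavy-atom cutoff is the standard contact convention covering hydrogen
#' bonds and hydrophobic packing. Contacts from any chain are reported
#' (binding pockets can span protomer interfaces), with the chain recorded
#' so cross-chain contacts remain distinguishable.
#'
#' @param s A [PDBStructure-class] sharing a coordinate frame with the
#'   ligand.
#' @param l A [Ligand-class].
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return A [ContactProfile-class]; per residue, the exact minimum
#'   heavy-atom distance, whether the contact is via mainchain, sidechain
#'   or both, and the ligand atom names within the cutoff.
#' @examples
#' toy <- generateToyComplex(seed = 1)
#' findContacts(toy$structure, extractLigand(toy$structure, "LIG"))
#' @export
findContacts <- function(s, l, cutoff = 4.0) {
  stopifnot(is(s, "PDBStructure"), is(l, "Ligand"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  lig <- l@atoms[!l@atoms$hydrogen, , drop = FALSE]
  if (!nrow(lig)) stop("empty ligand", call. = FALSE)
  prot <- s@atoms[!s@atoms$hetero & !s@atoms$hydrogen, , drop = FALSE]
  empty <- data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      min_dist = numeric(), via = character(),
                      ligand_part = character(), stringsAsFactors = FALSE)
  if (!nrow(prot))
    return(new("ContactProfile", records = empty, cutoff = cutoff,
               source = s@id))
  D <- .cross_dist(as.matrix(prot[, c("x", "y", "z")]),
                   as.matrix(lig[, c("x", "y", "z")]))
  within <- D <= cutoff
  hit_atom <- rowSums(within) > 0
  if (!any(hit_atom))
    return(new("ContactProfile", records = empty, cutoff = cutoff,
               source = s@id))
  key <- .residue_key(prot)
  rows <- lapply(split(which(hit_atom), key[hit_atom]), function(idx) {
    r1 <- prot[idx[1], ]
    sub <- within[idx, , drop = FALSE]
    main <- prot$name[idx] %in% .MAINCHAIN_ATOMS
    via <- if (any(main) && any(!main)) "both"
           else if (any(main)) "mainchain" else "sidechain"
    data.frame(chain = r1$chain, resno = r1$resno, icode = r1$icode,
               resname = r1$resname,
               min_dist = min(D[idx, , drop = FALSE]),
               via = via,
               ligand_part = paste(sort(unique(
                 lig$name[colSums(sub) > 0])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rows)
  rec <- rec[order(rec$chain, rec$resno, rec$icode), , drop = FALSE]
  rownames(rec) <- NULL
  new("ContactProfile", records = rec, cutoff = cutoff, source = s@id)
}

#' Identify the lower axial metal ligand
#'
#' For a metal-containing cofactor (cobalt in cobalamin), returns the
#' protein residue owning the heavy atom nearest the metal, provided that
#' atom is within \code{max_dist}; this is the residue coordinating the
#' metal face opposite the organic upper ligand (e.g. the histidine below
#' the corrin ring).
#'
#' @param s A [PDBStructure-class].
#' @param l A [Ligand-class] containing exactly one atom of
#'   \code{metal_element}.
#' @param metal_element Element symbol of the metal (default \code{"Co"}).
#' @param max_dist Maximum coordination distance in Angstrom (default 3.0).
#' @return A list with \code{found} (logical); when found, also
#'   \code{chain}, \code{resno}, \code{icode}, \code{resname},
#'   \code{atom} (coordinating protein atom name) and \code{dist}.
#'   \code{found = FALSE} (no protein atom within range) is a valid result,
#'   not an error.
#' @export
axialLigand <- function(s, l, metal_element = "Co", max_dist = 3.0) {
  stopifnot(is(s, "PDBStructure"), is(l, "Ligand"))
  metal_element <- .normalize_element(metal_element)
  mi <- which(l@atoms$element == metal_element & !l@atoms$hydrogen)
  if (length(mi) == 0L)
    stop("ligand contains no ", metal_element, " atom", call. = FALSE)
  if (length(mi) > 1L)
    stop("ligand contains ", length(mi), " ", metal_element,
         " atoms; exactly one is required", call. = FALSE)
  m <- as.numeric(l@atoms[mi, c("x", "y", "z")])
  prot <- s@atoms[!s@atoms$hetero & !s@atoms$hydrogen, , drop = FALSE]
  if (!nrow(prot)) stop("structure has no polymer atoms", call. = FALSE)
  d <- sqrt(colSums((t(as.matrix(prot[, c("x", "y", "z")])) - m)^2))
  i <- which.min(d)
  if (d[i] > max_dist) return(list(found = FALSE, dist = unname(d[i])))
  list(found = TRUE, chain = prot$chain[i], resno = prot$resno[i],
       icode = prot$icode[i], resname = prot$resname[i],
       atom = prot$name[i], dist = unname(d[i]))
}

#' Per-residue contact frequency over a pose ensemble
#'
#' Runs [findContacts()] for every pose and reports, per residue, the
#' fraction of poses in which it is a contact. Records are sorted by
#' frequency (descending), then residue number.
#'
#' @param poses A [PoseSet-class].
#' @param s Receptor [PDBStructure-class].
#' @param cutoff Heavy-atom distance cutoff in Angstrom.
#' @param box Optional [Box-class]; poses whose centroid lies further than
#'   twice the box edge from the box centre trigger a frame-mismatch
#'   warning but are still counted.
#' @return A [ContactProfile-class] whose records carry a
#'   \code{frequency} column.
#' @export
contactFrequency <- function(poses, s, cutoff = 4.0, box = NULL) {
  stopifnot(is(poses, "PoseSet"))
  n <- length(poses@poses)
  if (n < 1L) stop("at least one pose required", call. = FALSE)
  all_rec <- list()
  for (i in seq_len(n)) {
    p <- poses@poses[[i]]
    if (!is.null(box)) {
      ctr <- colMeans(.heavy_coords(p))
      if (sqrt(sum((ctr - box@center)^2)) > 2 * box@edge)
        warning("pose ", i, " centroid lies far from the docking box ",
                "(possible frame mismatch); pose still counted",
                call. = FALSE)
    }
    prof <- findContacts(s, p, cutoff = cutoff)
    r <- prof@records
    if (nrow(r)) { r$pose <- i; all_rec[[length(all_rec) + 1L]] <- r }
  }
  if (!length(all_rec)) {
    rec <- data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      min_dist = numeric(), via = character(),
                      ligand_part = character(), frequency = numeric(),
                      stringsAsFactors = FALSE)
    return(new("ContactProfile", records = rec, cutoff = cutoff,
               source = "pose ensemble"))
  }
  rec <- do.call(rbind, all_rec)
  key <- paste(rec$chain, rec$resno, rec$icode, sep = "\r")
  rows <- lapply(split(seq_len(nrow(rec)), key), function(idx) {
    r1 <- rec[idx[1], ]
    via <- unique(rec$via[idx])
    data.frame(chain = r1$chain, resno = r1$resno, icode = r1$icode,
               resname = r1$resname, min_dist = min(rec$min_dist[idx]),
               via = if (length(via) == 1L) via else "both",
               ligand_part = paste(sort(unique(unlist(
                 strsplit(rec$ligand_part[idx], ",")))), collapse = ","),
               frequency = length(idx) / n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$frequency, out$resno, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  new("ContactProfile", records = out, cutoff = cutoff,
      source = "pose ensemble")
}
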