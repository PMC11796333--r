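#' @import methods
#' @importFrom stats setNames
NULL

## Canonical atom table columns used by PDBStructure and Ligand. Coordinates
## are in Angstrom, masses in atomic mass units, numbering is author numbering.
.ATOM_COLS <- c("serial", "name", "altloc", "resname", "chain", "resno",
                "icode", "x", "y", "z", "occupancy", "element", "mass",
                "hetero", "hydrogen")

.validate_atom_table <- function(atoms) {
  if (!is.data.frame(atoms)) return("'atoms' must be a data.frame")
  missing_cols <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing_cols))
    return(paste0("atom table lacks columns: ",
                  paste(missing_cols, collapse = ", ")))
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      return("atom coordinates must be finite")
    if (!all(is.finite(atoms$mass) & atoms$mass > 0))
      return("atom masses must be positive and finite")
    if (any(!nzchar(atoms$element)))
      return("atom elements must be non-empty")
  }
  TRUE
}

#' Macromolecular structure
#'
#' Holds all ATOM/HETATM records of a structure in a single atom table with
#' author residue numbering (including insertion codes) preserved. Polymer
#' atoms come from ATOM records; heterogens (ligands, ions, waters) from
#' HETATM records and are flagged \code{hetero}.
#'
#' @slot id Structure identifier (file stem or PDB id).
#' @slot atoms A data.frame with one row per atom; columns \code{serial},
#'   \code{name}, \code{altloc}, \code{resname}, \code{chain}, \code{resno},
#'   \code{icode}, \code{x}, \code{y}, \code{z}, \code{occupancy},
#'   \code{element}, \code{mass}, \code{hetero}, \code{hydrogen}.
#' @seealso [readStructure()], [writeStructure()], [extractLigand()]
#' @exportClass PDBStructure
setClass("PDBStructure",
         representation(id = "character", atoms = "data.frame"),
         validity = function(object) {
           msg <- .validate_atom_table(object@atoms)
           if (!isTRUE(msg)) return(msg)
           if (nrow(object@atoms) == 0L) return("structure has zero atoms")
           TRUE
         })

#' Small-molecule ligand extracted from a structure
#'
#' Heavy atoms of one heterogen residue group, carrying element and mass so
#' that the centre of mass and radius of gyration are computable.
#'
#' @slot source Identifier of the parent structure.
#' @slot code Three-letter heterogen code (e.g. \code{"B12"}).
#' @slot atoms Atom table (same columns as [PDBStructure-class]).
#' @exportClass Ligand
setClass("Ligand",
         representation(source = "character", code = "character",
                        atoms = "data.frame"),
         validity = function(object) {
           msg <- .validate_atom_table(object@atoms)
           if (!isTRUE(msg)) return(msg)
           if (nrow(object@atoms) == 0L) return("ligand has zero atoms")
           TRUE
         })

#' Result of an optimal rigid-body superposition
#'
#' @slot rotation 3x3 proper rotation matrix (determinant +1).
#' @slot translation Length-3 translation vector (Angstrom).
#' @slot rmsd Root-mean-square deviation after superposition (Angstrom).
#' @slot n_pairs Number of paired atoms.
#' @slot pairs Provenance data.frame mapping paired residues (may be empty).
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", n_pairs = "integer",
                        pairs = "data.frame"),
         validity = function(object) {
           R <- object@rotation
           if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
           if (abs(det(R) - 1) > 1e-9)
             return("rotation determinant must be +1 (within 1e-9)")
           if (max(abs(crossprod(R) - diag(3))) > 1e-9)
             return("rotation must be orthonormal")
           if (object@rmsd < 0) return("rmsd must be non-negative")
           TRUE
         })

#' Cubic docking box derived from a ligand
#'
#' Edge length equals \code{ratio} times the ligand radius of gyration; the
#' centre is the ligand centre of mass.
#'
#' @slot center Length-3 centre (Angstrom).
#' @slot edge Cubic edge length (Angstrom).
#' @slot ratio Dimensionless multiplier applied to the radius of gyration.
#' @exportClass Box
setClass("Box",
         representation(center = "numeric", edge = "numeric",
                        ratio = "numeric"),
         validity = function(object) {
           if (length(object@center) != 3L) return("center must be length 3")
           if (object@edge <= 0) return("edge must be positive")
           TRUE
         })

#' Set of externally docked ligand poses
#'
#' Poses are produced by a third-party docking engine and ingested as
#' ligand-only PDB files; the engine name and settings are recorded as
#' metadata only.
#'
#' @slot poses List of [Ligand-class] conformers, best score first.
#' @slot scores Numeric engine scores aligned with \code{poses} (lower is
#'   better, the usual binding-affinity convention); may be \code{NA}.
#' @slot engine_meta Free-text engine provenance.
#' @exportClass PoseSet
setClass("PoseSet",
         representation(poses = "list", scores = "numeric",
                        engine_meta = "character"),
         validity = function(object) {
           if (length(object@poses) < 1L) return("at least one pose required")
           if (length(object@scores) != length(object@poses))
             return("scores must align with poses")
           s <- object@scores[!is.na(object@scores)]
           if (length(s) > 1L && is.unsorted(s))
             return("poses must be ordered best score first")
           TRUE
         })

#' Ligand-contact profile of a structure
#'
#' One record per protein residue with at least one heavy atom within the
#' distance cutoff of a heavy ligand atom.
#'
#' @slot records data.frame with columns \code{chain}, \code{resno},
#'   \code{icode}, \code{resname}, \code{min_dist}, \code{via}
#'   (\code{"mainchain"}, \code{"sidechain"} or \code{"both"}),
#'   \code{ligand_part} (comma-joined ligand atom names within the cutoff)
#'   and optionally \code{frequency} for pose-ensemble profiles.
#' @slot cutoff Heavy-atom distance cutoff (Angstrom).
#' @slot source Structure or pose-set identifier.
#' @exportClass ContactProfile
setClass("ContactProfile",
         representation(records = "data.frame", cutoff = "numeric",
                        source = "character"),
         validity = function(object) {
           req <- c("chain", "resno", "icode", "resname", "min_dist", "via")
           if (!all(req %in% names(object@records)))
             return(paste("records must have columns:",
                          paste(req, collapse = ", ")))
           r <- object@records
           if (nrow(r)) {
             if (any(r$min_dist > object@cutoff + 1e-9))
               return("min_dist must not exceed the cutoff")
             if ("frequency" %in% names(r) &&
                 any(r$frequency < 0 | r$frequency > 1))
               return("frequencies must lie in [0, 1]")
           }
           TRUE
         })

#' Per-column conservation of a multiple sequence alignment
#'
#' The score is the modal-residue fraction: the count of the most common
#' non-gap residue divided by the number of non-gap rows. Columns with gap
#' fraction above the masking threshold are scored 0.
#'
#' @slot scores Numeric vector in [0, 1], one per alignment column.
#' @slot gap_fraction Per-column fraction of gap characters.
#' @slot metric Name of the conservation metric.
#' @exportClass ConservationProfile
setClass("ConservationProfile",
         representation(scores = "numeric", gap_fraction = "numeric",
                        metric = "character"),
         validity = function(object) {
           if (length(object@scores) != length(object@gap_fraction))
             return("scores and gap_fraction must have equal length")
           if (length(object@scores) &&
               (min(object@scores) < 0 || max(object@scores) > 1))
             return("scores must lie in [0, 1]")
           TRUE
         })

#' Alignment column to reference residue-number map
#'
#' @slot reference_id Row id of the reference sequence in the alignment.
#' @slot col_to_refpos Integer vector, one entry per column; \code{NA} for
#'   columns where the reference row has a gap.
#' @exportClass ColumnMap
setClass("ColumnMap",
         representation(reference_id = "character",
                        col_to_refpos = "integer"),
         validity = function(object) {
           v <- object@col_to_refpos[!is.na(object@col_to_refpos)]
           if (length(v) > 1L && any(diff(v) <= 0))
             return("mapped reference positions must be strictly increasing")
           TRUE
         })

#' Spaced sequence signature
#'
#' An ordered series of short motif elements (e.g. \code{"GxxW"}) separated
#' by bounded gaps. Each element pattern is over the 20 amino-acid letters
#' plus the wildcard \code{x}, and starts and ends with a specific residue.
#'
#' @slot elements data.frame with columns \code{pattern} and \code{ref_start}
#'   (reference residue number of the first pattern position; \code{NA} when
#'   the signature was parsed from text without provenance).
#' @slot gap_min,gap_max Integer vectors of length \code{nrow(elements) - 1}:
#'   allowed residue separations between the end of one element and the
#'   start of the next.
#' @slot region Length-2 numeric, reference region spanned (or \code{NA}).
#' @seealso [deriveSignature()], [matchSignature()], [signatureToText()]
#' @exportClass Signature
setClass("Signature",
         representation(elements = "data.frame", gap_min = "integer",
                        gap_max = "integer", region = "numeric"),
         validity = function(object) {
           el <- object@elements
           if (!all(c("pattern", "ref_start") %in% names(el)))
             return("elements must have columns pattern, ref_start")
           if (nrow(el) == 0L) return("signature must have >= 1 element")
           bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY][ACDEFGHIKLMNPQRSTVWYx]*$",
                         el$pattern) |
                  grepl("x$", el$pattern)
           if (any(bad))
             return(paste0("element patterns must start and end with a ",
                           "specific residue: ",
                           paste(el$pattern[bad], collapse = ", ")))
           if (length(object@gap_min) != nrow(el) - 1L ||
               length(object@gap_max) != nrow(el) - 1L)
             return("gap ranges must have one entry per adjacent pair")
           if (any(object@gap_min < 0L, na.rm = TRUE))
             return("gap minima must be non-negative")
           if (any(object@gap_max < object@gap_min, na.rm = TRUE))
             return("gap max must be >= gap min")
           rs <- el$ref_start
           if (!all(is.na(rs)) && any(diff(rs[!is.na(rs)]) <= 0))
             return("elements must be ordered by ref_start")
           TRUE
         })

#' Placement of a signature in a sequence
#'
#' @slot sequence_id Identifier of the matched sequence.
#' @slot element_starts 1-based start position of each element.
#' @slot span First and last matched positions.
#' @slot n_elements Number of elements matched (all of them for a hit).
#' @exportClass SignatureMatch
setClass("SignatureMatch",
         representation(sequence_id = "character",
                        element_starts = "integer", span = "integer",
                        n_elements = "integer"),
         validity = function(object) {
           s <- object@element_starts
           if (length(s) > 1L && any(diff(s) <= 0))
             return("element starts must be strictly increasing")
           TRUE
         })

#' Greedy identity clustering result
#'
#' @slot members data.frame with columns \code{representative},
#'   \code{member}, \code{identity} (percent identity of member to its
#'   representative; 100 for the representative itself).
#' @slot threshold Identity fraction used for cluster membership.
#' @exportClass ClusterSet
setClass("ClusterSet",
         representation(members = "data.frame", threshold = "numeric"),
         validity = function(object) {
           req <- c("representative", "member", "identity")
           if (!all(req %in% names(object@members)))
             return("members must have representative, member, identity")
           if (anyDuplicated(object@members$member))
             return("clusters must partition the input (duplicate member)")
           TRUE
         })

#' Sequence similarity network
#'
#' Undirected graph whose nodes are sequences (typically cluster
#' representatives) and whose edges connect pairs at or above the identity
#' threshold, weighted by percent identity.
#'
#' @slot graph An \pkg{igraph} graph with vertex attribute \code{length} and
#'   edge attribute \code{identity}.
#' @slot threshold Minimum percent identity retained as an edge.
#' @slot metric Name of the similarity metric stamped into exports.
#' @exportClass SSNGraph
setClass("SSNGraph",
         representation(graph = "ANY", threshold = "numeric",
                        metric = "character"),
         validity = function(object) {
           if (!igraph::is_igraph(object@graph))
             return("graph must be an igraph object")
           if (igraph::any_loop(object@graph)) return("no self-edges allowed")
           w <- igraph::E(object@graph)$identity
           if (length(w) && any(w < object@threshold - 1e-9))
             return("all edge weights must be >= threshold")
           TRUE
         })

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat("PDBStructure", object@id, "\n")
  cat(" ", nrow(a), "atoms;", sum(!a$hetero), "polymer,",
      sum(a$hetero), "hetero;",
      length(unique(a$chain[!a$hetero])), "chain(s)\n")
  het <- unique(a$resname[a$hetero & !a$resname %in% .WATER_CODES])
  if (length(het)) cat("  het codes:", paste(het, collapse = ", "), "\n")
})

setMethod("show", "Ligand", function(object) {
  cat("Ligand", object@code, "from", object@source, "—",
      nrow(object@atoms), "atoms\n")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd %.4f Å over %d pairs\n",
              object@rmsd, object@n_pairs))
})

setMethod("show", "Box", function(object) {
  cat(sprintf("Box: center (%.3f, %.3f, %.3f), edge %.3f Å (ratio %.2f)\n",
              object@center[1], object@center[2], object@center[3],
              object@edge, object@ratio))
})

setMethod("show", "ContactProfile", function(object) {
  cat(sprintf("ContactProfile (%s): %d contact residue(s) at %.1f Å cutoff\n",
              object@source, nrow(object@records), object@cutoff))
})

setMethod("show", "Signature", function(object) {
  cat("Signature:", signatureToText(object), "\n")
  if (!any(is.na(object@region)))
    cat("  reference region:", object@region[1], "-", object@region[2], "\n")
})

setMethod("show", "SSNGraph", function(object) {
  cat(sprintf("SSNGraph: %d nodes, %d edges (>= %.1f%% %s)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              object@threshold, object@metric))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d sequences in %d clusters (threshold %.2f)\n",
              nrow(object@members),
              length(unique(object@members$representative)),
              object@threshold))
})
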