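#' Accessors for cofsig S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x An object of the documented class.
#' @return \code{atomTable}: the atom data.frame; \code{structureId} /
#'   \code{ligandCode}: character scalars; \code{contactRecords},
#'   \code{signatureElements}, \code{clusterMembers}: data.frames;
#'   \code{conservationScores}, \code{gapFraction}: numeric vectors;
#'   \code{columnMap}: integer vector (NA at reference-gap columns);
#'   \code{ssnGraph}: the underlying igraph object.
#' @examples
#' toy <- generateToyComplex(seed = 1)
#' nrow(atomTable(toy$structure))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "PDBStructure", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomTable", "Ligand", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setMethod("structureId", "PDBStructure", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("ligandCode", function(x) standardGeneric("ligandCode"))
#' @rdname accessors
#' @export
setMethod("ligandCode", "Ligand", function(x) x@code)

#' @rdname accessors
#' @export
setGeneric("contactRecords", function(x) standardGeneric("contactRecords"))
#' @rdname accessors
#' @export
setMethod("contactRecords", "ContactProfile", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("conservationScores",
           function(x) standardGeneric("conservationScores"))
#' @rdname accessors
#' @export
setMethod("conservationScores", "ConservationProfile", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("gapFraction", function(x) standardGeneric("gapFraction"))
#' @rdname accessors
#' @export
setMethod("gapFraction", "ConservationProfile", function(x) x@gap_fraction)

#' @rdname accessors
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @rdname accessors
#' @export
setMethod("columnMap", "ColumnMap", function(x) x@col_to_refpos)

#' @rdname accessors
#' @export
setGeneric("signatureElements",
           function(x) standardGeneric("signatureElements"))
#' @rdname accessors
#' @export
setMethod("signatureElements", "Signature", function(x) x@elements)

#' @rdname accessors
#' @export
setGeneric("gapRanges", function(x) standardGeneric("gapRanges"))
#' @rdname accessors
#' @export
setMethod("gapRanges", "Signature", function(x)
  data.frame(min = x@gap_min, max = x@gap_max))

#' @rdname accessors
#' @export
setGeneric("elementStarts", function(x) standardGeneric("elementStarts"))
#' @rdname accessors
#' @export
setMethod("elementStarts", "SignatureMatch", function(x) x@element_starts)

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("ssnGraph", function(x) standardGeneric("ssnGraph"))
#' @rdname accessors
#' @export
setMethod("ssnGraph", "SSNGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("poseLigands", function(x) standardGeneric("poseLigands"))
#' @rdname accessors
#' @export
setMethod("poseLigands", "PoseSet", function(x) x@poses)

#' @rdname accessors
#' @export
setGeneric("poseScores", function(x) standardGeneric("poseScores"))
#' @rdname accessors
#' @export
setMethod("poseScores", "PoseSet", function(x) x@scores)
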