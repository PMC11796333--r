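## Pairwise global alignment, MSA handling, per-column conservation and the
## alignment-column to reference-position map. Alignment optimisation is
## delegated to Biostrings (Needleman-Wunsch, affine gaps); multiple
## sequence alignment construction is deliberately out of scope — the
## package consumes pre-aligned FASTA.

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X")

.check_protein <- function(seqs) {
  seqs <- toupper(as.character(seqs))
  for (s in seqs) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    ch <- unique(strsplit(s, "")[[1]])
    bad <- setdiff(ch, .AA_ALPHABET)
    if (length(bad))
      stop("illegal sequence character(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  seqs
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- as.matrix(get(utils::data("BLOSUM62",
                                          package = "Biostrings",
                                          envir = environment())))
    cache
  }
})

## Core pairwise global alignment; returns aligned strings + score.
.align_core <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  mat <- if (is.matrix(substitutionMatrix)) substitutionMatrix
         else .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

.identity_from_aligned <- function(ga, gb) {
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  cols <- !(ca == "-" & cb == "-")         # exclude dual-gap columns
  100 * sum(ca == cb & ca != "-" & cols) / sum(cols)
}

#' Global pairwise alignment of two protein sequences
#'
#' Optimal Needleman-Wunsch alignment under BLOSUM62 with affine gap
#' penalties (a gap of length k costs \code{gapOpening} +
#' k * \code{gapExtension}; terminal gaps are penalised). The percent
#' identity uses a single fixed definition: identical aligned pairs divided
#' by alignment columns, excluding columns that are gaps in both rows.
#'
#' @param a,b Protein sequences over the 20 amino-acid letters plus X.
#' @param substitutionMatrix Scoring matrix name or matrix
#'   (default BLOSUM62).
#' @param gapOpening,gapExtension Affine gap costs (defaults 10 and 0.5).
#' @return A list of class \code{"AlignmentResult"}: \code{aligned_a},
#'   \code{aligned_b} (gapped strings), \code{score}, \code{identity_pct},
#'   and a \code{params} echo for reproducibility.
#' @examples
#' globalAlign("ACDEFGHIK", "ACDEFGIK")$identity_pct
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  seqs <- .check_protein(c(a, b))
  al <- .align_core(seqs[1], seqs[2], substitutionMatrix,
                    gapOpening, gapExtension)
  structure(list(
    aligned_a = al$aligned_a, aligned_b = al$aligned_b, score = al$score,
    identity_pct = .identity_from_aligned(al$aligned_a, al$aligned_b),
    params = list(matrix = if (is.matrix(substitutionMatrix)) "custom"
                           else substitutionMatrix,
                  gapOpening = gapOpening, gapExtension = gapExtension)),
    class = "AlignmentResult")
}

#' Percent identity between two sequences
#'
#' @inheritParams globalAlign
#' @return Percentage in [0, 100]; identical sequences give 100.
#' @export
percentIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                            gapOpening = 10, gapExtension = 0.5) {
  globalAlign(a, b, substitutionMatrix, gapOpening,
              gapExtension)$identity_pct
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Aligned FASTA file: equal-length gapped rows with unique
#'   ids.
#' @return An [Biostrings::AAStringSet] of equal-width gapped rows.
#' @export
readMSA <- function(path) {
  msa <- Biostrings::readAAStringSet(path)
  validateMSA(msa)
  msa
}

#' Validate an alignment object
#'
#' @param msa An \code{AAStringSet} (or named character vector) of gapped
#'   rows.
#' @return The alignment as an \code{AAStringSet}, invisibly erroring on
#'   ragged rows or duplicate ids.
#' @export
validateMSA <- function(msa) {
  if (is.character(msa))
    msa <- Biostrings::AAStringSet(msa)
  w <- Biostrings::width(msa)
  if (length(w) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(w)) != 1L) {
    bad <- names(msa)[w != w[1]][1]
    stop("ragged alignment: row '", bad, "' has width ", w[w != w[1]][1],
         ", expected ", w[1], call. = FALSE)
  }
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("alignment rows must have unique ids", call. = FALSE)
  msa
}

#' Write an alignment to FASTA
#'
#' @param msa An \code{AAStringSet}.
#' @param path Output path.
#' @export
writeMSA <- function(msa, path) {
  Biostrings::writeXStringSet(validateMSA(msa), path)
  invisible(path)
}

## Character matrix view of an alignment (rows x columns).
.msa_matrix <- function(msa) {
  msa <- validateMSA(msa)
  do.call(rbind, strsplit(toupper(as.character(msa)), ""))
}

#' Per-column conservation of an alignment
#'
#' The conservation score of a column is the modal-residue fraction: the
#' count of the most common non-gap residue divided by the number of
#' non-gap rows in that column. Columns whose gap fraction exceeds
#' \code{gap_mask} are masked to score 0 (they are dominated by indels,
#' not substitution signal).
#'
#' @param msa An \code{AAStringSet} alignment with at least two rows.
#' @param gap_mask Gap-fraction threshold above which a column scores 0
#'   (default 0.5).
#' @return A [ConservationProfile-class].
#' @export
columnConservation <- function(msa, gap_mask = 0.5) {
  M <- .msa_matrix(msa)
  if (nrow(M) < 2L)
    stop("conservation requires at least two alignment rows", call. = FALSE)
  gap <- M == "-" | M == "."
  gap_fraction <- colMeans(gap)
  scores <- vapply(seq_len(ncol(M)), function(j) {
    col <- M[!gap[, j], j]
    if (!length(col)) return(0)
    max(table(col)) / length(col)
  }, numeric(1))
  scores[gap_fraction > gap_mask] <- 0
  new("ConservationProfile", scores = scores, gap_fraction = gap_fraction,
      metric = "modal_fraction")
}

#' Map alignment columns to reference residue numbers
#'
#' The k-th non-gap column of the reference row maps to
#' \code{start_number + k - 1}; columns where the reference row has a gap
#' are unmapped (NA). Author numbering of the reference sequence is the
#' canonical coordinate system for signatures.
#'
#' @param msa An \code{AAStringSet} alignment.
#' @param reference_id Row id of the reference sequence.
#' @param start_number Author residue number of the reference's first
#'   residue (default 1).
#' @return A [ColumnMap-class].
#' @export
mapColumns <- function(msa, reference_id, start_number = 1L) {
  msa <- validateMSA(msa)
  if (!reference_id %in% names(msa))
    stop("reference id '", reference_id, "' not present in alignment",
         call. = FALSE)
  ref <- strsplit(toupper(as.character(msa[[reference_id]])), "")[[1]]
  nongap <- !(ref == "-" | ref == ".")
  map <- rep(NA_integer_, length(ref))
  map[nongap] <- as.integer(start_number) + seq_len(sum(nongap)) - 1L
  new("ColumnMap", reference_id = reference_id, col_to_refpos = map)
}
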