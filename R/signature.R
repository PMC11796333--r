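## The core artifact: a spaced signature motif derived from the
## intersection of ligand-contact residues and alignment conservation,
## compiled into a deterministic scanner for database mining.

#' Derive a spaced signature from contacts and conservation
#'
#' The anchor set is the intersection of ligand-contact residues (in
#' reference author numbering) with alignment columns conserved at or above
#' \code{tau}. Anchors whose reference separation is at most
#' \code{merge_gap} are merged into one element, with intervening positions
#' rendered as the wildcard \code{x} (so contacts at 128 and 131 with two
#' unconstrained residues between become \code{GxxW}-shaped); isolated
#' anchors become length-1 elements. Allowed separations between adjacent
#' elements are the reference separations widened by
#' \code{gap_tolerance} (default 25\%, rounded, at least 1 residue),
#' because homologs mined at family scale do not keep exact spacing.
#'
#' @param contacts A [ContactProfile-class] whose residue numbers are in
#'   reference numbering.
#' @param cons A [ConservationProfile-class] over the family alignment.
#' @param cmap A [ColumnMap-class] anchoring alignment columns to reference
#'   numbering; it must cover every contact position.
#' @param tau Conservation threshold in [0, 1] for calling a contact
#'   conserved (default 0.8).
#' @param merge_gap Maximum anchor separation merged into one element
#'   (default 4, so a G...P pair four residues apart forms one
#'   \code{GxxxP}-shaped element).
#' @param gap_tolerance Fractional widening of inter-element separations
#'   (default 0.25).
#' @return A [Signature-class].
#' @examples
#' fam <- generateFamily(n_positive = 10, n_decoy = 0, seed = 1)
#' fam$signature
#' @export
deriveSignature <- function(contacts, cons, cmap, tau = 0.8, merge_gap = 4L,
                            gap_tolerance = 0.25) {
  stopifnot(is(contacts, "ContactProfile"), is(cons, "ConservationProfile"),
            is(cmap, "ColumnMap"))
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]", call. = FALSE)
  rec <- contacts@records
  if (!nrow(rec)) stop("contact profile is empty", call. = FALSE)
  ## one row per reference position
  rec <- rec[!duplicated(rec$resno), , drop = FALSE]
  map <- cmap@col_to_refpos
  col_of <- match(rec$resno, map)
  if (anyNA(col_of))
    stop("column map does not cover contact position(s): ",
         paste(rec$resno[is.na(col_of)], collapse = ", "), call. = FALSE)
  conserved <- cons@scores[col_of] >= tau
  anchors <- sort(rec$resno[conserved])
  if (!length(anchors))
    stop("no conserved contact residues at tau = ", tau, call. = FALSE)
  letters1 <- suppressWarnings(bio3d::aa321(rec$resname))
  letters1[is.na(letters1) | !nzchar(letters1)] <- "X"
  letter_of <- stats::setNames(letters1, rec$resno)

  ## merge anchors into elements
  runs <- split(anchors, cumsum(c(1, diff(anchors) > merge_gap)))
  patterns <- vapply(runs, function(pos) {
    span <- seq(min(pos), max(pos))
    ch <- rep("x", length(span))
    ch[span %in% pos] <- letter_of[as.character(span[span %in% pos])]
    paste(ch, collapse = "")
  }, character(1))
  ref_start <- vapply(runs, min, numeric(1))
  ref_end <- vapply(runs, max, numeric(1))

  n <- length(runs)
  gmin <- gmax <- integer(max(n - 1L, 0L))
  if (n > 1L) for (i in seq_len(n - 1L)) {
    sep <- ref_start[i + 1L] - ref_end[i] - 1L
    tol <- max(1L, as.integer(round(gap_tolerance * sep)))
    gmin[i] <- max(0L, as.integer(sep) - tol)
    gmax[i] <- as.integer(sep) + tol
  }
  new("Signature",
      elements = data.frame(pattern = unname(patterns),
                            ref_start = as.integer(unname(ref_start)),
                            stringsAsFactors = FALSE),
      gap_min = gmin, gap_max = gmax,
      region = c(min(anchors), max(anchors)))
}

## All 1-based start positions where a fixed-length wildcard pattern occurs.
.element_hits <- function(chars, pattern) {
  pc <- strsplit(pattern, "")[[1]]
  L <- length(pc); n <- length(chars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    if (pc[j] == "x") next
    ok <- ok & chars[seq.int(j, j + n - L)] == pc[j]
  }
  which(ok)
}

## Lexicographically smallest feasible placement of elements (ordered, with
## per-pair separation windows), by depth-first search with failure
## memoisation.
.place_elements <- function(hit_list, lens, gmin, gmax) {
  k <- length(hit_list)
  failed <- new.env(hash = TRUE, parent = emptyenv())
  search <- function(i, prev_end) {
    key <- paste0(i, ":", prev_end)
    if (!is.null(failed[[key]])) return(NULL)
    cand <- hit_list[[i]]
    if (i > 1L)
      cand <- cand[cand >= prev_end + 1L + gmin[i - 1L] &
                   cand <= prev_end + 1L + gmax[i - 1L]]
    for (st in cand) {
      if (i == k) return(st)
      rest <- search(i + 1L, st + lens[i] - 1L)
      if (!is.null(rest)) return(c(st, rest))
    }
    failed[[key]] <- TRUE
    NULL
  }
  search(1L, 0L)
}

#' Match a spaced signature against a sequence
#'
#' A sequence matches when every element occurs, in order, with
#' inter-element separations inside the signature's gap ranges. Specific
#' letters must match exactly; \code{x} matches any residue. Among multiple
#' placements, the leftmost-then-tightest one (lexicographically smallest
#' vector of element starts) is reported, making the scan deterministic.
#'
#' @param seq An ungapped protein sequence (character scalar).
#' @param sig A [Signature-class].
#' @param sequence_id Identifier recorded in the match.
#' @param min_elements Minimum number of elements required (in order, with
#'   combined gap windows across skipped elements). Defaults to all
#'   elements: a hit is binary, no partial-credit scoring.
#' @return A [SignatureMatch-class], or \code{NULL} when the signature is
#'   absent (a valid result, not an error).
#' @examples
#' sig <- parseSignature("GxxW{8,12}EH")
#' matchSignature("AAGAAWAAAAAAAAAEHAA", sig)
#' @export
matchSignature <- function(seq, sig, sequence_id = "query",
                           min_elements = NULL) {
  stopifnot(is(sig, "Signature"))
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "")[[1]]
  pats <- sig@elements$pattern
  lens <- nchar(pats)
  n <- length(pats)
  if (is.null(min_elements)) min_elements <- n
  min_elements <- max(1L, min(as.integer(min_elements), n))

  try_subset <- function(keep) {
    hit_list <- lapply(pats[keep], function(p) .element_hits(chars, p))
    if (any(!lengths(hit_list))) return(NULL)
    ## combined separation windows across skipped elements
    if (length(keep) > 1L) {
      gmin <- gmax <- integer(length(keep) - 1L)
      for (j in seq_len(length(keep) - 1L)) {
        lo <- keep[j]; hi <- keep[j + 1L]
        idx <- seq(lo, hi - 1L)                # gap slots lo..hi-1
        gmin[j] <- sum(sig@gap_min[idx])
        gmax[j] <- sum(sig@gap_max[idx])
        if (hi - lo > 1L) {
          skipped <- seq(lo + 1L, hi - 1L)
          gmin[j] <- gmin[j] + sum(lens[skipped])
          gmax[j] <- gmax[j] + sum(lens[skipped])
        }
      }
    } else gmin <- gmax <- integer(0)
    st <- .place_elements(hit_list, lens[keep], gmin, gmax)
    if (is.null(st)) return(NULL)
    list(keep = keep, starts = st)
  }

  result <- NULL
  for (size in seq(n, min_elements)) {
    if (size == n) {
      result <- try_subset(seq_len(n))
    } else {
      subsets <- utils::combn(n, size, simplify = FALSE)
      for (keep in subsets) {
        result <- try_subset(keep)
        if (!is.null(result)) break
      }
    }
    if (!is.null(result)) break
  }
  if (is.null(result)) return(NULL)
  st <- as.integer(result$starts)
  ends <- st + lens[result$keep] - 1L
  new("SignatureMatch", sequence_id = sequence_id, element_starts = st,
      span = c(st[1], ends[length(ends)]),
      n_elements = length(st))
}

#' Render a signature in canonical text form
#'
#' Elements joined by their gap ranges, e.g.
#' \code{"GxxW\{8,12\}EH\{30,40\}GxxH\{45,52\}GxxxP"}.
#'
#' @param sig A [Signature-class].
#' @return Character scalar.
#' @export
signatureToText <- function(sig) {
  stopifnot(is(sig, "Signature"))
  pats <- sig@elements$pattern
  if (length(pats) == 1L) return(pats)
  paste0(paste0(pats[-length(pats)],
                sprintf("{%d,%d}", sig@gap_min, sig@gap_max),
                collapse = ""),
         pats[length(pats)])
}

#' Parse a signature from canonical text form
#'
#' @param text Signature text, e.g. \code{"GxxW\{8,12\}EH"}. Element
#'   patterns must start and end with a specific residue letter.
#' @return A [Signature-class] (without reference anchoring; \code{ref_start}
#'   is NA unless restored from a sidecar by [readSignature()]).
#' @export
parseSignature <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) stop("empty signature text", call. = FALSE)
  pats <- character(0); gmin <- gmax <- integer(0)
  pos <- 1L; n <- nchar(text)
  repeat {
    rest <- substring(text, pos)
    m <- regexpr("^[A-Zx]+", rest)
    if (m == -1L)
      stop("signature parse error at position ", pos,
           ": expected an element pattern", call. = FALSE)
    pat <- regmatches(rest, m)
    if (grepl("^x|x$", pat))
      stop("signature parse error at position ", pos, ": element '", pat,
           "' must start and end with a specific residue", call. = FALSE)
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWYx]+$", pat))
      stop("signature parse error at position ", pos,
           ": illegal letter in element '", pat, "'", call. = FALSE)
    pats <- c(pats, pat)
    pos <- pos + attr(m, "match.length")
    if (pos > n) break
    rest <- substring(text, pos)
    g <- regexpr("^\\{([0-9]+),([0-9]+)\\}", rest)
    if (g == -1L)
      stop("signature parse error at position ", pos,
           ": expected gap range {min,max}", call. = FALSE)
    nums <- as.integer(strsplit(gsub("[{}]", "", regmatches(rest, g)),
                                ",")[[1]])
    if (nums[2] < nums[1])
      stop("signature parse error at position ", pos,
           ": gap max below gap min", call. = FALSE)
    gmin <- c(gmin, nums[1]); gmax <- c(gmax, nums[2])
    pos <- pos + attr(g, "match.length")
    if (pos > n)
      stop("signature parse error at position ", pos,
           ": trailing gap range without a following element",
           call. = FALSE)
  }
  new("Signature",
      elements = data.frame(pattern = pats,
                            ref_start = rep(NA_integer_, length(pats)),
                            stringsAsFactors = FALSE),
      gap_min = gmin, gap_max = gmax,
      region = c(NA_real_, NA_real_))
}

#' Write a signature file (text plus JSON sidecar)
#'
#' The file holds the single-line canonical text; a \code{.json} sidecar
#' next to it records elements, gap ranges, reference region and
#' derivation provenance.
#'
#' @param sig A [Signature-class].
#' @param path Output file path.
#' @param provenance Optional named list (e.g. tau, contact cutoff,
#'   structure id) stored in the sidecar.
#' @export
writeSignature <- function(sig, path, provenance = list()) {
  writeLines(signatureToText(sig), path)
  side <- list(elements = sig@elements, gap_min = sig@gap_min,
               gap_max = sig@gap_max, region = sig@region,
               provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a signature file
#'
#' @param path Path written by [writeSignature()] (the sidecar, when
#'   present, restores reference anchoring).
#' @return A [Signature-class].
#' @export
readSignature <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signature file: ", path, call. = FALSE)
  sig <- parseSignature(lines[1])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$elements$ref_start) &&
        length(side$elements$ref_start) == nrow(sig@elements))
      sig@elements$ref_start <- as.integer(side$elements$ref_start)
    if (!is.null(side$region) && length(side$region) == 2L)
      sig@region <- as.numeric(side$region)
  }
  sig
}
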