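## Database mining: signature scan of a FASTA stream, greedy identity
## clustering of the hits, and sequence-similarity-network construction and
## export.

#' Scan a sequence database for a signature
#'
#' Streams a protein FASTA database in chunks (constant memory in database
#' size) and reports exactly the sequences for which [matchSignature()]
#' finds a placement, preserving input order.
#'
#' @param db Path to a FASTA file, or an \code{AAStringSet} / named
#'   character vector.
#' @param sig A [Signature-class].
#' @param min_elements Passed to [matchSignature()].
#' @param chunk_size Records per streaming chunk when \code{db} is a file
#'   (default 500).
#' @return data.frame (hit table) with columns \code{sequence_id},
#'   \code{element_starts} (comma-joined), \code{span_start},
#'   \code{span_end}, \code{length}.
#' @export
scanDatabase <- function(db, sig, min_elements = NULL, chunk_size = 500L) {
  stopifnot(is(sig, "Signature"))
  scan_set <- function(seqs, ids) {
    rows <- list()
    for (i in seq_along(seqs)) {
      m <- matchSignature(seqs[i], sig, sequence_id = ids[i],
                          min_elements = min_elements)
      if (!is.null(m))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = ids[i],
          element_starts = paste(m@element_starts, collapse = ","),
          span_start = m@span[1], span_end = m@span[2],
          length = nchar(seqs[i]), stringsAsFactors = FALSE)
    }
    rows
  }
  rows <- list()
  if (is.character(db) && length(db) == 1L && file.exists(db) &&
      is.null(names(db))) {
    skip <- 0L
    repeat {
      chunk <- Biostrings::readAAStringSet(db, nrec = chunk_size,
                                           skip = skip)
      if (!length(chunk)) break
      ids <- sub("\\s.*$", "", names(chunk))
      rows <- c(rows, scan_set(as.character(chunk), ids))
      skip <- skip + length(chunk)
      if (length(chunk) < chunk_size) break
    }
    if (skip == 0L) warning("empty database: ", db, call. = FALSE)
  } else {
    seqs <- if (is(db, "XStringSet"))
      stats::setNames(as.character(db), sub("\\s.*$", "", names(db)))
    else stats::setNames(as.character(db), names(db))
    if (!length(seqs)) warning("empty database", call. = FALSE)
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    rows <- scan_set(seqs, ids)
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(),
                      element_starts = character(),
                      span_start = integer(), span_end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$sequence_id))
    stop("duplicate sequence ids in database", call. = FALSE)
  rownames(out) <- NULL
  out
}

## Coerce a sequence input (path / AAStringSet / named character) to a
## named character vector.
.as_seq_vector <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs)) &&
      file.exists(seqs))
    seqs <- Biostrings::readAAStringSet(seqs)
  if (is(seqs, "XStringSet")) {
    v <- as.character(seqs)
    names(v) <- sub("\\s.*$", "", names(seqs))
    return(v)
  }
  stats::setNames(as.character(seqs), names(seqs))
}

#' Greedy identity clustering
#'
#' CD-HIT-style incremental clustering: sequences are sorted by length
#' (descending), ties by id; the first unassigned sequence founds a
#' cluster, and each subsequent sequence joins the first existing
#' representative to which its percent identity is at or above the
#' threshold, otherwise founds a new cluster. Identities use exact global
#' alignment (no k-mer prescreen), which is adequate at desk scale.
#'
#' @param seqs FASTA path, \code{AAStringSet} or named character vector.
#' @param threshold Identity fraction in (0, 1]; default 0.8 (the family
#'   mining convention of clustering at 80\% identity).
#' @return A [ClusterSet-class].
#' @export
greedyCluster <- function(seqs, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  v <- .as_seq_vector(seqs)
  if (!length(v)) stop("empty input", call. = FALSE)
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop("sequences must have unique ids", call. = FALSE)
  ord <- order(-nchar(v), names(v))
  v <- v[ord]
  reps <- character(0)
  rows <- vector("list", length(v))
  for (i in seq_along(v)) {
    assigned <- FALSE
    for (r in reps) {
      pid <- percentIdentity(v[[i]], v[[r]])
      if (pid >= 100 * threshold) {
        rows[[i]] <- data.frame(representative = r, member = names(v)[i],
                                identity = pid, stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, names(v)[i])
      rows[[i]] <- data.frame(representative = names(v)[i],
                              member = names(v)[i], identity = 100,
                              stringsAsFactors = FALSE)
    }
  }
  new("ClusterSet", members = do.call(rbind, rows), threshold = threshold)
}

#' Build a sequence similarity network
#'
#' All-pairs percent identity among the input sequences (typically cluster
#' representatives); an undirected edge is retained when the identity is
#' at or above \code{min_identity}. Node annotations (e.g. predicted
#' functional domains) pass through from a user table.
#'
#' @param reps FASTA path, \code{AAStringSet} or named character vector
#'   with at least two sequences and unique ids.
#' @param min_identity Minimum percent identity kept as an edge
#'   (default 40).
#' @param annotations Optional data.frame with an \code{id} column; other
#'   columns become node attributes.
#' @return An [SSNGraph-class].
#' @export
buildSSN <- function(reps, min_identity = 40, annotations = NULL) {
  v <- .as_seq_vector(reps)
  if (length(v) < 2L) stop("at least two sequences required", call. = FALSE)
  if (is.null(names(v)) || anyDuplicated(names(v)))
    stop("duplicate or missing sequence ids", call. = FALSE)
  ids <- names(v)
  edges <- list()
  for (i in seq_len(length(v) - 1L)) for (j in seq(i + 1L, length(v))) {
    pid <- percentIdentity(v[[i]], v[[j]])
    if (pid >= min_identity)
      edges[[length(edges) + 1L]] <- data.frame(
        from = ids[i], to = ids[j], identity = pid,
        stringsAsFactors = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            length = nchar(v))
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    g <- igraph::add_edges(g, rbind(match(ed$from, ids),
                                    match(ed$to, ids)),
                           identity = ed$identity)
  }
  if (!is.null(annotations)) {
    if (!"id" %in% names(annotations))
      stop("annotations need an 'id' column", call. = FALSE)
    idx <- match(ids, annotations$id)
    for (col in setdiff(names(annotations), "id"))
      g <- igraph::set_vertex_attr(g, col, value = annotations[[col]][idx])
  }
  new("SSNGraph", graph = g, threshold = min_identity,
      metric = "global_percent_identity")
}

#' Export a sequence similarity network
#'
#' Deterministic ordering: nodes lexicographic, edges lexicographic by
#' (source, target) with source < target.
#'
#' @param g An [SSNGraph-class].
#' @param path Output file.
#' @param format \code{"tsv"} (edge-list with a \code{# metric} header
#'   comment and a node section file \code{<path>.nodes.tsv}) or
#'   \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
exportGraph <- function(g, path, format = c("tsv", "graphml")) {
  stopifnot(is(g, "SSNGraph"))
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown graph format: ", format[1],
                            call. = FALSE))
  gr <- g@graph
  if (format == "graphml") {
    igraph::write_graph(gr, path, format = "graphml")
    return(invisible(path))
  }
  ids <- igraph::V(gr)$name
  el <- igraph::as_edgelist(gr)
  lines <- c(sprintf("# metric=%s min_identity=%g", g@metric, g@threshold),
             "source\ttarget\tidentity_pct")
  if (nrow(el)) {
    src <- pmin(el[, 1], el[, 2]); tgt <- pmax(el[, 1], el[, 2])
    w <- igraph::E(gr)$identity
    ord <- order(src, tgt)
    lines <- c(lines, sprintf("%s\t%s\t%.6g", src[ord], tgt[ord], w[ord]))
  }
  writeLines(lines, path)
  nodes <- data.frame(id = ids, length = igraph::V(gr)$length,
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  utils::write.table(nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import an edge-list TSV written by [exportGraph()]
#'
#' @param path Edge-list TSV path.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{identity_pct}.
#' @export
importGraphTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
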