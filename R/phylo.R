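## Distance-based tree construction and the "same branch as the reference"
## photoreceptor-candidate classification. Maximum-likelihood trees from
## external tools are ingested as newick via loadTree(); the in-package
## route uses p-distances and neighbor joining.

#' Pairwise p-distance matrix from an alignment
#'
#' Mismatch fraction over the columns where both rows are non-gap, with an
#' optional Poisson correction \code{-ln(1 - p)} for multiple
#' substitutions.
#'
#' @param msa An \code{AAStringSet} alignment with at least three rows.
#' @param correction \code{"none"} (default) or \code{"poisson"}.
#' @return Symmetric numeric matrix with row/column names = sequence ids.
#' @export
pDistanceMatrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  M <- .msa_matrix(msa)
  if (nrow(M) < 3L) stop("at least three sequences required", call. = FALSE)
  ids <- names(validateMSA(msa))
  gap <- M == "-" | M == "."
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    shared <- !gap[i, ] & !gap[j, ]
    if (!any(shared))
      stop("sequences '", ids[i], "' and '", ids[j],
           "' share no aligned columns", call. = FALSE)
    p <- mean(M[i, shared] != M[j, shared])
    if (correction == "poisson") {
      if (p >= 1) stop("p-distance of 1 cannot be Poisson-corrected (pair ",
                       ids[i], ", ", ids[j], ")", call. = FALSE)
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (exact on additive matrices), with negative
#' branch lengths clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal and labelled
#'   rows/columns; at least three taxa.
#' @return An \pkg{ape} \code{phylo} tree (unrooted).
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("at least three taxa required", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Load a tree from a newick file
#'
#' @param path Newick file (e.g. the best tree exported by an external
#'   maximum-likelihood run).
#' @return An \pkg{ape} \code{phylo} tree; branch lengths and internal
#'   labels are preserved.
#' @export
loadTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parseNewick(txt)
}

#' Parse a newick string
#'
#' @param text Newick text.
#' @return An \pkg{ape} \code{phylo} tree.
#' @export
parseNewick <- function(text) {
  ## cheap structural pre-check so malformed input reports an offset
  depth <- 0L; chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error at character ", i,
             ": unbalanced ')'", call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("newick parse error: input is not a valid tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("leaf labels must be unique", call. = FALSE)
  tr
}

#' Serialize a tree to newick
#'
#' @param tree An \pkg{ape} \code{phylo} tree.
#' @param path Optional output file; when \code{NULL} the newick string is
#'   returned.
#' @export
saveTree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Patristic distances between all leaves
#'
#' @param tree An \pkg{ape} \code{phylo} tree with branch lengths.
#' @return Symmetric matrix of path-length distances.
#' @export
patristicDistances <- function(tree) {
  stats::cophenetic(tree)
}

#' Classify query leaves relative to a reference leaf
#'
#' Operationalises "same branch of the tree as the reference" in two
#' explicit ways, because tree neighbourhood alone does not define a
#' branch: (1) with \code{negatives} — the tree is rooted on the edge
#' leading to the negatives' most recent common ancestor, and a query is a
#' candidate iff the smallest clade containing both the reference and the
#' query contains no negative leaf; (2) with \code{dist_threshold} — a
#' query is a candidate iff its patristic distance to the reference is at
#' or below the threshold. The rule used is stamped into the output.
#'
#' @param tree An \pkg{ape} \code{phylo} tree.
#' @param reference_id Leaf label of the reference (always a candidate).
#' @param queries Leaf labels to classify (default: all non-reference
#'   leaves).
#' @param negatives Optional leaf labels of known non-candidates
#'   (outgroup).
#' @param dist_threshold Optional patristic distance threshold.
#' @return data.frame with columns \code{query_id}, \code{call}
#'   (\code{"photoreceptor-candidate"} or \code{"non-candidate"}),
#'   \code{evidence}, \code{rule}.
#' @export
classifyByClade <- function(tree, reference_id, queries = NULL,
                            negatives = NULL, dist_threshold = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!reference_id %in% tree$tip.label)
    stop("reference '", reference_id, "' absent from tree", call. = FALSE)
  if (is.null(queries))
    queries <- setdiff(tree$tip.label, reference_id)
  missing_q <- setdiff(queries, tree$tip.label)
  if (length(missing_q))
    stop("query leaves absent from tree: ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  if (is.null(negatives) && is.null(dist_threshold))
    stop("configuration error: provide 'negatives' or 'dist_threshold'",
         call. = FALSE)

  if (!is.null(negatives)) {
    missing_n <- setdiff(negatives, tree$tip.label)
    if (length(missing_n))
      stop("negative leaves absent from tree: ",
           paste(missing_n, collapse = ", "), call. = FALSE)
    rooted <- tryCatch({
      if (length(negatives) == 1L) {
        ape::root(tree, outgroup = negatives, resolve.root = TRUE)
      } else {
        nd <- ape::getMRCA(tree, negatives)
        root_node <- length(tree$tip.label) + 1L
        if (is.null(nd) || nd == root_node) tree
        else ape::root(tree, node = nd, resolve.root = TRUE)
      }
    }, error = function(e)
      stop("cannot root on negatives (", conditionMessage(e), ")",
           call. = FALSE))
    clade_leaves <- function(q) {
      mrca <- ape::getMRCA(rooted, c(reference_id, q))
      if (is.null(mrca)) return(rooted$tip.label)   # spans the root
      ape::extract.clade(rooted, mrca)$tip.label
    }
    calls <- vapply(queries, function(q) {
      if (q == reference_id) return(TRUE)
      !any(negatives %in% clade_leaves(q))
    }, logical(1))
    evidence <- vapply(queries, function(q) {
      if (q == reference_id) return("reference")
      leaves <- clade_leaves(q)
      paste0("clade_size=", length(leaves),
             ";negatives_in_clade=", sum(negatives %in% leaves))
    }, character(1))
    rule <- "negatives"
  } else {
    pd <- patristicDistances(tree)
    dvec <- pd[reference_id, queries]
    calls <- dvec <= dist_threshold
    evidence <- sprintf("patristic=%.6g", dvec)
    rule <- "distance"
  }
  data.frame(query_id = queries,
             call = ifelse(calls, "photoreceptor-candidate",
                           "non-candidate"),
             evidence = evidence, rule = rule,
             row.names = NULL, stringsAsFactors = FALSE)
}
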