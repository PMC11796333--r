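## Brute-force reference implementations. Deliberately slow and structured
## completely differently from the production code paths; used by the test
## suite (and the acceptance script) as independent cross-checks. Each
## refuses instances above its design size.

#' Brute-force minimum RMSD by rotation search
#'
#' Scans a dense Euler-angle grid of proper rotations (translation solved
#' by centroid matching at each step) and polishes the best grid point
#' with Nelder-Mead. Independent of the SVD-based closed form.
#'
#' @param a,b Paired n x 3 coordinate matrices, n <= 12.
#' @param grid_step Grid step in degrees (default 20).
#' @return Minimum RMSD (Angstrom).
#' @export
bruteRmsd <- function(a, b, grid_step = 20) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) > 12L) stop("bruteRmsd refuses instances above 12 points",
                          call. = FALSE)
  a0 <- sweep(a, 2L, colMeans(a)); b0 <- sweep(b, 2L, colMeans(b))
  rot_zyz <- function(ang) {
    cz1 <- cos(ang[1]); sz1 <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz2 <- cos(ang[3]); sz2 <- sin(ang[3])
    Rz1 <- matrix(c(cz1, -sz1, 0, sz1, cz1, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz2 <- matrix(c(cz2, -sz2, 0, sz2, cz2, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  cost <- function(ang) sqrt(mean(rowSums((a0 %*% rot_zyz(ang) - b0)^2)))
  step <- grid_step * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  best <- Inf; best_ang <- c(0, 0, 0)
  for (al in alphas) for (be in betas) for (ga in alphas) {
    v <- cost(c(al, be, ga))
    if (v < best) { best <- v; best_ang <- c(al, be, ga) }
  }
  op <- stats::optim(best_ang, cost, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  min(best, op$value)
}

#' Brute-force contact detection (all atom pairs, explicit loops)
#'
#' @param s A [PDBStructure-class] (<= 5000 atoms).
#' @param l A [Ligand-class].
#' @param cutoff Heavy-atom cutoff (Angstrom).
#' @return data.frame with columns \code{chain}, \code{resno},
#'   \code{icode}, \code{resname}, \code{min_dist}, sorted by chain then
#'   residue number.
#' @export
bruteContacts <- function(s, l, cutoff = 4.0) {
  if (nrow(s@atoms) > 5000L)
    stop("bruteContacts refuses instances above 5000 atoms", call. = FALSE)
  prot <- s@atoms[!s@atoms$hetero & !s@atoms$hydrogen, , drop = FALSE]
  lig <- l@atoms[!l@atoms$hydrogen, , drop = FALSE]
  found <- list()
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                (prot$z[i] - lig$z[j])^2)
      if (d <= cutoff) {
        key <- paste(prot$chain[i], prot$resno[i], prot$icode[i])
        if (is.null(found[[key]]) || d < found[[key]]$min_dist)
          found[[key]] <- data.frame(
            chain = prot$chain[i], resno = prot$resno[i],
            icode = prot$icode[i], resname = prot$resname[i],
            min_dist = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(found))
    return(data.frame(chain = character(), resno = integer(),
                      icode = character(), resname = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, found)
  out <- out[order(out$chain, out$resno, out$icode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force global alignment score by path enumeration
#'
#' Enumerates every monotone alignment path (match/insert/delete moves)
#' between two short sequences and scores each with affine gaps (a gap of
#' length k costs \code{gapOpening + k * gapExtension}, terminal gaps
#' included), returning the maximum. Exponential; refuses sequences over
#' 8 residues.
#'
#' @param a,b Protein sequences, each <= 8 residues.
#' @param substitutionMatrix Scoring matrix (default BLOSUM62).
#' @param gapOpening,gapExtension Affine gap costs.
#' @return Optimal alignment score.
#' @export
bruteAlign <- function(a, b, substitutionMatrix = NULL, gapOpening = 10,
                       gapExtension = 0.5) {
  if (nchar(a) > 8L || nchar(b) > 8L)
    stop("bruteAlign refuses sequences above 8 residues", call. = FALSE)
  mat <- if (is.null(substitutionMatrix)) .blosum62() else substitutionMatrix
  ca <- strsplit(toupper(a), "")[[1]]; cb <- strsplit(toupper(b), "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  ## moves: 1 = diagonal, 2 = gap in b (consume a), 3 = gap in a (consume b)
  rec <- function(i, j, prev, sc) {
    if (i == n && j == m) { if (sc > best) best <<- sc; return(invisible()) }
    if (i < n && j < m)
      rec(i + 1L, j + 1L, 1L, sc + mat[ca[i + 1L], cb[j + 1L]])
    if (i < n)
      rec(i + 1L, j, 2L,
          sc - (if (prev == 2L) gapExtension else gapOpening + gapExtension))
    if (j < m)
      rec(i, j + 1L, 3L,
          sc - (if (prev == 3L) gapExtension else gapOpening + gapExtension))
  }
  rec(0L, 0L, 0L, 0)
  best
}

#' Patristic distances by explicit path traversal
#'
#' Computes leaf-to-leaf path-length sums by walking parent pointers —
#' independent of the cophenetic-matrix route.
#'
#' @param tree An \pkg{ape} \code{phylo} tree with branch lengths
#'   (<= 64 leaves).
#' @return Symmetric matrix of path sums, labelled by leaf.
#' @export
treePathDistances <- function(tree) {
  n_leaf <- length(tree$tip.label)
  if (n_leaf > 64L)
    stop("treePathDistances refuses trees above 64 leaves", call. = FALSE)
  edge <- tree$edge; len <- tree$edge.length
  parent_of <- integer(max(edge)); elen_of <- numeric(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  elen_of[edge[, 2]] <- len
  root <- setdiff(edge[, 1], edge[, 2])[1]
  path_to_root <- function(v) {
    nodes <- v; lens <- numeric(0)
    while (v != root) {
      lens <- c(lens, elen_of[v])
      v <- parent_of[v]
      nodes <- c(nodes, v)
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  paths <- lapply(seq_len(n_leaf), path_to_root)
  d <- matrix(0, n_leaf, n_leaf,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_leaf - 1L)) for (j in seq(i + 1L, n_leaf)) {
    pi_ <- paths[[i]]; pj <- paths[[j]]
    common <- intersect(pi_$nodes, pj$nodes)
    ## deepest common node = first common entry along either path
    anc <- pi_$nodes[min(match(common, pi_$nodes))]
    d[i, j] <- d[j, i] <-
      pi_$cum[match(anc, pi_$nodes)] + pj$cum[match(anc, pj$nodes)]
  }
  d
}

#' Naive signature placement enumeration
#'
#' Enumerates every combination of element occurrences and returns the
#' lexicographically smallest placement satisfying order and gap windows,
#' or NULL. Used to cross-check the scanner's search.
#'
#' @param seq Protein sequence (<= 2000 residues).
#' @param sig A [Signature-class].
#' @return Integer vector of element starts, or NULL.
#' @export
bruteMatch <- function(seq, sig) {
  if (nchar(seq) > 2000L)
    stop("bruteMatch refuses sequences above 2000 residues", call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1]]
  pats <- sig@elements$pattern
  lens <- nchar(pats)
  occ <- lapply(pats, function(p) .element_hits(chars, p))
  if (any(!lengths(occ))) return(NULL)
  grid <- expand.grid(rev(occ), KEEP.OUT.ATTRS = FALSE)
  grid <- as.matrix(grid[, rev(seq_len(ncol(grid))), drop = FALSE])
  ok <- rep(TRUE, nrow(grid))
  if (length(pats) > 1L)
    for (k in seq_len(length(pats) - 1L)) {
      sep <- grid[, k + 1L] - (grid[, k] + lens[k] - 1L) - 1L
      ok <- ok & sep >= sig@gap_min[k] & sep <= sig@gap_max[k]
    }
  if (!any(ok)) return(NULL)
  cand <- grid[ok, , drop = FALSE]
  ord <- do.call(order, as.data.frame(cand))
  as.integer(cand[ord[1], ])
}
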