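## Optimal rigid superposition (Kabsch) and the RMSD-based structural
## classification filter applied to homology models.

#' Kabsch optimal superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, by singular value decomposition of the covariance
#' matrix with the usual determinant correction so that reflections are
#' never returned.
#'
#' @param a,b Numeric n x 3 matrices of paired coordinates (Angstrom),
#'   n >= 3 and not collinear.
#' @param pairs Optional provenance data.frame describing the residue
#'   pairing, carried through to the result.
#' @return A [SuperpositionResult-class]. Applying the rotation and
#'   translation to \code{a} (\code{a \%*\% t(rotation) + translation})
#'   superposes it onto \code{b}.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' res <- kabschSuperpose(a, a + 5)   # pure translation
#' res@rmsd
#' @export
kabschSuperpose <- function(a, b, pairs = data.frame()) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.numeric(a) || !is.numeric(b) || ncol(a) != 3L || ncol(b) != 3L)
    stop("coordinates must be numeric n x 3 matrices", call. = FALSE)
  if (nrow(a) != nrow(b)) stop("paired sets must have equal length",
                               call. = FALSE)
  n <- nrow(a)
  if (n < 3L) stop("at least 3 point pairs are required", call. = FALSE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  sv_a <- svd(a0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate (collinear) coordinates: superposition is not unique",
         call. = FALSE)
  s <- svd(crossprod(a0, b0))          # t(a0) %*% b0 = U D t(V)
  d <- sign(det(s$u) * det(s$v))
  if (d == 0) d <- 1
  W <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)   # a0 %*% W ~ b0
  rotation <- t(W)
  translation <- as.numeric(cb - ca %*% W)
  resid <- a0 %*% W - b0
  rmsd <- sqrt(sum(resid^2) / n)
  new("SuperpositionResult", rotation = rotation, translation = translation,
      rmsd = rmsd, n_pairs = as.integer(n), pairs = pairs)
}

## One-letter sequence + residue bookkeeping for each polymer chain.
.chain_records <- function(s) {
  a <- s@atoms[!s@atoms$hetero, , drop = FALSE]
  if (!nrow(a)) stop("structure ", s@id, " has no polymer chain",
                     call. = FALSE)
  key <- .residue_key(a)
  first <- !duplicated(key)
  res <- a[first, c("chain", "resno", "icode", "resname"), drop = FALSE]
  res$key <- key[first]
  lapply(split(seq_len(nrow(res)), res$chain), function(idx) {
    r <- res[idx, , drop = FALSE]
    letters1 <- suppressWarnings(bio3d::aa321(r$resname))
    letters1[is.na(letters1) | !nzchar(letters1)] <- "X"
    list(chain = r$chain[1], residues = r,
         seq = paste(letters1, collapse = ""))
  })
}

## Coordinates of a named backbone atom for given residue keys; NA rows for
## residues lacking the atom.
.atom_coords_for_keys <- function(s, keys, atom_name) {
  a <- s@atoms[!s@atoms$hetero & s@atoms$name == atom_name & !s@atoms$hydrogen,
               , drop = FALSE]
  k <- .residue_key(a)
  idx <- match(keys, k)
  cbind(a$x[idx], a$y[idx], a$z[idx])
}

#' Pair C-alpha atoms of a model and a reference by sequence alignment
#'
#' Chains are globally aligned (BLOSUM62, affine gaps) and the chain pair
#' with the highest alignment score is used; C-alpha atoms of matched
#' (non-gap) columns are paired. Models share their sequence with the
#' reference by construction, so sequence pairing is well-defined; spatial
#' pre-alignment is not required.
#'
#' @param model,ref [PDBStructure-class] objects with at least one polymer
#'   chain each.
#' @param atoms \code{"calpha"} (default) pairs C-alpha atoms only;
#'   \code{"backbone"} pairs N, CA, C and O of each matched residue.
#' @param min_coverage Minimum fraction of the shorter chain that must be
#'   paired; below this the model is considered to diverge from the
#'   reference and an error is raised. Default 0.6.
#' @return A list with elements \code{a} and \code{b} (paired coordinate
#'   matrices for model and reference), \code{pairs} (residue provenance),
#'   and \code{coverage}.
#' @export
pairCAlpha <- function(model, ref, atoms = c("calpha", "backbone"),
                       min_coverage = 0.6) {
  atoms <- match.arg(atoms)
  mc <- .chain_records(model); rc <- .chain_records(ref)
  best <- NULL; best_score <- -Inf
  for (m in mc) for (r in rc) {
    al <- .align_core(m$seq, r$seq)
    if (al$score > best_score) { best_score <- al$score
                                 best <- list(m = m, r = r, al = al) }
  }
  ## map aligned columns back to residue indices
  am <- strsplit(best$al$aligned_a, "")[[1]]
  ar <- strsplit(best$al$aligned_b, "")[[1]]
  im <- cumsum(am != "-"); ir <- cumsum(ar != "-")
  both <- which(am != "-" & ar != "-")
  mres <- best$m$residues[im[both], , drop = FALSE]
  rres <- best$r$residues[ir[both], , drop = FALSE]

  names_needed <- if (atoms == "calpha") "CA" else c("N", "CA", "C", "O")
  A <- NULL; B <- NULL; keep_res <- logical(length(both))
  coords_m <- lapply(names_needed, function(nm)
    .atom_coords_for_keys(model, mres$key, nm))
  coords_r <- lapply(names_needed, function(nm)
    .atom_coords_for_keys(ref, rres$key, nm))
  rows_ok <- rep(TRUE, length(both))
  for (k in seq_along(names_needed))
    rows_ok <- rows_ok & stats::complete.cases(coords_m[[k]]) &
      stats::complete.cases(coords_r[[k]])
  for (k in seq_along(names_needed)) {
    A <- rbind(A, coords_m[[k]][rows_ok, , drop = FALSE])
    B <- rbind(B, coords_r[[k]][rows_ok, , drop = FALSE])
  }
  ## interleave per residue for readability of provenance
  n_res <- sum(rows_ok)
  coverage <- n_res / min(nrow(best$m$residues), nrow(best$r$residues))
  if (coverage < min_coverage)
    stop(sprintf(paste0("low coverage (%.2f < %.2f): model %s diverges from ",
                        "the reference %s"), coverage, min_coverage,
                 model@id, ref@id), call. = FALSE)
  pairs <- data.frame(
    model_chain = mres$chain[rows_ok], model_resno = mres$resno[rows_ok],
    ref_chain = rres$chain[rows_ok], ref_resno = rres$resno[rows_ok],
    stringsAsFactors = FALSE)
  list(a = A, b = B, pairs = pairs, coverage = coverage)
}

#' Superpose a model onto a reference structure
#'
#' Convenience wrapper: [pairCAlpha()] followed by [kabschSuperpose()].
#'
#' @inheritParams pairCAlpha
#' @return A [SuperpositionResult-class].
#' @export
superposeStructures <- function(model, ref, atoms = c("calpha", "backbone"),
                                min_coverage = 0.6) {
  p <- pairCAlpha(model, ref, atoms = atoms, min_coverage = min_coverage)
  kabschSuperpose(p$a, p$b, pairs = p$pairs)
}

#' RMSD filter for homology models
#'
#' Classifies each model against a ligand-bound reference: a model is
#' accepted when its C-alpha RMSD to the reference (after optimal
#' superposition over the sequence-paired region) is at or below the
#' cutoff. Outlier models above the cutoff are rejected from further
#' processing but reported with their RMSD. The default cutoff of 2.0
#' Angstrom is the workflow's structural-similarity threshold.
#'
#' @param models Named list of [PDBStructure-class] models.
#' @param ref Reference [PDBStructure-class].
#' @param cutoff RMSD acceptance threshold in Angstrom (default 2.0).
#' @param atoms Atom set for RMSD, \code{"calpha"} or \code{"backbone"}.
#' @return data.frame with columns \code{model_id}, \code{rmsd},
#'   \code{n_pairs}, \code{accepted}, \code{note}. Models that cannot be
#'   paired (low coverage) are rejected with \code{NA} RMSD and the reason
#'   in \code{note}.
#' @export
rmsdFilter <- function(models, ref, cutoff = 2.0,
                       atoms = c("calpha", "backbone")) {
  atoms <- match.arg(atoms)
  if (!is.list(models) || !length(models))
    stop("'models' must be a non-empty list of structures", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  ids <- names(models)
  if (is.null(ids))
    ids <- vapply(models, function(m) m@id, character(1))
  rows <- lapply(seq_along(models), function(i) {
    res <- tryCatch(superposeStructures(models[[i]], ref, atoms = atoms),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(model_id = ids[i], rmsd = NA_real_, n_pairs = 0L,
                 accepted = FALSE, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(model_id = ids[i], rmsd = res@rmsd, n_pairs = res@n_pairs,
                 accepted = res@rmsd <= cutoff, note = "",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
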