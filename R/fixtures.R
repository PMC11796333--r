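## Synthetic-data generators: a planted-motif sequence family with
## controlled per-anchor conservation, a conservation fixture with exact
## per-column modal frequencies, and a toy metal-ligand complex with a
## known contact set. All generators are pure functions of (spec, seed):
## one explicit Mersenne-Twister stream per call, global RNG state
## restored afterwards.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

## Default planted signature: four elements shaped like the
## cobalamin-photoreceptor motif series, anchored at reference positions
## 10, 21, 31 and 41.
.default_family_signature <- function() {
  sig <- parseSignature("GxxW{5,9}EH{6,10}GxxH{4,8}GxxxP")
  sig@elements$ref_start <- c(10L, 21L, 31L, 41L)
  sig@region <- c(10, 45)
  sig
}

#' Generate a planted-motif sequence family
#'
#' Positives are i.i.d. uniform 20-letter sequences into which each
#' signature anchor (specific, non-wildcard position) is written with
#' probability \code{conservation}, at fixed per-element offsets
#' (the signature's reference starts). Decoys are rejection-sampled
#' uniform sequences that do not match the signature at all. Identical
#' seeds give byte-identical output.
#'
#' @param n_positive,n_decoy Family sizes (defaults 50 and 200).
#' @param signature A [Signature-class] with reference starts; default is
#'   a four-element motif series spanning reference 10-45.
#' @param conservation Per-anchor planting probability in [0, 1]
#'   (default 1.0).
#' @param length Sequence length (default 80); must cover the signature
#'   span.
#' @param seed Integer seed (required; the generator is pure in it).
#' @param max_attempts Rejection-sampling cap per decoy (default 1e6).
#' @return List with \code{sequences} (named character vector, positives
#'   \code{pos###} then decoys \code{dec###}), \code{reference} (a fully
#'   planted sequence named \code{"reference"}), \code{truth} (data.frame
#'   id, is_positive, planted_starts), \code{signature}, and the spec
#'   echo in \code{params}.
#' @export
generateFamily <- function(n_positive = 50L, n_decoy = 200L,
                           signature = NULL, conservation = 1.0,
                           length = 80L, seed, max_attempts = 1e6) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (conservation < 0 || conservation > 1)
    stop("conservation must lie in [0, 1]", call. = FALSE)
  if (is.null(signature)) signature <- .default_family_signature()
  stopifnot(is(signature, "Signature"))
  starts <- signature@elements$ref_start
  if (anyNA(starts))
    stop("signature must carry reference starts for planting",
         call. = FALSE)
  pats <- strsplit(signature@elements$pattern, "")
  span_end <- max(starts + lengths(pats) - 1L)
  if (length < span_end)
    stop("sequence length ", length, " below signature span ", span_end,
         call. = FALSE)

  .with_seed(seed, {
    rand_seq <- function()
      paste(sample(.AA20, length, replace = TRUE), collapse = "")
    plant <- function(s, prob) {
      ch <- strsplit(s, "")[[1]]
      for (e in seq_along(pats)) {
        pc <- pats[[e]]
        for (j in seq_along(pc)) {
          if (pc[j] == "x") next
          if (stats::runif(1) <= prob) ch[starts[e] + j - 1L] <- pc[j]
        }
      }
      paste(ch, collapse = "")
    }
    positives <- vapply(seq_len(n_positive), function(i)
      plant(rand_seq(), conservation), character(1))
    reference <- plant(rand_seq(), 1.0)
    decoys <- character(n_decoy)
    for (i in seq_len(n_decoy)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- rand_seq()
        if (is.null(matchSignature(cand, signature))) {
          decoys[i] <- cand; ok <- TRUE; break
        }
      }
      if (!ok)
        stop("rejection sampling exceeded ", max_attempts,
             " attempts per decoy: signature too permissive",
             call. = FALSE)
    }
    ids <- c(sprintf("pos%03d", seq_len(n_positive)),
             sprintf("dec%03d", seq_len(n_decoy)))
    seqs <- stats::setNames(c(positives, decoys), ids)
    truth <- data.frame(
      id = ids,
      is_positive = rep(c(TRUE, FALSE), c(n_positive, n_decoy)),
      planted_starts = c(rep(paste(starts, collapse = ","), n_positive),
                         rep("", n_decoy)),
      stringsAsFactors = FALSE)
    list(sequences = seqs, reference = reference, truth = truth,
         signature = signature,
         params = list(n_positive = n_positive, n_decoy = n_decoy,
                       conservation = conservation, length = length,
                       seed = seed))
  })
}

#' Write a generated family to disk
#'
#' @param fam Output of [generateFamily()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (FASTA, truth TSV, signature
#'   file).
#' @export
writeFamily <- function(fam, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "family.fasta")
  writeLines(paste0(">", names(fam$sequences), "\n", fam$sequences), fa)
  ref <- file.path(dir, "reference.fasta")
  writeLines(paste0(">reference\n", fam$reference), ref)
  tt <- file.path(dir, "truth.tsv")
  utils::write.table(fam$truth, tt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sg <- file.path(dir, "signature.txt")
  writeSignature(fam$signature, sg, provenance = fam$params)
  invisible(c(fa, ref, tt, sg))
}

#' Generate an alignment with exact per-column modal frequencies
#'
#' For testing conservation scoring: column j of the returned alignment
#' has exactly \code{round(freqs[j] * n_rows)} copies of a modal residue,
#' the remaining rows cycling through other letters so no other residue
#' reaches the modal count.
#'
#' @param n_rows Number of rows (default 50).
#' @param freqs Target modal fractions per column (each > 0.25).
#' @param seed Integer seed.
#' @return List with \code{msa} (\code{AAStringSet}) and \code{truth}
#'   (achieved modal fractions).
#' @export
generateConservationFixture <- function(n_rows = 50L, freqs, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (any(freqs <= 0.25 | freqs > 1))
    stop("freqs must lie in (0.25, 1]", call. = FALSE)
  .with_seed(seed, {
    cols <- lapply(freqs, function(f) {
      k <- max(1L, round(f * n_rows))
      modal <- sample(.AA20, 1)
      others <- setdiff(.AA20, modal)
      fill <- rep(others, length.out = n_rows - k)
      if (length(fill) && max(table(fill)) >= k)
        stop("infeasible column: modal count not unique", call. = FALSE)
      sample(c(rep(modal, k), fill))       # shuffle rows
    })
    M <- do.call(cbind, cols)
    truth <- vapply(seq_along(freqs), function(j)
      max(table(M[, j])) / n_rows, numeric(1))
    rows <- apply(M, 1, paste, collapse = "")
    msa <- Biostrings::AAStringSet(stats::setNames(
      rows, sprintf("row%03d", seq_len(n_rows))))
    list(msa = msa, truth = truth)
  })
}

## Fibonacci-sphere directions (deterministic, well separated).
.sphere_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate a toy metal-ligand complex with a known contact set
#'
#' Builds a synthetic single-chain protein around a small five-atom ligand
#' (one metal plus four carbons): each planted contact residue gets one
#' side-chain heavy atom 3.0-3.9 Angstrom from the nearest ligand atom;
#' the axial residue's side-chain nitrogen sits 2.2 Angstrom from the
#' metal; every other residue keeps all atoms more than 6 Angstrom from
#' every ligand atom. Geometry is schematic (no rotamers, no sterics) —
#' the construction exists so contact detection has exact ground truth.
#'
#' @param n_residues Chain length (default 50).
#' @param planted_contacts Residue numbers in contact. The default pocket
#'   sits at the specific positions of the default family signature
#'   (G10/W13, E21/H22, G31/H34, G41/P45), so a family generated by
#'   [generateFamily()] and this complex form a consistent end-to-end
#'   fixture.
#' @param contact_resnames Three-letter codes for the planted contacts.
#' @param metal Metal element (default \code{"Co"}).
#' @param axial_residue Residue number of the lower axial ligand; must be
#'   one of \code{planted_contacts} (default 22, the pocket histidine).
#' @param ligand_code Het code written for the ligand (default
#'   \code{"LIG"}).
#' @param seed Integer seed.
#' @return List with \code{structure} ([PDBStructure-class]),
#'   \code{contacts} (truth data.frame: resno, resname, target distance),
#'   \code{axial_residue}, \code{ligand_code}.
#' @export
generateToyComplex <- function(n_residues = 50L,
                               planted_contacts = c(10L, 13L, 21L, 22L,
                                                    31L, 34L, 41L, 45L),
                               contact_resnames = c("GLY", "TRP", "GLU",
                                                    "HIS", "GLY", "HIS",
                                                    "GLY", "PRO"),
                               metal = "Co", axial_residue = NULL,
                               ligand_code = "LIG", seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  planted_contacts <- as.integer(planted_contacts)
  if (length(contact_resnames) != length(planted_contacts))
    stop("contact_resnames must align with planted_contacts", call. = FALSE)
  if (is.null(axial_residue)) {
    his <- planted_contacts[contact_resnames == "HIS"]
    axial_residue <- if (length(his)) his[1]
                     else if (length(planted_contacts))
                       planted_contacts[length(planted_contacts)]
                     else NA_integer_
  }
  axial_residue <- as.integer(axial_residue)
  if (!is.na(axial_residue) && !axial_residue %in% planted_contacts)
    stop("axial_residue must be one of planted_contacts", call. = FALSE)
  if (any(planted_contacts < 1L | planted_contacts > n_residues))
    stop("planted_contacts outside 1..n_residues", call. = FALSE)

  .with_seed(seed, {
    metal <- .normalize_element(metal)
    ## ligand: metal at origin + four carbons at 1.5 A (tetrahedral-ish)
    lig_xyz <- rbind(c(0, 0, 0),
                     1.5 * rbind(c(1, 1, 1), c(1, -1, -1),
                                 c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3))
    lig <- data.frame(
      serial = 0L, name = c(toupper(metal), paste0("C", 1:4)),
      altloc = "", resname = ligand_code, chain = "L",
      resno = 200L, icode = "",
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      occupancy = 1, element = c(metal, rep("C", 4)),
      stringsAsFactors = FALSE)

    dirs <- .sphere_directions(n_residues)
    min_lig_dist <- function(p)
      min(sqrt(colSums((t(lig_xyz) - p)^2)))
    ## radial placement: find R with min ligand distance == target
    solve_radius <- function(u, target) {
      lo <- 0; hi <- 40
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (min_lig_dist(u * mid) < target) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }
    aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
             "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
    rows <- list()
    truth <- list()
    serial <- 1L
    for (i in seq_len(n_residues)) {
      u <- dirs[i, ]
      is_contact <- i %in% planted_contacts
      is_axial <- !is.na(axial_residue) && i == axial_residue
      resname <- if (is_contact)
        contact_resnames[match(i, planted_contacts)]
      else sample(setdiff(aa3, "HIS"), 1)
      if (is_axial) {
        ## fixed direction opposite the first ligand carbon: keeps the
        ## coordinating N 2.2 A from the metal and > 2 A from every carbon
        u <- -c(1, 1, 1) / sqrt(3)
        anchor <- u * 2.2
        anchor_name <- "NE2"; anchor_el <- "N"
      } else if (is_contact) {
        target <- stats::runif(1, 3.1, 3.8)
        R <- solve_radius(u, target)
        anchor <- u * R
        anchor_name <- "CB"; anchor_el <- "C"
      } else {
        target <- stats::runif(1, 6.8, 8.5)
        R <- solve_radius(u, target)
        anchor <- u * R
        anchor_name <- "CB"; anchor_el <- "C"
      }
      base_r <- sqrt(sum(anchor^2))
      bb <- function(extra) u * (base_r + extra)
      atoms_i <- rbind(
        data.frame(name = "N",  el = "N", p = I(list(bb(1.2)))),
        data.frame(name = "CA", el = "C", p = I(list(bb(2.2)))),
        data.frame(name = "C",  el = "C", p = I(list(bb(3.2)))),
        data.frame(name = "O",  el = "O", p = I(list(bb(4.0)))),
        data.frame(name = anchor_name, el = anchor_el,
                   p = I(list(anchor))))
      for (k in seq_len(nrow(atoms_i))) {
        p <- atoms_i$p[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          serial = serial, name = atoms_i$name[k], altloc = "",
          resname = resname, chain = "A", resno = i, icode = "",
          x = p[1], y = p[2], z = p[3], occupancy = 1,
          element = atoms_i$el[k], stringsAsFactors = FALSE)
        serial <- serial + 1L
      }
      if (is_contact)
        truth[[length(truth) + 1L]] <- data.frame(
          resno = i, resname = resname,
          target_dist = if (is_axial) 2.2 else target,
          stringsAsFactors = FALSE)
    }
    prot <- do.call(rbind, rows)
    lig$serial <- seq(serial, serial + nrow(lig) - 1L)
    atoms <- rbind(cbind(prot, hetero = FALSE),
                   cbind(lig, hetero = TRUE))
    atoms$mass <- .element_masses(atoms$element)
    atoms$hydrogen <- FALSE
    atoms <- atoms[, .ATOM_COLS]
    rownames(atoms) <- NULL
    s <- new("PDBStructure", id = "toy_complex", atoms = atoms)

    ## feasibility audit against the stated construction guarantees
    truth_df <- do.call(rbind, truth)
    for (i in seq_len(n_residues)) {
      sub <- atoms[!atoms$hetero & atoms$resno == i, c("x", "y", "z")]
      dmin <- min(apply(sub, 1, min_lig_dist))
      if (i %in% planted_contacts) {
        lim <- if (!is.na(axial_residue) && i == axial_residue) 2.0
               else 3.0
        if (dmin < lim - 1e-6 || dmin > 3.9 + 1e-6)
          stop("infeasible packing for contact residue ", i, call. = FALSE)
      } else if (dmin <= 6.0)
        stop("infeasible packing: residue ", i,
             " intrudes into the pocket", call. = FALSE)
    }
    list(structure = s, contacts = truth_df,
         axial_residue = as.integer(axial_residue),
         ligand_code = ligand_code)
  })
}
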