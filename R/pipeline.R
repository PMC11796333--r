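## End-to-end orchestration: tree classification -> structural (RMSD)
## filter -> ligand contacts -> conservation -> signature derivation ->
## optional database mining. External engines (modelling, docking,
## maximum-likelihood trees) are never invoked in-process: their outputs
## are ingested from files named in the config.

.CONFIG_SPEC <- list(
  reference_sequence   = list(type = "path", required = TRUE),
  reference_structure  = list(type = "path", required = TRUE),
  ligand_code          = list(type = "character", required = TRUE),
  queries              = list(type = "path", required = TRUE),
  out_dir              = list(type = "character", required = TRUE),
  alignment            = list(type = "path", required = FALSE),
  models               = list(type = "character", required = FALSE),
  database             = list(type = "path", required = FALSE),
  tree                 = list(type = "character", required = FALSE,
                              default = "internal-NJ"),
  negatives            = list(type = "character", required = FALSE),
  dist_threshold       = list(type = "numeric", required = FALSE,
                              range = c(0, Inf)),
  rmsd_cutoff          = list(type = "numeric", default = 2.0,
                              range = c(1e-9, 100)),
  box_ratio            = list(type = "numeric", default = 1.0,
                              range = c(1e-9, 100)),
  contact_cutoff       = list(type = "numeric", default = 4.0,
                              range = c(1e-9, 20)),
  conservation_threshold = list(type = "numeric", default = 0.8,
                              range = c(0, 1)),
  cluster_identity     = list(type = "numeric", default = 0.8,
                              range = c(1e-9, 1)),
  ssn_min_identity     = list(type = "numeric", default = 40,
                              range = c(0, 100)),
  merge_gap            = list(type = "numeric", default = 4,
                              range = c(0, 100)),
  min_template_identity = list(type = "numeric", default = 20,
                              range = c(0, 100)),
  reference_start_number = list(type = "numeric", default = 1,
                              range = c(-1e6, 1e6)),
  seed                 = list(type = "numeric", default = 1,
                              range = c(-2^31, 2^31))
)

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a named list), applies defaults, rejects
#' unknown keys (with a nearest-key suggestion), range-checks every
#' threshold and verifies that referenced paths exist.
#'
#' @param config Path to a YAML file or a named list.
#' @return A validated named list of class \code{"PipelineConfig"}.
#' @export
validateConfig <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a YAML path or a named list", call. = FALSE)

  unknown <- setdiff(names(cfg), names(.CONFIG_SPEC))
  if (length(unknown)) {
    sug <- vapply(unknown, function(k) {
      hit <- agrep(k, names(.CONFIG_SPEC), max.distance = 0.3,
                   value = TRUE)
      if (length(hit)) paste0(" (did you mean '", hit[1], "'?)") else ""
    }, character(1))
    stop("unknown config key(s): ",
         paste0(unknown, sug, collapse = ", "), call. = FALSE)
  }
  for (k in names(.CONFIG_SPEC)) {
    sp <- .CONFIG_SPEC[[k]]
    if (is.null(cfg[[k]])) {
      if (isTRUE(sp$required))
        stop("missing required config key: ", k, call. = FALSE)
      if (!is.null(sp$default)) cfg[[k]] <- sp$default
      next
    }
    v <- cfg[[k]]
    if (sp$type == "numeric") {
      if (!is.numeric(v) || length(v) != 1L)
        stop("config key '", k, "' must be a single number", call. = FALSE)
      if (!is.null(sp$range) && (v < sp$range[1] || v > sp$range[2]))
        stop("config key '", k, "' = ", v, " outside allowed range [",
             sp$range[1], ", ", sp$range[2], "]", call. = FALSE)
    }
    if (sp$type == "path" && (!is.character(v) || !file.exists(v)))
      stop("config key '", k, "' must name an existing path (got '",
           v, "')", call. = FALSE)
  }
  structure(cfg, class = "PipelineConfig")
}

.read_fasta_named <- function(path) {
  v <- as.character(Biostrings::readAAStringSet(path))
  names(v) <- sub("\\s.*$", "", names(v))
  v
}

#' Run the signature-discovery pipeline
#'
#' Stage order: phylogenetic classification of the queries relative to the
#' reference; structural (RMSD) filtering of externally supplied homology
#' models against the reference structure (queries below the template
#' identity floor are marked not modelled); ligand-contact analysis of the
#' reference complex; per-column conservation of the candidate alignment;
#' signature derivation from the contact/conservation intersection; and an
#' optional database scan with greedy clustering and similarity-network
#' export. All stage outputs are written under \code{out_dir}; rerunning
#' with identical config and inputs is byte-identical (no timestamps).
#'
#' @param config A config path or list accepted by [validateConfig()].
#' @return A list of class \code{"RunReport"}: \code{config} echo,
#'   \code{stages} (per-stage summaries), \code{verdicts} (one row per
#'   query), \code{signature}, and mining tables when a database was
#'   scanned.
#' @export
runPipeline <- function(config) {
  cfg <- validateConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()

  ref_vec <- .read_fasta_named(cfg$reference_sequence)
  reference_id <- names(ref_vec)[1]
  reference_seq <- unname(ref_vec[1])
  queries <- .read_fasta_named(cfg$queries)
  queries <- queries[setdiff(names(queries), reference_id)]
  if (length(queries) < 3L)
    stop("at least three query sequences are required (got ",
         length(queries), ")", call. = FALSE)
  all_seqs <- c(stats::setNames(reference_seq, reference_id), queries)

  ## alignment: supplied pre-aligned, or already-aligned equal-length input
  if (!is.null(cfg$alignment)) {
    msa <- readMSA(cfg$alignment)
  } else if (length(unique(nchar(all_seqs))) == 1L) {
    msa <- Biostrings::AAStringSet(all_seqs)
  } else {
    stop("queries are not equal-length; supply a pre-aligned FASTA via ",
         "the 'alignment' config key", call. = FALSE)
  }
  if (!reference_id %in% names(msa))
    stop("alignment lacks the reference row '", reference_id, "'",
         call. = FALSE)
  stages$input <- list(reference = reference_id, n_queries = length(queries))

  ## --- stage 1: tree classification ------------------------------------
  tree <- if (!is.null(cfg$tree) && cfg$tree != "internal-NJ") {
    loadTree(cfg$tree)
  } else {
    neighborJoining(pDistanceMatrix(msa))
  }
  saveTree(tree, file.path(cfg$out_dir, "tree.nwk"))
  gated <- !is.null(cfg$negatives) || !is.null(cfg$dist_threshold)
  if (gated) {
    calls <- classifyByClade(tree, reference_id,
                             queries = names(queries),
                             negatives = cfg$negatives,
                             dist_threshold = cfg$dist_threshold)
  } else {
    calls <- data.frame(query_id = names(queries),
                        call = "photoreceptor-candidate",
                        evidence = "ungated", rule = "none",
                        stringsAsFactors = FALSE)
  }
  utils::write.table(calls, file.path(cfg$out_dir, "clade_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$tree <- list(gated = gated,
                      candidates = sum(calls$call ==
                                       "photoreceptor-candidate"))

  ## --- stage 2: structural filter --------------------------------------
  ref_structure <- readStructure(cfg$reference_structure)
  template_pid <- vapply(queries, function(q)
    percentIdentity(q, reference_seq), numeric(1))
  modelled_status <- ifelse(template_pid < cfg$min_template_identity,
                            "not modelled (template identity < floor)",
                            "modellable")
  rmsd_tab <- NULL
  if (!is.null(cfg$models)) {
    files <- list.files(cfg$models, pattern = "\\.pdb$", full.names = TRUE)
    ids <- tools::file_path_sans_ext(basename(files))
    keep <- ids %in% names(queries)
    models <- stats::setNames(lapply(files[keep], readStructure), ids[keep])
    if (length(models)) {
      rmsd_tab <- rmsdFilter(models, ref_structure,
                             cutoff = cfg$rmsd_cutoff)
      utils::write.table(rmsd_tab, file.path(cfg$out_dir, "rmsd.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  stages$structure <- list(
    n_models = if (is.null(rmsd_tab)) 0L else nrow(rmsd_tab),
    accepted = if (is.null(rmsd_tab)) NA_integer_
               else sum(rmsd_tab$accepted),
    rmsd_cutoff = cfg$rmsd_cutoff)

  ## --- stage 3: ligand contacts + box ----------------------------------
  ligand <- extractLigand(ref_structure, cfg$ligand_code)
  box <- dockingBox(ligand, ratio = cfg$box_ratio)
  writeBoxParams(box, file.path(cfg$out_dir, "docking_box.txt"))
  contacts <- findContacts(ref_structure, ligand,
                           cutoff = cfg$contact_cutoff)
  utils::write.table(contacts@records,
                     file.path(cfg$out_dir, "contacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$contacts <- list(n = nrow(contacts@records),
                          cutoff = cfg$contact_cutoff,
                          box_edge = box@edge)

  ## --- stage 4: conservation over candidate rows -----------------------
  cand_ids <- c(reference_id,
                calls$query_id[calls$call == "photoreceptor-candidate"])
  cand_msa <- msa[names(msa) %in% cand_ids]
  cons <- columnConservation(cand_msa)
  cmap <- mapColumns(cand_msa, reference_id,
                     start_number = cfg$reference_start_number)
  cons_tab <- data.frame(column = seq_along(cons@scores),
                         refpos = cmap@col_to_refpos,
                         score = cons@scores,
                         gap_fraction = cons@gap_fraction)
  utils::write.table(cons_tab, file.path(cfg$out_dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stages$conservation <- list(n_cols = length(cons@scores),
                              tau = cfg$conservation_threshold)

  ## --- stage 5: signature ----------------------------------------------
  sig <- deriveSignature(contacts, cons, cmap,
                         tau = cfg$conservation_threshold,
                         merge_gap = cfg$merge_gap)
  writeSignature(sig, file.path(cfg$out_dir, "signature.txt"),
                 provenance = list(tau = cfg$conservation_threshold,
                                   contact_cutoff = cfg$contact_cutoff,
                                   structure = ref_structure@id))
  stages$signature <- list(text = signatureToText(sig),
                           n_elements = nrow(sig@elements))

  ## per-query verdicts
  sig_match <- vapply(names(queries), function(q)
    !is.null(matchSignature(queries[[q]], sig, sequence_id = q)),
    logical(1))
  verdicts <- data.frame(
    query_id = names(queries),
    tree_call = calls$call[match(names(queries), calls$query_id)],
    template_identity = round(template_pid, 2),
    modelled = modelled_status,
    rmsd = if (is.null(rmsd_tab)) NA_real_
           else rmsd_tab$rmsd[match(names(queries), rmsd_tab$model_id)],
    signature_match = sig_match,
    stringsAsFactors = FALSE)
  utils::write.table(verdicts, file.path(cfg$out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- stage 6: optional database mining -------------------------------
  mining <- NULL
  if (!is.null(cfg$database)) {
    hits <- scanDatabase(cfg$database, sig)
    utils::write.table(hits, file.path(cfg$out_dir, "hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    db <- .read_fasta_named(cfg$database)
    mining <- list(hits = hits)
    if (nrow(hits)) {
      cl <- greedyCluster(db[hits$sequence_id],
                          threshold = cfg$cluster_identity)
      utils::write.table(cl@members,
                         file.path(cfg$out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      reps <- unique(cl@members$representative)
      mining$clusters <- cl
      if (length(reps) >= 2L) {
        ssn <- buildSSN(db[reps], min_identity = cfg$ssn_min_identity)
        exportGraph(ssn, file.path(cfg$out_dir, "ssn.tsv"), "tsv")
        mining$ssn <- ssn
      }
      stages$mining <- list(n_hits = nrow(hits),
                            n_hit_sequences = nrow(hits),
                            n_clusters = length(reps))
    } else {
      stages$mining <- list(n_hits = 0L, n_clusters = 0L)
    }
  }

  for (st in names(stages))
    message("[cofsig] ", st, ": ",
            paste(names(stages[[st]]), unlist(lapply(stages[[st]],
                  paste, collapse = ",")), sep = "=", collapse = " "))
  report <- list(config = unclass(cfg), stages = stages,
                 verdicts = verdicts, signature = sig, mining = mining)
  class(report) <- "RunReport"
  yaml::write_yaml(list(config = unclass(cfg), stages = stages),
                   file.path(cfg$out_dir, "report.yaml"))
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("cofsig run report\n")
  cat("  reference:", x$stages$input$reference, "|",
      x$stages$input$n_queries, "queries\n")
  cat("  tree candidates:", x$stages$tree$candidates,
      if (x$stages$tree$gated) "(gated)" else "(ungated)", "\n")
  cat("  contacts:", x$stages$contacts$n, "residues\n")
  cat("  signature:", x$stages$signature$text, "\n")
  if (!is.null(x$stages$mining))
    cat("  mining:", x$stages$mining$n_hits, "hits in",
        x$stages$mining$n_clusters, "clusters\n")
  invisible(x)
}
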