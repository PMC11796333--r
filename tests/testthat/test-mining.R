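test_that("database scan returns exactly the planted positives", {
  fam <- family_fixture()
  hits <- scanDatabase(fam$sequences, fam$signature)
  expect_equal(hits$sequence_id, fam$truth$id[fam$truth$is_positive])
  # reported placements equal the enumeration oracle's leftmost placement
  oracle_starts <- vapply(hits$sequence_id, function(id)
    paste(bruteMatch(fam$sequences[[id]], fam$signature), collapse = ","),
    character(1))
  expect_equal(unname(oracle_starts), hits$element_starts)
  # streaming from file equals in-memory scan, in input order
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(fam$sequences), "\n", fam$sequences), f)
  hits_file <- scanDatabase(f, fam$signature, chunk_size = 32)
  expect_identical(hits_file, hits)
  # reference sequence is always among its own hits
  db2 <- c(fam$sequences, reference = fam$reference)
  expect_true("reference" %in%
              scanDatabase(db2, fam$signature)$sequence_id)
  expect_warning(scanDatabase(character(0), fam$signature), "empty")
})

test_that("greedy clustering honours the representative-identity property", {
  set.seed(14)
  base <- random_protein(60)
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    ch[idx] <- vapply(ch[idx], function(x)
      sample(setdiff(c("A","C","D","E","G","W","Y","H"), x), 1),
      character(1))
    paste(ch, collapse = "")
  }
  seqs <- c(fam_a1 = base, fam_a2 = mutate(base, 5),
            fam_a3 = mutate(base, 8),
            solo1 = random_protein(55), solo2 = random_protein(50))
  cl <- greedyCluster(seqs, threshold = 0.8)
  mem <- clusterMembers(cl)
  # partition of the input
  expect_setequal(mem$member, names(seqs))
  expect_false(anyDuplicated(mem$member) > 0)
  # every member's identity to its representative is >= threshold
  for (i in seq_len(nrow(mem)))
    expect_gte(percentIdentity(seqs[[mem$member[i]]],
                               seqs[[mem$representative[i]]]), 80)
  # default threshold is the 80% family-mining convention
  expect_equal(formals(greedyCluster)$threshold, 0.8)
})

test_that("clustering edge cases: identical sequences and all-distinct", {
  same <- setNames(rep(strrep("ACDEFGHIKL", 4), 5), paste0("s", 1:5))
  cl <- greedyCluster(same, 0.8)
  expect_equal(length(unique(clusterMembers(cl)$representative)), 1L)
  set.seed(15)
  distinct <- setNames(vapply(1:6, function(i) random_protein(50),
                              character(1)), paste0("d", 1:6))
  pid <- outer(seq_along(distinct), seq_along(distinct),
               Vectorize(function(i, j)
                 if (i == j) 100 else
                 percentIdentity(distinct[[i]], distinct[[j]])))
  expect_true(all(pid[upper.tri(pid)] < 80))  # verified by oracle
  cl2 <- greedyCluster(distinct, 0.8)
  expect_equal(length(unique(clusterMembers(cl2)$representative)), 6L)
  # cluster count is monotone non-increasing as the threshold decreases
  n_at <- function(th)
    length(unique(clusterMembers(greedyCluster(distinct, th))$representative))
  counts <- vapply(c(0.9, 0.5, 0.2, 0.05), n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(greedyCluster(character(0)), "empty")
})

test_that("SSN keeps edges above threshold and is monotone in it", {
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  ch <- strsplit(base, "")[[1]]
  near <- ch; near[1:6] <- "A"          # ~90% identical to base
  seqs <- c(A = base, B = paste(near, collapse = ""),
            C = random_protein(60))
  pid_ab <- percentIdentity(seqs[["A"]], seqs[["B"]])
  pid_ac <- percentIdentity(seqs[["A"]], seqs[["C"]])
  pid_bc <- percentIdentity(seqs[["B"]], seqs[["C"]])
  thr <- (max(pid_ac, pid_bc) + min(90, pid_ab)) / 2
  g <- buildSSN(seqs, min_identity = thr)
  el <- igraph::as_edgelist(ssnGraph(g))
  expect_equal(nrow(el), 1L)
  expect_setequal(as.vector(el), c("A", "B"))
  # threshold 0: complete graph minus self-edges
  g0 <- buildSSN(seqs, min_identity = 0)
  expect_equal(igraph::ecount(ssnGraph(g0)), 3L)
  expect_equal(igraph::any_loop(ssnGraph(g0)), FALSE)
  # edge-set monotonicity
  edge_key <- function(g) {
    el <- igraph::as_edgelist(ssnGraph(g))
    if (!nrow(el)) return(character(0))
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  e_lo <- edge_key(buildSSN(seqs, min_identity = 10))
  e_hi <- edge_key(buildSSN(seqs, min_identity = 60))
  expect_true(all(e_hi %in% e_lo))
  expect_error(buildSSN(setNames(c("ACD", "ACD"), c("x", "x"))),
               "duplicate")
})

test_that("graph export is deterministic and round-trips over TSV", {
  set.seed(16)
  fam <- family_fixture()
  pos <- fam$sequences[fam$truth$id[fam$truth$is_positive]][1:6]
  g <- buildSSN(pos, min_identity = 20)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  exportGraph(g, f1, "tsv"); exportGraph(g, f2, "tsv")
  expect_identical(readLines(f1), readLines(f2))
  tab <- importGraphTSV(f1)
  el <- igraph::as_edgelist(ssnGraph(g))
  expect_equal(nrow(tab), nrow(el))
  expect_setequal(paste(tab$source, tab$target),
                  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  # graphml export is parseable XML with one node element per vertex
  fg <- tempfile(fileext = ".graphml")
  exportGraph(g, fg, "graphml")
  doc <- xml2::read_xml(fg)
  expect_equal(length(xml2::xml_find_all(doc, "//*[local-name()='node']")),
               igraph::vcount(ssnGraph(g)))
  expect_error(exportGraph(g, tempfile(), "dot"), "unknown graph format")
})
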