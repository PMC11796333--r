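random_additive_tree <- function(n_leaf) {
  tr <- ape::rtree(n_leaf, br = NULL)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  tr
}

test_that("p-distances count mismatches over shared non-gap columns", {
  msa <- Biostrings::AAStringSet(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL",
                                   c = "ACDEFGHIKV"))
  d <- pDistanceMatrix(msa)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.1)
  # gaps shrink the shared denominator
  msa2 <- Biostrings::AAStringSet(c(a = "ACDEF-----", b = "ACDVF-----",
                                    c = "ACDEFGHIKL"))
  expect_equal(pDistanceMatrix(msa2)["a", "b"], 0.2)  # 1 of 5 shared
  # poisson correction
  expect_equal(pDistanceMatrix(msa, correction = "poisson")["a", "c"],
               -log(0.9))
  # random MSAs agree with a per-pair explicit count
  set.seed(11)
  rows <- setNames(vapply(1:5, function(i) random_protein(40),
                          character(1)), paste0("s", 1:5))
  d2 <- pDistanceMatrix(Biostrings::AAStringSet(rows))
  for (i in 1:4) for (j in (i + 1):5) {
    ci <- strsplit(rows[i], "")[[1]]; cj <- strsplit(rows[j], "")[[1]]
    expect_equal(d2[i, j], mean(ci != cj))
  }
  # disjoint coverage errors with the pair named
  msa3 <- Biostrings::AAStringSet(c(a = "AC---", b = "---DE", c = "ACDEF"))
  expect_error(pDistanceMatrix(msa3), "'a' and 'b'")
})

test_that("neighbor joining recovers random additive 8-leaf trees", {
  set.seed(12)
  for (i in 1:10) {
    tr <- random_additive_tree(8)
    d <- treePathDistances(tr)          # independent path-sum oracle
    nj_tree <- neighborJoining(d)
    expect_true(ape::all.equal.phylo(ape::unroot(tr),
                                     ape::unroot(nj_tree),
                                     use.edge.length = FALSE))
    d_rec <- treePathDistances(nj_tree)[rownames(d), colnames(d)]
    expect_lt(max(abs(d_rec - d)), 1e-9)
  }
  # four-point condition: AB|CD additive structure joins A,B first
  d4 <- matrix(c(0, 2, 7, 7,
                 2, 0, 7, 7,
                 7, 7, 0, 2,
                 7, 7, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighborJoining(d4)
  drop_ab <- ape::drop.tip(t4, c("C", "D"))
  expect_setequal(drop_ab$tip.label, c("A", "B"))
  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)), "three taxa")
  dns <- d4; dns[1, 2] <- 5
  expect_error(neighborJoining(dns), "symmetric")
})

test_that("NJ is invariant under taxon relabeling", {
  set.seed(13)
  tr <- random_additive_tree(6)
  d <- treePathDistances(tr)
  perm <- sample(6)
  d2 <- d[perm, perm]
  t1 <- neighborJoining(d); t2 <- neighborJoining(d2)
  expect_true(ape::all.equal.phylo(ape::unroot(t1), ape::unroot(t2),
                                   use.edge.length = FALSE))
})

test_that("newick parsing is lossless and rejects malformed input", {
  txt <- "((A:1,B:2):1,(C:3,D:1):1);"
  f <- tempfile(fileext = ".nwk")
  writeLines(txt, f)
  tr <- loadTree(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  rt <- parseNewick(saveTree(tr))
  expect_true(ape::all.equal.phylo(tr, rt))
  expect_equal(sort(rt$edge.length), sort(tr$edge.length))
  expect_error(parseNewick("((A:1,B:2"), "unclosed")
  expect_error(parseNewick("(A:1,B:2));"), "unbalanced")
  # patristic distances equal the traversal oracle
  expect_equal(patristicDistances(tr)[tr$tip.label, tr$tip.label],
               treePathDistances(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-12)
})

test_that("clade classification follows the negatives rule", {
  # handcrafted: ((REF,Q1),Q2) with negative outgroup NEG
  tr <- parseNewick("(((REF:1,Q1:1):1,Q2:2):1,NEG:3);")
  calls <- classifyByClade(tr, "REF", negatives = "NEG")
  verdict <- setNames(calls$call, calls$query_id)
  expect_equal(unname(verdict["Q1"]), "photoreceptor-candidate")
  expect_equal(unname(verdict["Q2"]), "photoreceptor-candidate")
  # a query nested beyond/inside the negatives' clade is out
  tr2 <- parseNewick("((REF:1,Q1:1):1,((N1:1,Q2:1):1,N2:1):1);")
  calls2 <- classifyByClade(tr2, "REF", negatives = c("N1", "N2"))
  v2 <- setNames(calls2$call, calls2$query_id)
  expect_equal(unname(v2["Q1"]), "photoreceptor-candidate")
  expect_equal(unname(v2["Q2"]), "non-candidate")
  # clade-enumeration oracle on the first tree: the candidate set is
  # exactly the leaf set of one clade of the rooted tree (connectedness)
  cand <- c("REF", calls$query_id[calls$call == "photoreceptor-candidate"])
  rooted <- ape::root(tr, outgroup = "NEG", resolve.root = TRUE)
  clades <- lapply(setdiff(unique(rooted$edge[, 1]),
                           seq_along(rooted$tip.label)), function(nd)
    sort(ape::extract.clade(rooted, nd)$tip.label))
  expect_true(list(sort(unique(cand))) %in% clades)
  # star tree: all non-negative leaves are candidates
  star <- parseNewick("(A:1,B:1,REF:1,NEG:1);")
  sc <- classifyByClade(star, "REF", negatives = "NEG")
  expect_true(all(sc$call[sc$query_id != "NEG"] ==
                  "photoreceptor-candidate"))
  expect_equal(sc$call[sc$query_id == "NEG"], "non-candidate")
})

test_that("distance rule and configuration errors behave as documented", {
  tr <- parseNewick("(((REF:1,Q1:1):1,Q2:2):1,OUT:5);")
  calls <- classifyByClade(tr, "REF", dist_threshold = 2.5)
  v <- setNames(calls$call, calls$query_id)
  expect_equal(unname(v["Q1"]), "photoreceptor-candidate")  # d = 2
  expect_equal(unname(v["OUT"]), "non-candidate")           # d = 7
  expect_error(classifyByClade(tr, "REF"), "configuration error")
  expect_error(classifyByClade(tr, "MISSING", negatives = "OUT"),
               "absent")
})
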