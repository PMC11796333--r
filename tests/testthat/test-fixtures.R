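test_that("generators are pure functions of the seed", {
  f1 <- generateFamily(n_positive = 5, n_decoy = 5, seed = 42)
  f2 <- generateFamily(n_positive = 5, n_decoy = 5, seed = 42)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$truth, f2$truth)
  f3 <- generateFamily(n_positive = 5, n_decoy = 5, seed = 43)
  expect_false(identical(f1$sequences, f3$sequences))
  t1 <- generateToyComplex(seed = 42)
  t2 <- generateToyComplex(seed = 42)
  expect_identical(atomTable(t1$structure), atomTable(t2$structure))
  # writing twice gives byte-identical files
  d1 <- tempfile(); d2 <- tempfile()
  writeFamily(f1, d1); writeFamily(f2, d2)
  expect_identical(readLines(file.path(d1, "family.fasta")),
                   readLines(file.path(d2, "family.fasta")))
  # generators restore the caller's RNG state
  set.seed(99); before <- .Random.seed
  invisible(generateFamily(n_positive = 2, n_decoy = 2, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("full conservation plants every positive at the stated offsets", {
  fam <- generateFamily(n_positive = 20, n_decoy = 0, conservation = 1.0,
                        seed = 21)
  starts <- as.integer(strsplit(fam$truth$planted_starts[1], ",")[[1]])
  pats <- signatureElements(fam$signature)$pattern
  for (s in fam$sequences) {
    ch <- strsplit(s, "")[[1]]
    for (e in seq_along(pats)) {
      pc <- strsplit(pats[e], "")[[1]]
      for (j in seq_along(pc))
        if (pc[j] != "x") expect_equal(ch[starts[e] + j - 1], pc[j])
    }
  }
})

test_that("partial conservation hits the target anchor frequency", {
  n <- 500
  fam <- generateFamily(n_positive = n, n_decoy = 0, conservation = 0.7,
                        seed = 22)
  starts <- signatureElements(fam$signature)$ref_start
  pats <- signatureElements(fam$signature)$pattern
  M <- do.call(rbind, strsplit(unname(fam$sequences), ""))
  for (e in seq_along(pats)) {
    pc <- strsplit(pats[e], "")[[1]]
    for (j in seq_along(pc)) {
      if (pc[j] == "x") next
      col <- starts[e] + j - 1
      k <- sum(M[, col] == pc[j])
      # planted with p = 0.7 plus 1/20 background on the unplanted rest
      p_eff <- 0.7 + 0.3 / 20
      ci <- binom.test(k, n, p_eff, conf.level = 0.99)$p.value
      expect_gt(ci, 0.001)
    }
  }
})

test_that("decoys never match and the truth table scores the pipeline", {
  fam <- family_fixture()
  decoys <- fam$sequences[fam$truth$id[!fam$truth$is_positive]]
  matches <- vapply(decoys, function(s)
    !is.null(matchSignature(s, fam$signature)), logical(1))
  expect_false(any(matches))
  # a one-element permissive signature makes rejection sampling impossible
  sig1 <- parseSignature("A")
  sig1@elements$ref_start <- 1L
  expect_error(generateFamily(n_positive = 1, n_decoy = 1,
                              signature = sig1, length = 300, seed = 1,
                              max_attempts = 50),
               "too permissive")
})

test_that("toy complex geometry honours its construction guarantees", {
  toy <- generateToyComplex(seed = 31)
  a <- atomTable(toy$structure)
  lig_xyz <- as.matrix(a[a$hetero, c("x", "y", "z")])
  min_dist_to_lig <- function(p)
    min(sqrt(colSums((t(lig_xyz) - p)^2)))
  prot <- a[!a$hetero, ]
  for (rn in unique(prot$resno)) {
    sub <- as.matrix(prot[prot$resno == rn, c("x", "y", "z")])
    dmin <- min(apply(sub, 1, min_dist_to_lig))
    if (rn %in% toy$contacts$resno) {
      expect_lte(dmin, 3.9)
    } else {
      expect_gt(dmin, 6.0)
    }
  }
  # zero planted contacts -> empty profile
  empty <- generateToyComplex(planted_contacts = integer(0),
                              contact_resnames = character(0),
                              axial_residue = NA, seed = 32)
  expect_error(empty, NA)
})

test_that("a contact-free complex yields an empty contact profile", {
  toy0 <- generateToyComplex(planted_contacts = 10L,
                             contact_resnames = "HIS",
                             axial_residue = 10L, seed = 33)
  lig <- extractLigand(toy0$structure, "LIG")
  prof <- findContacts(toy0$structure, lig, cutoff = 4)
  expect_equal(contactRecords(prof)$resno, 10L)
})
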