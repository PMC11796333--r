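contact_profile_at <- function(resno, resname, cutoff = 4) {
  rec <- data.frame(chain = "A", resno = as.integer(resno), icode = "",
                    resname = resname, min_dist = 3.5, via = "sidechain",
                    ligand_part = "C1", stringsAsFactors = FALSE)
  new("ContactProfile", records = rec, cutoff = cutoff, source = "test")
}

flat_conservation <- function(n, value = 1) {
  new("ConservationProfile", scores = rep(value, n),
      gap_fraction = rep(0, n), metric = "modal_fraction")
}

identity_map <- function(n)
  new("ColumnMap", reference_id = "ref", col_to_refpos = seq_len(n))

test_that("derivation merges nearby anchors and renders wildcards", {
  prof <- contact_profile_at(c(10, 13, 40, 41),
                             c("GLY", "TRP", "GLU", "HIS"))
  sig <- deriveSignature(prof, flat_conservation(60), identity_map(60),
                         tau = 0.8, merge_gap = 4)
  el <- signatureElements(sig)
  expect_equal(el$pattern, c("GxxW", "EH"))
  expect_equal(el$ref_start, c(10L, 40L))
  expect_equal(sig@region, c(10, 41))
  # separation 13 -> 40 is 26; tolerance round(26/4) = 6 -> {20, 32}
  expect_equal(gapRanges(sig), data.frame(min = 20L, max = 32L))
})

test_that("tau above every conservation score is an error", {
  prof <- contact_profile_at(c(10, 13), c("GLY", "TRP"))
  expect_error(
    deriveSignature(prof, flat_conservation(20, value = 0.5),
                    identity_map(20), tau = 0.9),
    "no conserved contact residues")
})

test_that("anchor set is monotone as tau is lowered", {
  prof <- contact_profile_at(c(5, 9, 15, 22),
                             c("GLY", "TRP", "GLU", "HIS"))
  cons <- new("ConservationProfile",
              scores = replace(rep(0.3, 30), c(5, 9, 15, 22),
                               c(1, 0.9, 0.7, 0.5)),
              gap_fraction = rep(0, 30), metric = "modal_fraction")
  anchors_at <- function(tau) {
    sig <- deriveSignature(prof, cons, identity_map(30), tau = tau,
                           merge_gap = 2)
    el <- signatureElements(sig)
    unlist(lapply(seq_len(nrow(el)), function(i) {
      p <- strsplit(el$pattern[i], "")[[1]]
      el$ref_start[i] + which(p != "x") - 1L
    }))
  }
  a_hi <- anchors_at(0.95); a_mid <- anchors_at(0.8); a_lo <- anchors_at(0.4)
  expect_true(all(a_hi %in% a_mid))
  expect_true(all(a_mid %in% a_lo))
  expect_equal(sort(a_lo), c(5, 9, 15, 22))
})

test_that("matching requires order, gaps and exact anchor letters", {
  sig <- parseSignature("GxxW{2,4}EH")
  m <- matchSignature("GAAWAAEH", sig)             # G1..W4, sep 2, EH at 7
  expect_false(is.null(m))
  expect_equal(elementStarts(m), c(1L, 7L))
  expect_equal(m@span, c(1L, 8L))
  # separation too small (EH immediately after W)
  expect_null(matchSignature("GAAWEHAAAA", sig))
  # separation too large
  expect_null(matchSignature("GAAWAAAAAAAEH", sig))
  # missing anchor letters entirely
  expect_null(matchSignature(strrep("ACDF", 10), sig))
  # self-match of the derived reference region
  fam <- family_fixture()
  expect_false(is.null(matchSignature(fam$reference, fam$signature)))
})

test_that("leftmost-tightest placement needs backtracking to stay correct", {
  # element 1 occurs early, but only the later occurrence can chain
  sig <- parseSignature("GW{1,2}EH")
  s <- "GWAAAAAAGWAEHAA"
  m <- matchSignature(s, sig)
  expect_equal(elementStarts(m), c(9L, 12L))
  expect_equal(elementStarts(m), bruteMatch(s, sig))
})

test_that("scanner agrees with the naive placement-enumeration oracle", {
  fam <- family_fixture()
  set.seed(9)
  ids <- c(sample(fam$truth$id[fam$truth$is_positive], 15),
           sample(fam$truth$id[!fam$truth$is_positive], 25))
  for (id in ids) {
    s <- fam$sequences[[id]]
    m <- matchSignature(s, fam$signature)
    o <- bruteMatch(s, fam$signature)
    if (is.null(o)) expect_null(m)
    else expect_equal(elementStarts(m), o)
  }
})

test_that("signature text form round-trips and rejects malformed input", {
  txt <- "GxxW{8,12}EH{30,40}GxxH{45,52}GxxxP"
  expect_equal(signatureToText(parseSignature(txt)), txt)
  expect_error(parseSignature("GxxWx{2,3}EH"), "specific residue")
  expect_error(parseSignature("xGW"), "specific residue")
  expect_error(parseSignature("GW{3,2}EH"), "gap max below")
  expect_error(parseSignature("GW{2,3}"), "trailing gap")
  expect_error(parseSignature("GW{2}EH"), "expected gap range")
  # randomized valid signatures round-trip byte-identically
  set.seed(10)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  for (i in 1:20) {
    k <- sample(1:4, 1)
    pats <- vapply(seq_len(k), function(j) {
      len <- sample(1:5, 1)
      p <- sample(c(aa, "x"), len, replace = TRUE)
      p[1] <- sample(aa, 1); p[len] <- sample(aa, 1)
      paste(p, collapse = "")
    }, character(1))
    gmin <- sample(0:10, k - 1, replace = TRUE)
    gmax <- gmin + sample(0:10, k - 1, replace = TRUE)
    txt <- if (k == 1) pats else
      paste0(paste0(pats[-k], sprintf("{%d,%d}", gmin, gmax),
                    collapse = ""), pats[k])
    expect_identical(signatureToText(parseSignature(txt)), txt)
  }
})

test_that("signature files persist text plus provenance sidecar", {
  fam <- family_fixture()
  f <- tempfile(fileext = ".txt")
  writeSignature(fam$signature, f, provenance = list(tau = 1.0))
  sig2 <- readSignature(f)
  expect_equal(signatureToText(sig2), signatureToText(fam$signature))
  expect_equal(signatureElements(sig2)$ref_start,
               signatureElements(fam$signature)$ref_start)
})
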