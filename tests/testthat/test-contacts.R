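test_that("planted pocket is recovered exactly and matches the oracle", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  prof <- findContacts(toy$structure, lig, cutoff = 4.0)
  rec <- contactRecords(prof)
  expect_equal(sort(rec$resno), sort(toy$contacts$resno))
  expect_true(all(rec$min_dist <= 4.0))
  # all-pairs brute-force oracle agrees exactly
  oracle <- bruteContacts(toy$structure, lig, cutoff = 4.0)
  expect_equal(rec$resno, oracle$resno)
  expect_equal(rec$min_dist, oracle$min_dist, tolerance = 1e-12)
})

test_that("contact set is monotone in the cutoff", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  cuts <- c(2.5, 3.5, 4.5, 7.0)
  sets <- lapply(cuts, function(cc)
    contactRecords(findContacts(toy$structure, lig, cutoff = cc))$resno)
  for (k in seq_len(length(cuts) - 1))
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
})

test_that("a far-away ligand yields an empty profile", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  a <- atomTable(lig)
  a[, c("x","y","z")] <- a[, c("x","y","z")] + 50
  far <- new("Ligand", source = "far", code = "LIG", atoms = a)
  expect_equal(nrow(contactRecords(findContacts(toy$structure, far))), 0L)
})

test_that("the axial metal ligand is the planted coordinating residue", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  ax <- axialLigand(toy$structure, lig, metal_element = "Co")
  expect_true(ax$found)
  expect_equal(ax$resno, toy$axial_residue)
  expect_equal(ax$resname, "HIS")
  expect_equal(ax$atom, "NE2")
  expect_equal(ax$dist, 2.2, tolerance = 1e-6)
  # nearest-atom oracle: no protein heavy atom is closer to the metal
  a <- atomTable(toy$structure)
  prot <- a[!a$hetero, ]
  m <- a[a$hetero & a$element == "Co", c("x","y","z")]
  d <- sqrt((prot$x - m$x)^2 + (prot$y - m$y)^2 + (prot$z - m$z)^2)
  expect_equal(min(d), ax$dist, tolerance = 1e-9)
  # the axial residue is always among contacts at cutoff = max_dist
  rec <- contactRecords(findContacts(toy$structure, lig, cutoff = 3.0))
  expect_true(ax$resno %in% rec$resno)
})

test_that("axial detection distinguishes no-ligand from error", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  a <- atomTable(lig)
  a[, c("x","y","z")] <- a[, c("x","y","z")] + 50
  far <- new("Ligand", source = "far", code = "LIG", atoms = a)
  res <- axialLigand(toy$structure, far)
  expect_false(res$found)          # valid no-axial-ligand result
  no_metal <- new("Ligand", source = "x", code = "LIG",
                  atoms = a[a$element != "Co", ])
  expect_error(axialLigand(toy$structure, no_metal), "no Co atom")
})

test_that("pose-ensemble contact frequencies count pose membership", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  shift <- function(l, dz) {
    a <- atomTable(l); a$z <- a$z + dz
    new("Ligand", source = "p", code = "LIG", atoms = a)
  }
  # single pose: all its contacts at frequency 1
  ps1 <- new("PoseSet", poses = list(lig), scores = NA_real_,
             engine_meta = "fixture")
  f1 <- contactRecords(contactFrequency(ps1, toy$structure, cutoff = 4))
  expect_true(all(f1$frequency == 1.0))
  # mixed ensemble: in-place poses keep the pocket, displaced ones lose it
  poses <- c(replicate(7, lig, simplify = FALSE),
             replicate(3, shift(lig, 50), simplify = FALSE))
  ps <- new("PoseSet", poses = poses, scores = rep(NA_real_, 10),
            engine_meta = "fixture")
  fr <- contactRecords(contactFrequency(ps, toy$structure, cutoff = 4))
  expect_true(all(fr$frequency == 0.7))
  expect_equal(sort(fr$resno), sort(toy$contacts$resno))
  # sorted by frequency desc then residue number
  expect_true(!is.unsorted(rev(fr$frequency)))
})
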