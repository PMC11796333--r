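test_that("centre of mass is the mass-weighted heavy-atom mean", {
  l1 <- make_ligand("C1", "C", matrix(c(1, 2, 3), 1))
  expect_equal(centerOfMass(l1), c(1, 2, 3))
  l2 <- make_ligand(c("C1", "C2"), c("C", "C"),
                    rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(centerOfMass(l2), c(1, 0, 0))
  # carbon at origin + oxygen at (1,0,0): x = mO / (mC + mO)
  l3 <- make_ligand(c("C1", "O1"), c("C", "O"),
                    rbind(c(0, 0, 0), c(1, 0, 0)))
  mC <- cofsig:::.element_masses("C"); mO <- cofsig:::.element_masses("O")
  expect_equal(centerOfMass(l3), c(mO / (mC + mO), 0, 0), tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms and direct formula", {
  l1 <- make_ligand("C1", "C", matrix(c(4, 5, 6), 1))
  expect_equal(radiusOfGyration(l1), 0)
  # two atoms 2 A apart -> Rg 1
  l2 <- make_ligand(c("C1", "N1"), c("C", "N"),
                    rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(radiusOfGyration(l2), 1.0)
  # 20 random atoms: independent direct evaluation of the formula
  set.seed(4)
  xyz <- random_coords(20)
  l3 <- make_ligand(paste0("C", 1:20), rep("C", 20), xyz)
  ctr <- colMeans(xyz)
  direct <- sqrt(sum(apply(xyz, 1, function(p) sum((p - ctr)^2))) / 20)
  expect_equal(radiusOfGyration(l3), direct, tolerance = 1e-9)
})

test_that("rg and centre behave correctly under rigid motion and scaling", {
  set.seed(5)
  xyz <- random_coords(8)
  l <- make_ligand(paste0("C", 1:8), rep("C", 8), xyz)
  R <- random_rotation(); t <- c(3, -2, 7)
  l2 <- make_ligand(paste0("C", 1:8), rep("C", 8),
                    xyz %*% t(R) + rep(t, each = 8))
  expect_equal(radiusOfGyration(l2), radiusOfGyration(l), tolerance = 1e-9)
  expect_equal(centerOfMass(l2),
               as.numeric(centerOfMass(l) %*% t(R) + t), tolerance = 1e-9)
  l3 <- make_ligand(paste0("C", 1:8), rep("C", 8), xyz * 2.5)
  expect_equal(radiusOfGyration(l3), 2.5 * radiusOfGyration(l),
               tolerance = 1e-9)
})

test_that("the docking box is Rg-sized, ratio-linear, and centred on mass", {
  l2 <- make_ligand(c("C1", "C2"), c("C", "C"),
                    rbind(c(0, 0, 0), c(2, 0, 0)))
  b1 <- dockingBox(l2)            # default ratio 1.0
  expect_equal(b1@ratio, 1.0)
  expect_equal(b1@edge, 1.0)
  expect_equal(b1@center, centerOfMass(l2))
  b2 <- dockingBox(l2, ratio = 2.5)
  expect_equal(b2@edge, 2.5)
  # strict monotonicity in ratio
  ratios <- c(0.5, 1, 1.5, 3)
  edges <- vapply(ratios, function(r) dockingBox(l2, r)@edge, numeric(1))
  expect_true(all(diff(edges) > 0))
  # degenerate single-atom ligand
  l1 <- make_ligand("C1", "C", matrix(0, 1, 3))
  expect_error(dockingBox(l1), "degenerate")
  expect_error(dockingBox(l2, ratio = -1), "positive")
  lines <- writeBoxParams(b1)
  expect_match(lines[1], "^center_x = ")
  expect_match(lines[4], "^size_x = 1.000")
})

test_that("pose ingestion verifies composition and sorts by score", {
  toy <- toy_fixture()
  lig <- extractLigand(toy$structure, "LIG")
  jitter_pose <- function(sd, path) {
    a <- atomTable(lig)
    set.seed(round(sd * 100))
    a[, c("x","y","z")] <- a[, c("x","y","z")] + rnorm(nrow(a) * 3, sd = sd)
    s <- new("PDBStructure", id = "pose", atoms = a)
    writeStructure(s, path)
    path
  }
  p1 <- jitter_pose(0.1, tempfile(fileext = ".pdb"))
  p2 <- jitter_pose(0.2, tempfile(fileext = ".pdb"))
  p3 <- jitter_pose(0.3, tempfile(fileext = ".pdb"))
  ps <- ingestPoses(c(p1, p2, p3), scores = c(-5.1, -7.3, -6.0))
  expect_equal(poseScores(ps), c(-7.3, -6.0, -5.1))
  expect_equal(length(poseLigands(ps)), 3L)
  # composition mismatch names the offending file
  bad <- tempfile(fileext = ".pdb")
  a <- atomTable(lig)[-1, ]
  writeStructure(new("PDBStructure", id = "bad", atoms = a), bad)
  expect_error(ingestPoses(c(p1, bad)), basename(bad))
})
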