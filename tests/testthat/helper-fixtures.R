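# Shared fixtures, built once per test run. All randomness is explicitly
# seeded so the suite is deterministic.

toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateToyComplex(seed = 101)
    cache
  }
})

family_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateFamily(n_positive = 50, n_decoy = 200, seed = 202)
    cache
  }
})

random_protein <- function(n, seed = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_coords <- function(n, sd = 3) matrix(rnorm(n * 3, sd = sd), n, 3)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# a tiny hand-written PDB with 4 atoms in one chain plus one het atom
write_tiny_pdb <- function(path, altloc_pair = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.500   2.400   0.200  1.00  0.00           O")
  if (altloc_pair) lines <- c(lines,
    "ATOM      5  CB AALA A   1       2.000  -1.000   0.500  0.50  0.00           C",
    "ATOM      6  CB BALA A   1       2.100  -1.100   0.600  0.50  0.00           C")
  lines <- c(lines,
    "HETATM    9 CO   B12 A 200       5.000   0.000   0.000  1.00  0.00          CO",
    "END")
  writeLines(lines, path)
  path
}

make_ligand <- function(names, elements, xyz) {
  atoms <- data.frame(
    serial = seq_along(names), name = names, altloc = "",
    resname = "LIG", chain = "L", resno = 1L, icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = elements, stringsAsFactors = FALSE)
  atoms$mass <- cofsig:::.element_masses(elements)
  atoms$hetero <- TRUE; atoms$hydrogen <- FALSE
  new("Ligand", source = "test", code = "LIG", atoms = atoms)
}

# path where the public reference data (PDB entries and sequences) would
# live if retrieved; the paper-number reproduction tests require them
reference_data_path <- function(file)
  system.file("extdata", "reference_data", file, package = "cofsig")
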