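# In-code fixtures shared across test files.

pdb_line <- function(rec, serial, name, alt, resid, chain, resno, x, y, z,
                     occ, elem) {
  name_f <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name_f, alt, resid, chain, resno, x, y, z, occ, 0, elem)
}

# Minimal PDB: one chain, one residue, three atoms.
write_minimal_pdb <- function(path) {
  writeLines(c(
    pdb_line("ATOM", 1, "N", " ", "ALA", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line("ATOM", 2, "CA", " ", "ALA", "A", 1, 1.458, 0, 0, 1, "C"),
    pdb_line("ATOM", 3, "C", " ", "ALA", "A", 1, 2.009, 1.42, 0, 1, "C"),
    "END"
  ), path)
  path
}

# Two altloc conformers (A occ 0.6, B occ 0.4) plus a water.
write_altloc_pdb <- function(path) {
  writeLines(c(
    pdb_line("ATOM", 1, "N", " ", "SER", "A", 1, 0, 0, 0, 1, "N"),
    pdb_line("ATOM", 2, "CA", " ", "SER", "A", 1, 1.458, 0, 0, 1, "C"),
    pdb_line("ATOM", 3, "OG", "A", "SER", "A", 1, 2.0, 1.0, 0, 0.6, "O"),
    pdb_line("ATOM", 4, "OG", "B", "SER", "A", 1, 2.0, -1.0, 0, 0.4, "O"),
    pdb_line("HETATM", 5, "O", " ", "HOH", "A", 101, 8, 8, 8, 1, "O"),
    "END"
  ), path)
  path
}

# A bare structure from an atom table; defaults give carbon atoms.
atoms_structure <- function(xyz, element = "C", name = element, chain = "A",
                            resno = seq_len(nrow(xyz)), resid = "ALA") {
  epifoot:::new_epi_structure("fixture", data.frame(
    serial = seq_len(nrow(xyz)), name = name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1, altloc = "",
    chain = chain, resno = resno, insert = "", resid = resid,
    is_hetero = FALSE, stringsAsFactors = FALSE))
}

# Independent Monte-Carlo Shrake-Rupley oracle: random (not spiral) surface
# points, brute-force all-against-all occlusion, no grid.
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_points = 1e5, seed = 42) {
  set.seed(seed)
  n <- nrow(xyz)
  total <- numeric(n)
  for (i in seq_len(n)) {
    p <- matrix(rnorm(3 * n_points), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * (radii[i] + probe)
    p <- sweep(p, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)[-i]) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 >= (radii[j] + probe)^2
    }
    total[i] <- mean(exposed) * 4 * pi * (radii[i] + probe)^2
  }
  total
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_structure <- function(s, rot, shift = c(0, 0, 0)) {
  m <- sweep(epifoot:::coords_matrix(s) %*% t(rot), 2, shift, "+")
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

mapped_fp <- function(areas, ref_len = 120) {
  structure(list(areas = areas,
                 unmapped = data.frame(source_position = integer(0), dsasa = numeric(0)),
                 reference_length = ref_len, provenance = "fixture"),
            class = "mapped_footprint")
}

# Directory for opt-in integration inputs (deposited structures, not
# shipped with the package).
integration_file <- function(name) {
  testthat::test_path("integration", name)
}
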