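# Shared fixtures, all generated in code at test time.

# ideal straight-helix calpha_set along a given axis direction
ideal_helix_points <- function(n = 20, rise = 1.5, twist = 100, radius = 2.3) {
  k <- 0:(n - 1)
  th <- k * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), k * rise)
}

as_calpha <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                      segment = NA_character_) {
  out <- data.frame(chain = chain, resno = resno, insert = "",
                    segment = segment,
                    label = paste0(chain, ":", resno),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("calpha_set", "data.frame")
  out
}

# hand-written three-atom PDB fixture
three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.500   3.250   4.125  1.00 10.00           C",
    "ATOM      3  C   ALA A   1       3.750   4.500   5.625  1.00 10.00           C",
    "END"), path)
  path
}

# PDB fixture with alternate locations of differing occupancy
altloc_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.60 10.00           C",
    "ATOM      3  CA AALA A   2       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BALA A   2       8.000   9.000   9.000  0.50 10.00           C",
    "ATOM      5  CA  ALA A   3       2.000   0.000   0.000  1.00 10.00           C",
    "END"), path)
  path
}

# default two-domain test bundle (noise-free unless stated)
test_bundle <- function(noise_sd = 0, seed = 1, ...) {
  make_bundle(bundle_spec(noise_sd = noise_sd, seed = seed, ...))
}
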