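# fixtures built in code at test time; all stochastic pieces take fixed seeds

pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z, occ = 1,
                     b = 0, element = "") {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, resn, chain, resno, x, y, z, occ, b,
          element)
}

write_two_model_fixture <- function(path) {
  lines <- c(
    "MODEL        1",
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", " ", "ALA", "A", 1, 1.458, 0, 0, element = "C"),
    pdb_line(3, "CA", " ", "GLY", "A", 2, 3.0, 1.0, 0, element = "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 9, element = "N"),
    pdb_line(2, "CA", " ", "ALA", "A", 1, 1.458, 0, 9, element = "C"),
    pdb_line(3, "CA", " ", "GLY", "A", 2, 3.0, 1.0, 9, element = "C"),
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

write_altloc_fixture <- function(path, occ_a = 0.6, occ_b = 0.4) {
  lines <- c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, element = "N"),
    pdb_line(2, "CA", "A", "ALA", "A", 1, 1.458, 0, 0, occ = occ_a, element = "C"),
    pdb_line(3, "CA", "B", "ALA", "A", 1, 1.558, 0.1, 0, occ = occ_b, element = "C"),
    "END")
  writeLines(lines, path)
  path
}

# deterministic -RHStaple toy cystine used across files
toy_cystine <- function(chi = c(-60, -90, 100, -90, -60), ...) {
  gen_disulfide_model(chi, ...)
}

# a single isolated atom as a structure (for analytic-sphere ASA checks)
single_atom_structure <- function(element = "S", atom_name = "SG") {
  new_structure(tibble::tibble(atom_name = atom_name, res_name = "CYS",
                               chain_id = "A", res_seq = 1L,
                               x = 0, y = 0, z = 0, element = element))
}

# atom enclosed by a tight cage of neighbours (buried limit)
caged_atom_structure <- function(n_cage = 200, r_cage = 2.2) {
  i <- seq_len(n_cage) - 0.5
  phi <- acos(1 - 2 * i / n_cage)
  theta <- pi * (1 + sqrt(5)) * i
  cage <- tibble::tibble(
    atom_name = paste0("C", seq_len(n_cage)), res_name = "CAG",
    chain_id = "A", res_seq = 2L,
    x = r_cage * sin(phi) * cos(theta),
    y = r_cage * sin(phi) * sin(theta),
    z = r_cage * cos(phi),
    element = "C")
  centre <- tibble::tibble(atom_name = "SG", res_name = "CYS", chain_id = "A",
                           res_seq = 1L, x = 0, y = 0, z = 0, element = "S")
  new_structure(dplyr::bind_rows(centre, cage))
}

# brute-force min distance oracle: explicit double loop
brute_min_distance <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}
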