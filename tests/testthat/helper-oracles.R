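# Independent oracles and small fixture builders shared across tests.

# brute-force union-find over all point pairs: the reference answer for
# single-linkage clustering at a distance threshold
union_find_cluster <- function(pts, cutoff) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sqrt(sum((pts[i, ] - pts[j, ])^2)) <= cutoff) {
          ri <- find_root(i)
          rj <- find_root(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find_root, integer(1))
}

# canonical form of a cluster labeling, so partitions can be compared
# independently of label values
canon_partition <- function(cl) match(cl, unique(cl))

# a tiny atom tibble builder for hand-constructed scoring geometries
atom_row <- function(x, y, z, element = "O", name = "OD1", resid = "ASP",
                     record_kind = "protein", donor = FALSE,
                     acceptor = TRUE, aromatic = FALSE, serial = 1L) {
  tibble::tibble(
    serial = as.integer(serial), name = name, resid = resid, chain = "A",
    resno = as.integer(serial), x = x, y = y, z = z, element = element,
    record_kind = record_kind, is_donor = donor, is_acceptor = acceptor,
    is_carbon = element == "C", is_aromatic = aromatic, is_polar_h = FALSE
  )
}

write_lines_tmp <- function(lines, ext = ".pdb") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

minimal_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  O   ALA A   1      12.345   7.000  -4.500  1.00  0.00           O",
    "ATOM      3  CB  ALA A   1      10.000   5.000  -5.000  1.00  0.00           C",
    "ATOM      4  NZ  LYS A   2       8.000   5.000  -5.000  1.00  0.00           N",
    "HETATM    5  O   HOH A 101       1.000   2.000   3.000  1.00  0.00           O",
    "HETATM    6 NA    NA A 102       5.000   5.000   5.000  1.00  0.00          NA",
    "END"
  )
}

pdbqt_lines <- function(scores, coords = NULL) {
  coords <- coords %||% lapply(seq_along(scores), function(i) c(i, 0, 0))
  unlist(lapply(seq_along(scores), function(m) {
    c(sprintf("MODEL %d", m),
      sprintf("REMARK VINA RESULT:    %8.3f      0.000      0.000", scores[m]),
      sprintf("HETATM    1  O   HOH A   1    %8.3f%8.3f%8.3f  1.00  0.00           O",
              coords[[m]][1], coords[[m]][2], coords[[m]][3]),
      "ENDMDL")
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
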