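# Shared fixtures, all built in code.

EAS <- hydrophobinr::eas_delta15_sequence()

# residue tibble from a coordinate matrix
make_residues <- function(xyz, aa = NULL) {
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep("A", n)
  tibble::tibble(
    chain = "A", resno = seq_len(n), icode = "",
    aa = aa,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    sg_x = NA_real_, sg_y = NA_real_, sg_z = NA_real_,
    confidence = 0
  )
}

# equilateral triangle in the xy plane with the given side length
triangle_residues <- function(side) {
  make_residues(side * rbind(
    c(0, 0, 0),
    c(1, 0, 0),
    c(0.5, sqrt(3) / 2, 0)
  ))
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  cross <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
                  byrow = TRUE)
  diag(3) * c + s * cross + (1 - c) * outer(a, a)
}

coords_of <- function(residues) as.matrix(residues[, c("x", "y", "z")])

# minimal PDB text: CA atoms at given coordinates
minimal_pdb <- function(xyz, bfactor = 0, resname = "ALA") {
  paste(vapply(seq_len(nrow(xyz)), function(i) {
    sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i, resname, i, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1,
      if (length(bfactor) > 1) bfactor[i] else bfactor
    )
  }, character(1)), collapse = "\n")
}
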