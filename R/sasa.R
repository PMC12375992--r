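#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point quadrature: each heavy atom is expanded by the probe radius
#' and sampled with a deterministic Fibonacci point lattice; a sample point
#' is accessible when it lies outside every neighbouring expanded sphere.
#' Van der Waals radii follow the Bondi set; the default 960 points per
#' atom keep the quadrature error on an isolated sphere well under 1%.
#'
#' @param atoms Atom tibble (e.g. one element of the `atoms` list-column
#'   from [read_structure()], or [residues_as_atoms()] for backbone-level
#'   synthetic structures) with columns `x`, `y`, `z`, `element`, `resno`.
#'   Hydrogens and waters are excluded.
#' @param probe Probe (solvent) radius in Angstrom, default 1.4.
#' @param n_points Sample points per atom, default 960.
#' @return List with `total` (Angstrom^2), `per_residue` (tibble `resno`,
#'   `area`) and `per_atom` (numeric vector).
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  keep <- atoms$element != "H"
  if ("resname" %in% names(atoms)) keep <- keep & atoms$resname != "HOH"
  atoms <- atoms[keep, ]
  n <- nrow(atoms)
  if (n == 0) abort("no heavy atoms for surface-area computation")

  radii <- BONDI_RADII[toupper(atoms$element)]
  missing <- is.na(radii)
  if (any(missing)) {
    warn(paste0(
      "unknown element(s) ",
      paste(unique(atoms$element[missing]), collapse = ", "),
      "; using default radius ", BONDI_DEFAULT_RADIUS, " A"
    ))
    radii[missing] <- BONDI_DEFAULT_RADIUS
  }
  radii <- unname(radii)

  # exact duplicate atom records (same position and element) carry no extra
  # surface; keep the first of each
  dup <- duplicated(data.frame(atoms$x, atoms$y, atoms$z, radii))
  atoms <- atoms[!dup, ]
  radii <- radii[!dup]
  n <- nrow(atoms)

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pts <- fibonacci_sphere(n_points)
  ext <- radii + probe

  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nbr <- which(d < ext[i] + ext & seq_len(n) != i)
    p <- sweep(pts * ext[i], 2, xyz[i, ], `+`)
    if (length(nbr) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nbr) {
        dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
        acc <- acc & dj2 >= ext[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    per_atom[i] <- frac * 4 * pi * ext[i]^2
  }

  per_residue <- tibble(resno = atoms$resno, area = per_atom) |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
  list(total = sum(per_atom), per_residue = per_residue, per_atom = per_atom)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Backbone-level atom table from a residue tibble
#'
#' Turns a residue table (Calpha plus optional cysteine Sulfur-gamma
#' coordinates) into the atom-table layout expected by
#' [shrake_rupley_sasa()], for synthetic or backbone-only structures.
#'
#' @param residues Residue tibble.
#' @return Atom tibble with `resno`, `atom`, `element`, `x`, `y`, `z`.
#' @export
residues_as_atoms <- function(residues) {
  ca <- tibble(
    resno = residues$resno, atom = "CA", element = "C",
    x = residues$x, y = residues$y, z = residues$z
  )
  if (!is.null(residues$sg_x)) {
    has <- !is.na(residues$sg_x)
    sg <- tibble(
      resno = residues$resno[has], atom = "SG", element = "S",
      x = residues$sg_x[has], y = residues$sg_y[has], z = residues$sg_z[has]
    )
    ca <- dplyr::bind_rows(ca, sg)
  }
  dplyr::arrange(ca, .data$resno)
}
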