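#' Detect disulfide bonds and map their topology
#'
#' Pairs cysteine Sulfur-gamma atoms by greedy minimum-distance matching
#' under a covalent cutoff (an S-S bond is ~2.05 A; the default 2.5 A
#' excludes non-bonded contacts). Bonds are reported on cysteine ordinals,
#' i.e. the sequence order of the cysteines (C1, C2, ...), and compared with
#' the canonical hydrophobin topology C1-C6, C2-C5, C3-C4, C7-C8. Ties in
#' the greedy matching are broken by ascending (distance, lower ordinal),
#' which makes the result deterministic and independent of atom input
#' order.
#'
#' @param residues Residue tibble (from [read_structure()] /
#'   [model_residues()]) with `sg_x/sg_y/sg_z` for cysteines.
#' @param cutoff Maximum S-S distance in Angstrom (default 2.5).
#' @param reference Optional residue tibble of a structure with canonical
#'   topology; when given and the model is non-canonical, each model bond is
#'   mapped to the spatially nearest canonical bond after superposition.
#' @return An object of class `disulfide_topology`: list with `bonds`
#'   (tibble `ordinal_i`, `ordinal_j`, `resno_i`, `resno_j`, `distance`),
#'   `free_cys` (unpaired ordinals), `canonical_match` flag and
#'   `mapping_to_canonical` (tibble or `NULL`). Cysteines left unpaired
#'   under the cutoff are reported as free, not as an error.
#' @export
detect_disulfides <- function(residues, cutoff = 2.5, reference = NULL) {
  cys <- which(residues$aa == "C")
  sg <- cbind(residues$sg_x[cys], residues$sg_y[cys], residues$sg_z[cys])
  has_sg <- stats::complete.cases(sg)
  ord <- seq_along(cys)

  bonds <- tibble(
    ordinal_i = integer(), ordinal_j = integer(),
    resno_i = integer(), resno_j = integer(), distance = numeric()
  )
  if (sum(has_sg) >= 2) {
    idx <- which(has_sg)
    pairs <- utils::combn(idx, 2)
    d <- sqrt(rowSums((sg[pairs[1, ], , drop = FALSE] -
                         sg[pairs[2, ], , drop = FALSE])^2))
    keep <- d <= cutoff
    pairs <- pairs[, keep, drop = FALSE]
    d <- d[keep]
    o <- order(d, pairs[1, ], pairs[2, ])
    used <- logical(length(cys))
    for (k in o) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      bonds <- dplyr::bind_rows(bonds, tibble(
        ordinal_i = ord[i], ordinal_j = ord[j],
        resno_i = residues$resno[cys[i]], resno_j = residues$resno[cys[j]],
        distance = d[k]
      ))
    }
    free <- ord[!used]
  } else {
    free <- ord
  }
  bonds <- dplyr::arrange(bonds, .data$ordinal_i)

  canon <- CANONICAL_DISULFIDES
  bond_set <- purrr::map2(bonds$ordinal_i, bonds$ordinal_j, c)
  canonical_match <- length(bond_set) == length(canon) &&
    all(purrr::map_lgl(canon, function(b) {
      any(purrr::map_lgl(bond_set, identical, y = b))
    }))

  mapping <- NULL
  if (!canonical_match && !is.null(reference) && nrow(bonds) > 0) {
    mapping <- map_bonds_to_canonical(residues, bonds, reference)
  }

  structure(
    list(
      bonds = bonds, free_cys = free,
      canonical_match = canonical_match,
      mapping_to_canonical = mapping
    ),
    class = "disulfide_topology"
  )
}

# Superpose the model onto a canonical reference (sequence-based pairing of
# Calpha atoms) and assign each model bond to the nearest canonical
# reference bond by SG-midpoint distance.
map_bonds_to_canonical <- function(residues, bonds, reference) {
  pr <- pair_residues(residues, reference)
  if (nrow(pr) < 3) return(NULL)
  mob <- as.matrix(residues[pr$idx_model, c("x", "y", "z")])
  ref <- as.matrix(reference[pr$idx_ref, c("x", "y", "z")])
  fit <- kabsch_superpose(mob, ref)

  ref_top <- detect_disulfides(reference)
  if (nrow(ref_top$bonds) == 0) return(NULL)
  ref_cys <- which(reference$aa == "C")
  mod_cys <- which(residues$aa == "C")
  mid <- function(res, cysidx, b) {
    (c(res$sg_x[cysidx[b[1]]], res$sg_y[cysidx[b[1]]], res$sg_z[cysidx[b[1]]]) +
       c(res$sg_x[cysidx[b[2]]], res$sg_y[cysidx[b[2]]], res$sg_z[cysidx[b[2]]])) / 2
  }
  ref_mids <- t(apply(ref_top$bonds[, c("ordinal_i", "ordinal_j")], 1,
                      function(b) mid(reference, ref_cys, b)))
  purrr::map(seq_len(nrow(bonds)), function(k) {
    m <- mid(residues, mod_cys, c(bonds$ordinal_i[k], bonds$ordinal_j[k]))
    m2 <- drop(fit$rotation %*% m + fit$translation)
    j <- which.min(sqrt(rowSums(sweep(ref_mids, 2, m2)^2)))
    tibble(
      bond = paste0("C", bonds$ordinal_i[k], "-C", bonds$ordinal_j[k]),
      maps_to = paste0("C", ref_top$bonds$ordinal_i[j], "-C",
                       ref_top$bonds$ordinal_j[j]),
      midpoint_distance = sqrt(sum((ref_mids[j, ] - m2)^2))
    )
  }) |>
    dplyr::bind_rows()
}

#' @export
print.disulfide_topology <- function(x, ...) {
  cat("Disulfide topology:", nrow(x$bonds), "bond(s),",
      length(x$free_cys), "free cysteine(s)\n")
  if (nrow(x$bonds) > 0) {
    cat(paste0(
      "  C", x$bonds$ordinal_i, "-C", x$bonds$ordinal_j,
      sprintf(" (%.2f A)", x$bonds$distance),
      collapse = "\n"
    ), "\n")
  }
  cat("Canonical C1-C6/C2-C5/C3-C4/C7-C8 pattern:",
      if (x$canonical_match) "yes" else "no", "\n")
  invisible(x)
}

#' @export
tidy.disulfide_topology <- function(x, ...) x$bonds

#' @export
glance.disulfide_topology <- function(x, ...) {
  tibble(
    n_bonds = nrow(x$bonds),
    n_free_cys = length(x$free_cys),
    canonical_match = x$canonical_match
  )
}
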