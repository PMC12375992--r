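#' All-vs-all structural distance matrix
#'
#' Pairwise TM-scores computed in both normalisation directions and
#' averaged; distance = 1 - mean bidirectional TM-score, which is
#' symmetric, bounded in \[0, 1\] and length-aware. Labels are sorted
#' lexicographically so the matrix (and any downstream tree) is invariant
#' to input order.
#'
#' @param models Named list of residue tibbles (>= 2 entries, >= 3 residues
#'   each).
#' @return Object of class `structure_dist`: symmetric matrix with zero
#'   diagonal and sorted labels.
#' @export
structure_distance_matrix <- function(models) {
  if (length(models) < 2) abort("need at least 2 structures")
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    abort("models must be a named list")
  }
  models <- models[order(names(models))]
  labels <- names(models)
  n <- length(models)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pairing <- pair_residues(models[[i]], models[[j]])
      if (nrow(pairing) < 3) {
        abort(paste0(
          "fewer than 3 aligned residues between '", labels[i],
          "' and '", labels[j], "'"
        ))
      }
      tm_ij <- tm_score(models[[i]], models[[j]], pairing)$tm_score
      tm_ji <- tm_score(
        models[[j]], models[[i]],
        tibble(idx_model = pairing$idx_ref, idx_ref = pairing$idx_model)
      )$tm_score
      d[i, j] <- d[j, i] <- 1 - (tm_ij + tm_ji) / 2
    }
  }
  structure(d, class = c("structure_dist", "matrix"))
}

#' UPGMA tree from a structural distance matrix
#'
#' Average-linkage agglomeration on the distance matrix; node heights are
#' half the merge distance, so the tree is ultrametric and leaf-to-root
#' depths are equal. Ties are broken deterministically by the
#' lexicographic label order baked into the matrix.
#'
#' @param d Symmetric distance matrix (e.g. from
#'   [structure_distance_matrix()]), zero diagonal, non-negative.
#' @return Object of class `clade_tree`: list with `hclust`, `phylo`
#'   (\pkg{ape}), `newick` (text with branch lengths) and `labels`.
#' @export
upgma_tree <- function(d) {
  d <- unclass(as.matrix(d))
  if (any(d < 0)) abort("negative distances")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix is not symmetric")
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  structure(
    list(
      hclust = hc,
      phylo = phy,
      newick = ape::write.tree(phy),
      labels = hc$labels
    ),
    class = "clade_tree"
  )
}

#' Cut an ultrametric tree into k clades
#'
#' Cuts the UPGMA tree at the height yielding exactly `k` subtrees (the
#' lower of tied heights) and numbers the clades by the lexicographically
#' first label they contain.
#'
#' @param tree A `clade_tree` from [upgma_tree()].
#' @param k Number of clades, between 1 and the leaf count.
#' @return Tibble with `label` and `clade` (integer index).
#' @export
assign_clades <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) abort(paste0("k must be in [1, ", n, "]"))
  cl <- cutree(tree$hclust, k = k)
  first_label <- tapply(names(cl), cl, min)
  new_index <- rank(first_label)  # order clades by first-leaf label
  tibble(
    label = sort(names(cl)),
    clade = as.integer(new_index[as.character(cl[sort(names(cl))])])
  )
}

#' Write a clade tree to a Newick file
#' @param tree A `clade_tree`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_newick <- function(tree, file) {
  writeLines(tree$newick, file)
  invisible(file)
}

#' @export
print.clade_tree <- function(x, ...) {
  cat("UPGMA clade tree with", length(x$labels), "leaves\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
tidy.clade_tree <- function(x, ...) {
  m <- x$hclust$merge
  tibble(
    step = seq_len(nrow(m)),
    height = x$hclust$height,
    left = m[, 1],
    right = m[, 2]
  )
}

#' @export
glance.clade_tree <- function(x, ...) {
  tibble(
    n_leaves = length(x$labels),
    max_height = max(x$hclust$height)
  )
}

#' @export
plot.clade_tree <- function(x, k = NULL, ...) {
  if (!is.null(k)) {
    cl <- assign_clades(x, k)
    cols <- grDevices::hcl.colors(k, "Dark 3")[cl$clade[match(x$phylo$tip.label, cl$label)]]
    ape::plot.phylo(x$phylo, tip.color = cols, ...)
  } else {
    ape::plot.phylo(x$phylo, ...)
  }
  invisible(x)
}

#' iTOL-style clade annotation table
#'
#' @param tree A `clade_tree`.
#' @param k Number of clades.
#' @return Tibble `label`, `clade`, `color` (hex), ready for TSV export.
#' @export
clade_annotation <- function(tree, k) {
  cl <- assign_clades(tree, k)
  pal <- grDevices::hcl.colors(k, "Dark 3")
  dplyr::mutate(cl, color = pal[.data$clade])
}
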