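#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares superposition of a mobile onto a reference point set via
#' singular value decomposition of the covariance matrix, with the
#' determinant correction that enforces a proper rotation (no reflection).
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates
#'   (Angstrom), n >= 3 and not all collinear.
#' @return List with `rotation` (3 x 3), `translation` (length 3) mapping
#'   mobile onto reference as `R x + t`, and `rmsd` (Angstrom) after
#'   superposition.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) abort("coordinate sets differ in length")
  if (nrow(mobile) < 3) abort("need at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  if (is_collinear(a) || is_collinear(b)) {
    abort("degenerate (collinear) coordinates: rotation is underdetermined")
  }
  h <- t(a) %*% b
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- a %*% t(rot)
  list(
    rotation = rot,
    translation = as.numeric(cr - rot %*% cm),
    rmsd = sqrt(mean(rowSums((fitted - b)^2)))
  )
}

is_collinear <- function(centered, tol = 1e-9) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1e-300)
}

#' Residue correspondence between two structures
#'
#' Index pairing when the two sequences are identical; otherwise a global
#' alignment (match +1, mismatch -1, linear gap -2) and the aligned non-gap
#' pairs. Residues missing from either partner are dropped from the
#' pairing.
#'
#' @param model,reference Residue tibbles.
#' @return Tibble with `idx_model`, `idx_ref` (row indices into each
#'   residue table).
#' @export
pair_residues <- function(model, reference) {
  sm <- residue_sequence(model)
  sr <- residue_sequence(reference)
  if (identical(sm, sr)) {
    n <- nchar(sm)
    return(tibble(idx_model = seq_len(n), idx_ref = seq_len(n)))
  }
  letters_all <- sort(unique(c(strsplit(sm, "")[[1]], strsplit(sr, "")[[1]],
                               AA_STANDARD)))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sm), Biostrings::AAString(sr),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
    type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  im <- ir <- 0L
  idx_model <- idx_ref <- integer()
  for (k in seq_along(pa)) {
    if (pa[k] != "-") im <- im + 1L
    if (sa[k] != "-") ir <- ir + 1L
    if (pa[k] != "-" && sa[k] != "-") {
      idx_model <- c(idx_model, im)
      idx_ref <- c(idx_ref, ir)
    }
  }
  tibble(idx_model = idx_model, idx_ref = idx_ref)
}

ca_coords <- function(residues, idx) {
  as.matrix(residues[idx, c("x", "y", "z")])
}

#' TM-score of a model against a reference structure
#'
#' Template modeling score: `TM = (1/Lref) * sum_i 1/(1 + (d_i/d0)^2)`
#' maximised over rigid superpositions, with the length-dependent
#' normalisation `d0 = 1.24 (Lref - 15)^(1/3) - 1.8`, floored at 0.5 A for
#' short chains. `Lref` is the reference (experimental) chain length.
#' The maximisation seeds superpositions from the full aligned chain and
#' from contiguous fragments of half and quarter length at sliding
#' offsets; each seed is refined by repeatedly re-superposing on the
#' residues within `max(d0, 4.5)` A until the inlier set is stable, and the
#' best score over all seeds and iterations is reported.
#'
#' @param model,reference Residue tibbles.
#' @param pairing Optional correspondence from [pair_residues()].
#' @return List with `tm_score`, `d0` and `n_aligned`.
#' @export
tm_score <- function(model, reference, pairing = NULL) {
  if (is.null(pairing)) pairing <- pair_residues(model, reference)
  if (nrow(pairing) < 3) abort("fewer than 3 corresponding residue pairs")
  lref <- nrow(reference)
  d0 <- if (lref > 15) max(0.5, 1.24 * (lref - 15)^(1 / 3) - 1.8) else 0.5
  mob <- ca_coords(model, pairing$idx_model)
  ref <- ca_coords(reference, pairing$idx_ref)
  la <- nrow(mob)

  frag_lens <- unique(pmax(4L, c(la, floor(la / 2), floor(la / 4))))
  frag_lens <- frag_lens[frag_lens <= la]
  seeds <- list()
  for (fl in frag_lens) {
    step <- max(1L, floor(fl / 2))
    offs <- unique(c(seq(1L, la - fl + 1L, by = step), la - fl + 1L))
    for (o in offs) seeds[[length(seeds) + 1L]] <- seq(o, o + fl - 1L)
  }

  inlier_cut <- max(d0, 4.5)
  best <- 0
  for (seed in seeds) {
    subset <- seed
    for (iter in 1:30) {
      fit <- tryCatch(kabsch_superpose(mob[subset, , drop = FALSE],
                                       ref[subset, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(fit)) break
      moved <- sweep(mob %*% t(fit$rotation), 2, fit$translation, `+`)
      di <- sqrt(rowSums((moved - ref)^2))
      best <- max(best, sum(1 / (1 + (di / d0)^2)) / lref)
      inliers <- which(di < inlier_cut)
      if (length(inliers) < 3 || identical(inliers, subset)) break
      subset <- inliers
    }
  }
  list(tm_score = best, d0 = d0, n_aligned = la)
}

#' lDDT-Calpha of a model against a reference structure
#'
#' Superposition-free local distance difference test restricted to Calpha
#' atoms: over all residue pairs whose reference Calpha-Calpha distance is
#' below the 15 A inclusion radius, the score is the mean (over tolerances
#' 0.5, 1, 2, 4 A) of the fraction of pairs whose distance is preserved
#' within the tolerance.
#'
#' @param model,reference Residue tibbles.
#' @param pairing Optional correspondence from [pair_residues()].
#' @param inclusion_radius Reference distance cutoff in Angstrom (15).
#' @param tolerances Preservation thresholds in Angstrom.
#' @return Score in \[0, 1\].
#' @export
lddt_ca <- function(model, reference, pairing = NULL,
                    inclusion_radius = 15, tolerances = c(0.5, 1, 2, 4)) {
  if (is.null(pairing)) pairing <- pair_residues(model, reference)
  if (nrow(pairing) < 2) abort("fewer than 2 corresponding residue pairs")
  mob <- ca_coords(model, pairing$idx_model)
  ref <- ca_coords(reference, pairing$idx_ref)
  dref <- as.matrix(dist(ref))
  dmod <- as.matrix(dist(mob))
  mask <- upper.tri(dref) & dref < inclusion_radius
  if (!any(mask)) abort("no residue pairs within the inclusion radius")
  diffs <- abs(dmod[mask] - dref[mask])
  mean(purrr::map_dbl(tolerances, function(t) mean(diffs < t)))
}

#' Benchmark a predicted model against an experimental structure
#'
#' Computes Calpha RMSD (after Kabsch superposition), TM-score and
#' lDDT-Calpha of the predicted model against every member of the
#' experimental ensemble, and reports the member with the lowest Calpha
#' RMSD (the convention for NMR ensembles). Quality flags apply the
#' standard cut-offs: RMSD < 2.5 A, lDDT-Calpha > 0.6, TM-score > 0.6.
#'
#' @param predicted Residue tibble (or single-model ensemble tibble).
#' @param experimental Ensemble tibble from [read_structure()], a residue
#'   tibble, or a list of residue tibbles.
#' @param rmsd_cutoff,lddt_cutoff,tm_cutoff Quality cut-offs.
#' @return One-row tibble: `rmsd`, `tm_score`, `lddt_ca`, `n_aligned`,
#'   `d0`, `chosen_model_index`, `rmsd_good`, `lddt_good`, `tm_good`.
#' @export
benchmark_model <- function(predicted, experimental,
                            rmsd_cutoff = 2.5, lddt_cutoff = 0.6,
                            tm_cutoff = 0.6) {
  predicted <- as_residue_list(predicted)
  if (length(predicted) != 1) abort("predicted structure must be single-model")
  predicted <- predicted[[1]]
  members <- as_residue_list(experimental)
  if (length(members) == 0) abort("empty experimental ensemble")

  rows <- purrr::imap(members, function(ref, m) {
    pairing <- pair_residues(predicted, ref)
    if (nrow(pairing) < 3) abort("fewer than 3 corresponding residue pairs")
    fit <- kabsch_superpose(ca_coords(predicted, pairing$idx_model),
                            ca_coords(ref, pairing$idx_ref))
    tm <- tm_score(predicted, ref, pairing)
    tibble(
      rmsd = fit$rmsd,
      tm_score = tm$tm_score,
      lddt_ca = lddt_ca(predicted, ref, pairing),
      n_aligned = nrow(pairing),
      d0 = tm$d0,
      chosen_model_index = as.integer(m)
    )
  }) |>
    dplyr::bind_rows()

  best <- rows[which.min(rows$rmsd), ]
  dplyr::mutate(
    best,
    rmsd_good = .data$rmsd < rmsd_cutoff,
    lddt_good = .data$lddt_ca > lddt_cutoff,
    tm_good = .data$tm_score > tm_cutoff
  )
}

as_residue_list <- function(x) {
  if (is.data.frame(x)) {
    if ("residues" %in% names(x)) return(x$residues)  # ensemble tibble
    return(list(x))
  }
  if (is.list(x)) return(x)
  abort("expected a residue tibble, ensemble tibble, or list of residue tibbles")
}

#' Batch benchmark over predicted/experimental structure pairs
#'
#' @param pairs Tibble with columns `id`, `predicted`, `experimental`
#'   (each a file path, ensemble tibble or residue tibble; list-columns
#'   allowed) and optionally `class_label`.
#' @inheritParams benchmark_model
#' @return Tibble of per-pair [benchmark_model()] rows, with `id` and
#'   `class_label` carried through. Summarise with
#'   [summarise_benchmark()].
#' @export
benchmark_models <- function(pairs, rmsd_cutoff = 2.5, lddt_cutoff = 0.6,
                             tm_cutoff = 0.6) {
  load_struct <- function(x) {
    if (is.character(x)) read_structure(x) else x
  }
  purrr::map(seq_len(nrow(pairs)), function(i) {
    pred <- load_struct(if (is.list(pairs$predicted)) pairs$predicted[[i]] else pairs$predicted[i])
    expt <- load_struct(if (is.list(pairs$experimental)) pairs$experimental[[i]] else pairs$experimental[i])
    res <- benchmark_model(pred, expt, rmsd_cutoff, lddt_cutoff, tm_cutoff)
    res$id <- pairs$id[i]
    res$class_label <- if ("class_label" %in% names(pairs)) {
      pairs$class_label[i]
    } else {
      "unknown"
    }
    dplyr::relocate(res, "id", "class_label")
  }) |>
    dplyr::bind_rows()
}

#' Per-class mean and standard deviation of benchmark metrics
#'
#' @param results Tibble from [benchmark_models()].
#' @return Tibble with one row per class: n, mean and sd of RMSD,
#'   lDDT-Calpha and TM-score, and the fraction of pairs passing each
#'   quality cut-off.
#' @export
summarise_benchmark <- function(results) {
  results |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      rmsd_mean = mean(.data$rmsd), rmsd_sd = sd(.data$rmsd),
      lddt_mean = mean(.data$lddt_ca), lddt_sd = sd(.data$lddt_ca),
      tm_mean = mean(.data$tm_score), tm_sd = sd(.data$tm_score),
      frac_rmsd_good = mean(.data$rmsd_good),
      frac_lddt_good = mean(.data$lddt_good),
      frac_tm_good = mean(.data$tm_good),
      .groups = "drop"
    )
}
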