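#' Scan a sequence for the hydrophobin cysteine motif
#'
#' Hydrophobins carry eight cysteines in the pattern
#' `C-Xa-CC-Xb-C-Xc-C-Xd-CC-Xe-C`: cysteine ordinals 2-3 and 6-7 are
#' adjacent doublets and the remaining five intercysteine segments are loops
#' whose lengths are bounded by `spacing_min`/`spacing_max`. The scan walks
#' the sequence's cysteine positions left to right and greedily emits every
#' non-overlapping window of eight consecutive cysteines matching the
#' pattern, so multi-domain (polyhydrophobin) chains yield one motif per
#' domain.
#'
#' @param residues A single one-letter sequence.
#' @param spacing_min,spacing_max Allowed residue counts in non-doublet
#'   intercysteine segments (defaults 1 and 75; doublet segments are fixed
#'   at 0).
#' @param decet If `TRUE`, additionally match ten-cysteine windows (the
#'   five-disulfide variant): every gap must be 0 or within bounds and at
#'   least two doublets must be present. Ordinals are positional
#'   (C1...C10 in sequence order).
#' @return A tibble with one row per motif: `motif_index`, `n_cys`,
#'   `start`, `end`, and list-columns `positions` (1-based cysteine
#'   positions), `spacing` (residues between consecutive cysteines),
#'   `doublets` (ordinal pairs with zero spacing) and `loops` (a tibble of
#'   loop name, start, end, subsequence). Zero rows when no motif matches.
#' @examples
#' eas <- "SATTIGPNTCSIDDYKPYCCQSMSGSASLGCVVGVIGSQCGASVKCCKDDVTNTGNSFLIINAANCVA"
#' scan_cys_motif(eas)
#' @export
scan_cys_motif <- function(residues, spacing_min = 1L, spacing_max = 75L,
                           decet = FALSE) {
  stopifnot(length(residues) == 1)
  pos <- stringr::str_locate_all(residues, "C")[[1]][, "start"]
  out <- list()
  k <- if (decet) 10L else 8L
  i <- 1L
  while (i + k - 1L <= length(pos)) {
    win <- pos[i:(i + k - 1L)]
    gaps <- diff(win) - 1L
    ok <- if (decet) {
      all(gaps == 0L | (gaps >= spacing_min & gaps <= spacing_max)) &&
        sum(gaps == 0L) >= 2L
    } else {
      all(gaps[c(2L, 6L)] == 0L) &&
        all(gaps[-c(2L, 6L)] >= spacing_min & gaps[-c(2L, 6L)] <= spacing_max)
    }
    if (ok) {
      out[[length(out) + 1L]] <- motif_row(residues, win, gaps)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble(
      motif_index = integer(), n_cys = integer(),
      start = integer(), end = integer(),
      positions = list(), spacing = list(), doublets = list(), loops = list()
    ))
  }
  res <- dplyr::bind_rows(out)
  res$motif_index <- seq_len(nrow(res))
  dplyr::relocate(res, "motif_index")
}

motif_row <- function(residues, win, gaps) {
  k <- length(win)
  loop_names <- paste0("C", seq_len(k - 1L), "-C", seq_len(k - 1L) + 1L)
  loops <- tibble(
    loop = loop_names,
    start = win[-k] + 1L,
    end = win[-1] - 1L,
    subsequence = ifelse(
      gaps == 0L, "",
      substring(residues, win[-k] + 1L, win[-1] - 1L)
    )
  )
  dbl <- which(gaps == 0L)
  tibble(
    motif_index = NA_integer_,
    n_cys = k,
    start = win[1],
    end = win[k],
    positions = list(unname(win)),
    spacing = list(unname(gaps)),
    doublets = list(lapply(dbl, function(d) c(d, d + 1L))),
    loops = list(loops)
  )
}

#' Scan every record in a sequence set
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @inheritParams scan_cys_motif
#' @return A tibble of motifs across records (column `id` added); records
#'   without a motif contribute no rows.
#' @export
scan_motifs <- function(seqs, spacing_min = 1L, spacing_max = 75L,
                        decet = FALSE) {
  rows <- purrr::map2(seqs$id, seqs$residues, function(id, s) {
    m <- scan_cys_motif(s, spacing_min, spacing_max, decet = decet)
    if (nrow(m) > 0) dplyr::mutate(m, id = id, .before = 1) else NULL
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- dplyr::mutate(scan_cys_motif("", spacing_min, spacing_max),
                         id = character(), .before = 1)
  }
  out
}

#' Default class centroids for cysteine spacing
#'
#' Seven-component intercysteine-spacing centroids for class I and class II,
#' matching the defaults of the synthetic sequence generator (see
#' [synth_sequences()]); regenerate from labelled data with
#' [spacing_centroids()].
#'
#' @return A tibble with columns `class_label` and list-column `spacing`.
#' @export
default_spacing_centroids <- function() {
  tibble(
    class_label = c("class_I", "class_II"),
    spacing = list(
      c(8, 0, 16, 9, 6, 0, 17),
      c(9, 0, 11, 15, 8, 0, 6)
    )
  )
}

#' Recompute spacing centroids from a labelled sequence set
#'
#' @param seqs Labelled sequence tibble (`class_label` in
#'   `class_I`/`class_II`).
#' @param motifs Motif table from [scan_motifs()]; computed when `NULL`.
#' @return Centroid tibble in the format of [default_spacing_centroids()].
#' @export
spacing_centroids <- function(seqs, motifs = NULL) {
  if (is.null(motifs)) motifs <- scan_motifs(seqs)
  motifs <- dplyr::filter(motifs, .data$n_cys == 8L)
  motifs <- dplyr::left_join(
    motifs, seqs[, c("id", "class_label")], by = "id"
  )
  motifs <- dplyr::filter(motifs, .data$class_label %in% c("class_I", "class_II"))
  if (nrow(motifs) == 0) abort("no labelled octet motifs to average")
  sp <- do.call(rbind, motifs$spacing)
  cls <- sort(unique(motifs$class_label))
  tibble(
    class_label = cls,
    spacing = lapply(cls, function(cl) colMeans(sp[motifs$class_label == cl, , drop = FALSE]))
  )
}

#' Classify sequences as class I or class II hydrophobins
#'
#' Nearest-centroid decision on the seven-component intercysteine spacing
#' vector of each record's first octet motif. The returned confidence is the
#' margin between the distances to the two class centroids; exact ties are
#' broken by the mean Kyte-Doolittle hydropathy of the C7-C8 loop (more
#' hydrophobic favours class I, whose C7-C8 loop harbours the aggregation
#' segment). Records without an octet motif are labelled
#' `not_hydrophobin`. The rule is an explicit heuristic: class membership in
#' curated databases comes from family annotation, not from a stated
#' algorithm.
#'
#' @param seqs Sequence tibble.
#' @param motifs Motif table from [scan_motifs()]; computed when `NULL`.
#' @param centroids Centroid tibble ([default_spacing_centroids()]).
#' @return Tibble `id`, `predicted_class`, `confidence`, `motif_found`.
#' @export
classify_hydrophobin <- function(seqs, motifs = NULL,
                                 centroids = default_spacing_centroids()) {
  if (is.null(motifs)) motifs <- scan_motifs(seqs)
  octet <- dplyr::filter(motifs, .data$n_cys == 8L)
  first <- octet[!duplicated(octet$id), ]
  purrr::map(seq_len(nrow(seqs)), function(i) {
    id <- seqs$id[i]
    j <- match(id, first$id)
    if (is.na(j)) {
      return(tibble(
        id = id, predicted_class = "not_hydrophobin",
        confidence = NA_real_, motif_found = FALSE
      ))
    }
    sp <- first$spacing[[j]]
    d <- purrr::map_dbl(centroids$spacing, function(ct) sqrt(sum((sp - ct)^2)))
    ord <- order(d)
    label <- centroids$class_label[ord[1]]
    margin <- d[ord[2]] - d[ord[1]]
    if (margin < 1e-9) {
      loop78 <- first$loops[[j]]
      sub <- loop78$subsequence[loop78$loop == "C7-C8"]
      g <- if (nzchar(sub)) gravy(sub) else 0
      label <- if (g > 0) "class_I" else "class_II"
    }
    tibble(
      id = id, predicted_class = label,
      confidence = margin, motif_found = TRUE
    )
  }) |>
    dplyr::bind_rows()
}

#' Mine non-canonical hydrophobin features
#'
#' Flags, per record: `five_disulfide_candidate` (exactly 10 cysteines and
#' length under 250 residues), `extended_ntail` (at least 70 residues before
#' the first cysteine, length reported in `n_tail_length`), and
#' `polyhydrophobin` (more than one non-overlapping octet motif in a chain
#' longer than 250 residues), with the domain count labelled mono/di/tri/
#' tetra/penta-hydrophobin.
#'
#' @param seqs Sequence tibble.
#' @param motifs Motif table from [scan_motifs()]; computed when `NULL`.
#' @return Tibble `id`, `motif_found`, `cys_count`, `length`,
#'   `n_tail_length`, `domain_count`, `domain_label`,
#'   `five_disulfide_candidate`, `extended_ntail`, `polyhydrophobin`.
#' @export
mine_noncanonical <- function(seqs, motifs = NULL) {
  if (is.null(motifs)) motifs <- scan_motifs(seqs)
  octet <- dplyr::filter(motifs, .data$n_cys == 8L)
  n_dom <- table(octet$id)
  first_c <- unname(stringr::str_locate(seqs$residues, "C")[, "start"])
  len <- nchar(seqs$residues)
  cys <- stringr::str_count(seqs$residues, "C")
  domain_count <- as.integer(n_dom[seqs$id])
  domain_count[is.na(domain_count)] <- 0L
  labels <- c("monohydrophobin", "dihydrophobin", "trihydrophobin",
              "tetrahydrophobin", "pentahydrophobin")
  tibble(
    id = seqs$id,
    motif_found = domain_count > 0L,
    cys_count = cys,
    length = len,
    n_tail_length = ifelse(is.na(first_c), NA_integer_, first_c - 1L),
    domain_count = domain_count,
    domain_label = dplyr::case_when(
      domain_count == 0L ~ "none",
      domain_count <= 5L ~ labels[domain_count],
      TRUE ~ "multihydrophobin"
    ),
    five_disulfide_candidate = cys == 10L & len < 250L,
    extended_ntail = !is.na(first_c) & first_c - 1L >= 70L,
    polyhydrophobin = domain_count >= 2L & len > 250L
  )
}
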