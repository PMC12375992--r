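#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the non-ambiguous residues of a
#' sequence. Ambiguity codes (X/B/Z) and selenocysteine (U) carry no scale
#' value and are excluded from the mean rather than imputed.
#'
#' @param residues Character vector of one-letter amino-acid sequences.
#' @return Numeric vector of GRAVY scores, each in \[-4.5, 4.5\].
#' @examples
#' gravy("IIIII") # 4.5, the scale maximum
#' gravy("DR")    # -4.0
#' @export
gravy <- function(residues) {
  purrr::map_dbl(residues, function(s) {
    if (!nzchar(s)) abort("empty sequence")
    vals <- KD_HYDROPATHY[strsplit(s, "")[[1]]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      abort("GRAVY undefined: no residue with a hydropathy value")
    }
    mean(vals)
  })
}

# Henderson-Hasselbalch net charge at a given pH under the Bjellqvist pK set.
# Counts: N-terminus (residue-specific pK), C-terminus, and the titratable
# side chains D, E, C, Y (acidic) and K, R, H (basic). All cysteines are
# treated as free thiols.
net_charge <- function(residues, pH) {
  aa <- strsplit(residues, "")[[1]]
  pk <- BJELLQVIST_PK
  pos_pks <- c(
    pk$nterm[aa[1]] %|na|% pk$nterm_default,
    rep(pk$positive["K"], sum(aa == "K")),
    rep(pk$positive["R"], sum(aa == "R")),
    rep(pk$positive["H"], sum(aa == "H"))
  )
  neg_pks <- c(
    pk$cterm[aa[length(aa)]] %|na|% pk$cterm_default,
    rep(pk$negative["D"], sum(aa == "D")),
    rep(pk$negative["E"], sum(aa == "E")),
    rep(pk$negative["C"], sum(aa == "C")),
    rep(pk$negative["Y"], sum(aa == "Y"))
  )
  sum(1 / (1 + 10^(pH - pos_pks))) - sum(1 / (1 + 10^(neg_pks - pH)))
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else unname(x)

#' Isoelectric point (Bjellqvist method)
#'
#' pH at which the Henderson-Hasselbalch net charge of the sequence is zero,
#' using the Bjellqvist pK set with residue-specific terminal pK values.
#' The root is found by bisection on \[0, 14\] to a net-charge magnitude
#' below `tol`. All cysteines are treated as titratable free thiols
#' (sequence-only prediction; disulfide state is ignored).
#'
#' @param residues Character vector of one-letter amino-acid sequences.
#' @param tol Net-charge convergence tolerance (default `1e-3`).
#' @return Numeric vector of pI values in pH units.
#' @export
isoelectric_point <- function(residues, tol = 1e-3) {
  purrr::map_dbl(residues, function(s) {
    if (!nzchar(s)) abort("empty sequence")
    lo <- 0
    hi <- 14
    for (iter in 1:100) {
      mid <- (lo + hi) / 2
      q <- net_charge(s, mid)
      if (abs(q) < tol) break
      if (q > 0) lo <- mid else hi <- mid
    }
    mid
  })
}

#' Residue composition
#'
#' @param residues A single one-letter amino-acid sequence.
#' @return Named numeric vector: percent of sequence per residue code
#'   actually present (sums to 100).
#' @examples
#' residue_composition("AAC") # A 66.67, C 33.33
#' @export
residue_composition <- function(residues) {
  if (length(residues) != 1) abort("residue_composition() takes one sequence")
  if (!nzchar(residues)) abort("empty sequence")
  aa <- strsplit(residues, "")[[1]]
  counts <- table(aa)
  setNames(100 * as.numeric(counts) / length(aa), names(counts))
}

#' Physicochemical profile table
#'
#' Computes, per record: sequence length, literal cysteine count (U is not
#' counted as cysteine), GRAVY, Bjellqvist pI, and the percent composition
#' of every standard residue (wide columns `pct_A` ... `pct_V`).
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @return A tibble with columns `id`, `class_label`, `length`, `cys_count`,
#'   `gravy`, `pi`, and one `pct_*` column per standard residue.
#' @export
physchem_profile <- function(seqs) {
  comp <- purrr::map(seqs$residues, function(s) {
    aa <- strsplit(s, "")[[1]]
    counts <- table(factor(aa, levels = AA_STANDARD))
    100 * as.numeric(counts) / length(aa)
  })
  comp_mat <- do.call(rbind, comp)
  colnames(comp_mat) <- paste0("pct_", AA_STANDARD)
  dplyr::bind_cols(
    tibble(
      id = seqs$id,
      class_label = seqs$class_label,
      length = nchar(seqs$residues),
      cys_count = stringr::str_count(seqs$residues, "C"),
      gravy = gravy(seqs$residues),
      pi = isoelectric_point(seqs$residues)
    ),
    as_tibble(comp_mat)
  )
}
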