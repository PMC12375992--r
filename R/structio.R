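#' Read a PDB coordinate file into an ensemble tibble
#'
#' Parses fixed-column ATOM/HETATM records, honouring MODEL/ENDMDL blocks,
#' into a tidy ensemble: one row per model with nested residue and atom
#' tables. Alternate locations are resolved by keeping the blank altloc or,
#' where a residue atom has several, the highest occupancy (ties broken in
#' favour of altloc `A`). The temperature-factor column is stored as a
#' per-residue confidence value: predicted models conventionally carry
#' pLDDT (0-100) there.
#'
#' @param file Path to a PDB file. Ignored when `text` is given.
#' @param text Optional character scalar/vector of PDB text.
#' @return A tibble with columns `model_index` and list-columns `residues`
#'   (chain, resno, icode, aa, x, y, z, sg_x, sg_y, sg_z, confidence) and
#'   `atoms` (all heavy-atom coordinates incl. HETATM, for surface-area
#'   work). Residues are ordered by chain, residue number and insertion
#'   code; a cysteine without a Sulfur-gamma coordinate keeps `NA` there.
#' @export
read_structure <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) abort("supply `file` or `text`")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }

  rec <- substring(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substring(lines, 1, 4) == "ATOM"
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) abort("no ATOM records found")

  # model index per line: 0 before any MODEL record
  model_no <- cumsum(is_model)
  atom_idx <- which(is_atom)
  ml <- model_no[atom_idx]
  if (all(ml == 0)) ml <- rep(1L, length(ml))
  ml[ml == 0] <- 1L

  al <- lines[atom_idx]
  num <- function(chars, what) {
    v <- suppressWarnings(as.numeric(chars))
    bad <- which(is.na(v) & nzchar(trimws(chars)))
    if (length(bad) > 0) {
      abort(paste0(
        "malformed ", what, " field at line ", atom_idx[bad[1]]
      ))
    }
    v
  }
  atoms <- tibble(
    model_index = as.integer(ml),
    het = startsWith(al, "HETATM"),
    atom = trimws(substring(al, 13, 16)),
    altloc = substring(al, 17, 17),
    resname = trimws(substring(al, 18, 20)),
    chain = substring(al, 22, 22),
    resno = as.integer(num(substring(al, 23, 26), "residue number")),
    icode = substring(al, 27, 27),
    x = num(substring(al, 31, 38), "x coordinate"),
    y = num(substring(al, 39, 46), "y coordinate"),
    z = num(substring(al, 47, 54), "z coordinate"),
    occupancy = num(substring(al, 55, 60), "occupancy"),
    bfactor = num(substring(al, 61, 66), "temperature factor"),
    element = trimws(substring(al, 77, 78))
  )
  if (anyNA(atoms$resno)) abort("missing residue number in ATOM record")
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  # infer element from atom name when the element column is absent
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substring(gsub("[0-9 ]", "", atoms$atom[blank]), 1, 1)

  # altloc resolution per (model, chain, resno, icode, atom)
  atoms <- atoms |>
    dplyr::group_by(.data$model_index, .data$chain, .data$resno,
                    .data$icode, .data$atom, .data$het) |>
    dplyr::arrange(dplyr::desc(.data$altloc %in% c("", " ")),
                   dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  models <- sort(unique(atoms$model_index))
  tibble(
    model_index = seq_along(models),
    residues = purrr::map(models, function(m) {
      a <- dplyr::filter(atoms, .data$model_index == m, !.data$het)
      ca <- dplyr::filter(a, .data$atom == "CA")
      sg <- dplyr::filter(a, .data$atom == "SG")
      ca <- dplyr::arrange(ca, .data$chain, .data$resno, .data$icode)
      key <- paste(ca$chain, ca$resno, ca$icode)
      sg_key <- paste(sg$chain, sg$resno, sg$icode)
      j <- match(key, sg_key)
      tibble(
        chain = ca$chain,
        resno = ca$resno,
        icode = ca$icode,
        aa = unname(AA_THREE_TO_ONE[ca$resname]) %na% "X",
        x = ca$x, y = ca$y, z = ca$z,
        sg_x = sg$x[j], sg_y = sg$y[j], sg_z = sg$z[j],
        confidence = ca$bfactor
      )
    }),
    atoms = purrr::map(models, function(m) {
      dplyr::select(
        dplyr::filter(atoms, .data$model_index == m),
        -"model_index", -"altloc"
      )
    })
  )
}

`%na%` <- function(x, y) {
  x[is.na(x)] <- y
  x
}

#' Extract one model's residue table from an ensemble
#'
#' @param ensemble Ensemble tibble from [read_structure()].
#' @param model_index Which model (default 1).
#' @return Residue tibble for that model.
#' @export
model_residues <- function(ensemble, model_index = 1L) {
  j <- match(model_index, ensemble$model_index)
  if (is.na(j)) abort(paste0("no model with index ", model_index))
  ensemble$residues[[j]]
}

#' Sequence of a residue table
#' @param residues Residue tibble.
#' @return One-letter sequence string.
#' @export
residue_sequence <- function(residues) {
  paste0(residues$aa, collapse = "")
}

#' Write residue tables to a (multi-model) PDB file
#'
#' Writes CA records (plus SG records for cysteines with sulfur
#' coordinates) in fixed-column PDB format, wrapping each model in
#' MODEL/ENDMDL when more than one is given. Confidence values go to the
#' temperature-factor column.
#'
#' @param models A residue tibble or list of residue tibbles.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure <- function(models, file) {
  if (is.data.frame(models)) models <- list(models)
  one_to_three <- setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)
  con <- file(file, "w")
  on.exit(close(con))
  serial <- 0L
  fmt <- function(name, resname, chain, resno, x, y, z, b) {
    serial <<- serial + 1L
    sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, name, resname, chain, resno, x, y, z, 1, b,
      trimws(substring(name, 2, 2))
    )
  }
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    r <- models[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (i in seq_len(nrow(r))) {
      resname <- one_to_three[r$aa[i]] %na% "UNK"
      chain <- if ("chain" %in% names(r)) r$chain[i] else "A"
      if (!nzchar(chain)) chain <- "A"
      conf <- if ("confidence" %in% names(r)) r$confidence[i] else 0
      writeLines(
        fmt(" CA ", resname, chain, r$resno[i], r$x[i], r$y[i], r$z[i], conf),
        con
      )
      if (!is.null(r$sg_x) && !is.na(r$sg_x[i])) {
        writeLines(
          fmt(" SG ", resname, chain, r$resno[i],
              r$sg_x[i], r$sg_y[i], r$sg_z[i], conf),
          con
        )
      }
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
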