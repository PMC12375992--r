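#' Read protein sequences from FASTA
#'
#' Parses FASTA text into a tibble of sequence records. Headers may use the
#' UniProt three-field pipe dialect (`db|ACCESSION|NAME description`), in
#' which case the accession becomes the record id, or be bare, in which case
#' the first whitespace-delimited token is used. Wrapped sequence lines are
#' concatenated and lowercase residues coerced to uppercase. Alignment gap
#' characters (`-`, `.`) are stripped with a warning.
#'
#' @param file Path to a FASTA file. Ignored when `text` is given.
#' @param text Optional character scalar (or vector of lines) of FASTA text,
#'   for programmatic use.
#'
#' @return A tibble with one row per record and columns `id`, `description`,
#'   `residues`, `class_label` (initialised to `"unknown"`) and `taxon`
#'   (`NA` unless the header carries an `OS=` field).
#'
#' @details Residues are restricted to the 20 standard one-letter codes plus
#'   the ambiguity codes X/B/Z and selenocysteine U; any other character is a
#'   parse error that names the offending line. Duplicate ids are an error:
#'   ids must be unique within a dataset.
#'
#' @examples
#' read_fasta(text = ">seq1 demo\nacde\nFGHI")
#' @export
read_fasta <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) abort("supply `file` or `text`")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }

  ids <- character()
  descs <- character()
  seqs <- character()
  cur <- NULL
  gap_seen <- FALSE

  flush_record <- function() {
    if (is.null(cur)) return()
    ids[[length(ids) + 1L]] <<- cur$id
    descs[[length(descs) + 1L]] <<- cur$desc
    seqs[[length(seqs) + 1L]] <<- paste0(cur$chunks, collapse = "")
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      flush_record()
      header <- sub("^>\\s*", "", line)
      token <- sub("\\s.*$", "", header)
      desc <- trimws(sub("^\\S+\\s*", "", header))
      # UniProt dialect: db|ACC|NAME
      if (grepl("^[A-Za-z]{2}\\|[^|]+\\|\\S+", token)) {
        id <- strsplit(token, "|", fixed = TRUE)[[1]][2]
      } else {
        id <- token
      }
      if (!nzchar(id)) abort(paste0("empty FASTA header at line ", i))
      cur <- list(id = id, desc = desc, chunks = character())
    } else {
      if (is.null(cur)) {
        abort(paste0("sequence data before any FASTA header at line ", i))
      }
      chunk <- toupper(gsub("\\s", "", line))
      if (grepl("[-.]", chunk)) {
        gap_seen <- TRUE
        chunk <- gsub("[-.]", "", chunk)
      }
      bad <- setdiff(unique(strsplit(chunk, "")[[1]]), AA_ALLOWED)
      if (length(bad) > 0) {
        abort(paste0(
          "invalid residue character(s) ", paste0("'", bad, "'", collapse = ", "),
          " at line ", i
        ))
      }
      cur$chunks <- c(cur$chunks, chunk)
    }
  }
  flush_record()
  if (gap_seen) warn("gap characters ('-', '.') stripped from sequences")

  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate sequence id(s): ", paste(dup, collapse = ", ")))
  }

  taxon <- ifelse(
    grepl("OS=", descs),
    trimws(sub("^.*OS=(.*?)\\s*(OX=.*)?$", "\\1", descs, perl = TRUE)),
    NA_character_
  )

  tibble(
    id = ids,
    description = descs,
    residues = seqs,
    class_label = rep("unknown", length(ids)),
    taxon = taxon
  )
}

#' Write sequence records to FASTA
#'
#' @param seqs A tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param file Output path.
#' @param wrap Line width for sequence wrapping (default 80).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, wrap = 80L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  out <- purrr::map_chr(seq_len(nrow(seqs)), function(i) {
    header <- paste0(">", seqs$id[i], ifelse(nzchar(desc[i]), paste0(" ", desc[i]), ""))
    body <- gsub(paste0("(.{", wrap, "})"), "\\1\n", seqs$residues[i])
    body <- sub("\n$", "", body)
    paste0(header, "\n", body)
  })
  writeLines(out, file)
  invisible(file)
}

#' Attach class labels from a two-column table
#'
#' @param seqs Sequence tibble from [read_fasta()].
#' @param labels A data frame with columns `id` and `class_label`
#'   (values among `class_I`, `class_II`, `unknown`), e.g. read from TSV.
#' @return `seqs` with `class_label` filled in where ids match.
#' @export
add_class_labels <- function(seqs, labels) {
  stopifnot(all(c("id", "class_label") %in% names(labels)))
  ok <- c("class_I", "class_II", "unknown")
  bad <- setdiff(unique(labels$class_label), ok)
  if (length(bad) > 0) {
    abort(paste0("unknown class label(s): ", paste(bad, collapse = ", ")))
  }
  idx <- match(seqs$id, labels$id)
  seqs$class_label <- ifelse(is.na(idx), seqs$class_label, labels$class_label[idx])
  seqs
}

#' Trim residues preceding the first cysteine
#'
#' Pre-alignment trimming: every residue before the first `C` is removed so
#' that sequences are anchored on the cysteine scaffold. Records without any
#' cysteine cannot be anchored and are flagged (`has_cys = FALSE`) with their
#' residues left untouched; downstream motif analysis ignores them.
#'
#' @param seqs Sequence tibble (columns `id`, `residues`, ...).
#' @return The tibble with `residues` trimmed, plus integer `n_removed` and
#'   logical `has_cys` columns. Applying the function twice is a no-op.
#' @export
trim_before_first_cys <- function(seqs) {
  pos <- unname(stringr::str_locate(seqs$residues, "C")[, "start"])
  has <- !is.na(pos)
  seqs$n_removed <- ifelse(has, pos - 1L, NA_integer_)
  seqs$residues <- ifelse(has, substring(seqs$residues, pos), seqs$residues)
  seqs$has_cys <- has
  seqs
}

#' Per-record metadata table
#'
#' @param seqs Sequence tibble.
#' @return Tibble with `id`, `length`, `class_label`, ready for TSV export.
#' @export
sequence_metadata <- function(seqs) {
  tibble(
    id = seqs$id,
    length = nchar(seqs$residues),
    class_label = seqs$class_label
  )
}
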