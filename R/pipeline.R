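#' Run the full hydrophobin analysis pipeline
#'
#' Orchestrates the stages end-to-end on local inputs and writes plain-text
#' reports: physicochemical profile, motif scan + classification,
#' non-canonical mining, predicted-vs-experimental benchmark with per-class
#' summary, and (given several structures) the TM-score distance matrix,
#' UPGMA tree in Newick form and k-clade assignment. A JSON manifest
#' records the configuration so two runs with the same inputs and seed
#' produce byte-identical report files.
#'
#' @param fasta Path to the input FASTA file.
#' @param out_dir Output directory (created if missing).
#' @param class_labels Optional TSV path or data frame (`id`,
#'   `class_label`).
#' @param pair_table Optional TSV path or data frame with columns `id`,
#'   `predicted`, `experimental` (PDB paths) and optionally `class_label`,
#'   for the structure benchmark.
#' @param structures Optional named character vector of PDB paths (or a
#'   directory of `.pdb` files) for distance-matrix / clade analysis.
#' @param spacing_min,spacing_max Motif spacing bounds.
#' @param tail_min Extended N-tail threshold (residues, default 70).
#' @param ss_cutoff Disulfide S-S cutoff in Angstrom (recorded in the
#'   manifest; used when structures are given).
#' @param rmsd_cutoff,lddt_cutoff,tm_cutoff Benchmark quality cut-offs.
#' @param k_clades Number of clades to cut (default 6).
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, a named list of the computed tables.
#' @export
run_pipeline <- function(fasta, out_dir,
                         class_labels = NULL, pair_table = NULL,
                         structures = NULL,
                         spacing_min = 1L, spacing_max = 75L,
                         tail_min = 70L, ss_cutoff = 2.5,
                         rmsd_cutoff = 2.5, lddt_cutoff = 0.6,
                         tm_cutoff = 0.6, k_clades = 6L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  log_stage <- function(...) message("[hydrophobinr] ", ...)

  seqs <- stage("load", {
    s <- read_fasta(fasta)
    if (nrow(s) == 0) abort("no sequences in input FASTA")
    if (!is.null(class_labels)) {
      lab <- if (is.character(class_labels)) {
        readr::read_tsv(class_labels, show_col_types = FALSE)
      } else {
        class_labels
      }
      s <- add_class_labels(s, lab)
    }
    s
  })
  log_stage("loaded ", nrow(seqs), " sequence(s)")

  out$physchem <- stage("physchem", physchem_profile(seqs))
  readr::write_tsv(out$physchem, file.path(out_dir, "physchem.tsv"))

  out$motifs <- stage("motifs", scan_motifs(seqs, spacing_min, spacing_max))
  stage("motifs", write_motif_json(out$motifs, file.path(out_dir, "motifs.json")))

  out$classification <- stage("classify",
                              classify_hydrophobin(seqs, out$motifs))
  readr::write_tsv(out$classification, file.path(out_dir, "classification.tsv"))

  out$mining <- stage("mine", mine_noncanonical(seqs, out$motifs))
  readr::write_tsv(out$mining, file.path(out_dir, "mining.tsv"))
  log_stage("profiled, classified and mined ", nrow(seqs), " sequence(s)")

  if (!is.null(pair_table)) {
    pt <- if (is.character(pair_table)) {
      readr::read_tsv(pair_table, show_col_types = FALSE)
    } else {
      pair_table
    }
    out$benchmark <- stage("bench",
      benchmark_models(pt, rmsd_cutoff, lddt_cutoff, tm_cutoff))
    out$benchmark_summary <- stage("bench", summarise_benchmark(out$benchmark))
    readr::write_tsv(out$benchmark, file.path(out_dir, "benchmark.tsv"))
    readr::write_tsv(out$benchmark_summary,
                     file.path(out_dir, "benchmark_summary.tsv"))
    log_stage("benchmarked ", nrow(out$benchmark), " structure pair(s)")
  }

  if (!is.null(structures)) {
    models <- stage("tree", {
      paths <- structures
      if (length(paths) == 1 && dir.exists(paths)) {
        paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
        names(paths) <- sub("\\.pdb$", "", basename(paths))
      }
      lapply(paths, function(p) model_residues(read_structure(p)))
    })
    dmat <- stage("tree", structure_distance_matrix(models))
    readr::write_tsv(
      dplyr::bind_cols(tibble(label = rownames(dmat)),
                       as_tibble(unclass(dmat))),
      file.path(out_dir, "distance_matrix.tsv")
    )
    tree <- stage("tree", upgma_tree(dmat))
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    k <- min(k_clades, length(tree$labels))
    out$clades <- stage("tree", assign_clades(tree, k))
    readr::write_tsv(out$clades, file.path(out_dir, "clades.tsv"))
    out$tree <- tree
    out$distance_matrix <- dmat
    log_stage("built tree over ", length(models), " structure(s), k = ", k)
  }

  manifest <- list(
    package = "hydrophobinr",
    version = as.character(utils::packageVersion("hydrophobinr")),
    seed = seed,
    config = list(
      spacing_min = spacing_min, spacing_max = spacing_max,
      tail_min = tail_min, ss_cutoff = ss_cutoff,
      rmsd_cutoff = rmsd_cutoff, lddt_cutoff = lddt_cutoff,
      tm_cutoff = tm_cutoff, k_clades = k_clades
    ),
    inputs = list(
      fasta = basename(fasta),
      n_sequences = nrow(seqs)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

write_motif_json <- function(motifs, file) {
  lst <- purrr::map(seq_len(nrow(motifs)), function(i) {
    list(
      id = motifs$id[i],
      motif_index = motifs$motif_index[i],
      n_cys = motifs$n_cys[i],
      positions = motifs$positions[[i]],
      spacing = motifs$spacing[[i]],
      loops = motifs$loops[[i]]
    )
  })
  jsonlite::write_json(lst, file, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(file)
}
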