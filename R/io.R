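#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of amino acid sequences.
#' @export
read_fasta <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && !startsWith(first, ">")) {
    stop_mlploc("malformed FASTA (no '>' header): ", path)
  }
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- vapply(
    strsplit(names(seqs), "\\s+"), `[`, character(1), 1
  )
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path,
    width = 80
  )
  invisible(path)
}

#' Read the pre-computed homology table
#'
#' TSV with columns `query`, `accession`, `identity_pct`, `evalue` (the
#' stand-in for a live homology search).
#'
#' @param path TSV path.
#' @return Data frame with columns `query`, `accession`, `identity`,
#'   `evalue`.
#' @export
read_homology_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "identity_pct"] <- "identity"
  check_table(df, c("query", "accession", "identity", "evalue"),
    what = paste0("homology table ", path)
  )
  if (anyNA(df$evalue) || anyNA(df$identity)) {
    bad <- which(is.na(df$evalue) | is.na(df$identity))[1]
    stop_mlploc("malformed homology table row ", bad + 1L, " in ", path)
  }
  df
}

#' Read the annotation index (accession to GO terms)
#'
#' TSV with columns `accession` and `go_terms` (comma-separated ids).
#'
#' @param path TSV path.
#' @return Named list: accession -> character vector of GO ids.
#' @export
read_annotation_index <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_table(df, c("accession", "go_terms"),
    what = paste0("annotation index ", path)
  )
  setNames(
    lapply(strsplit(df$go_terms, ","), trimws),
    df$accession
  )
}

#' Read the domain hit table
#'
#' TSV with columns `protein`, `domain_id`, `evalue`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_domain_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_table(df, c("protein", "domain_id", "evalue"),
    what = paste0("domain hit table ", path)
  )
  df
}

#' Read a term/domain index file (one identifier per line)
#'
#' @param path Text file path; line order defines vector positions.
#' @return Character vector.
#' @export
read_index_file <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) stop_mlploc("duplicate ids in index ", path)
  ids
}

#' Read a multi-location benchmark table
#'
#' TSV with columns `protein` and `locations` (";"-joined site names).
#'
#' @param path TSV path.
#' @return Data frame with `protein` and list-column `labels`.
#' @export
read_benchmark <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_table(df, c("protein", "locations"),
    what = paste0("benchmark ", path)
  )
  out <- data.frame(protein = df$protein, stringsAsFactors = FALSE)
  out$labels <- lapply(strsplit(df$locations, ";"), trimws)
  out
}

#' Write a benchmark table
#'
#' @param benchmark Data frame with `protein` and list-column `labels`.
#' @param path Output TSV path.
#' @export
write_benchmark <- function(benchmark, path) {
  df <- data.frame(
    protein = benchmark$protein,
    locations = vapply(benchmark$labels, paste, character(1),
      collapse = ";"
    ),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a raw scoring matrix in the PSI-BLAST ASCII dialect
#'
#' Emits the header, the 40-letter column line (log-odds block followed by
#' the weighted-percentage block, both in PSI-BLAST residue order), one
#' line per position and a statistics footer, so that the file exercises
#' the same remapping and footer-skipping a real PSI-BLAST matrix needs.
#'
#' @param m Integer L x 20 matrix in alphabetical column order.
#' @param path Output path.
#' @param residues Optional per-position residue letters.
#' @export
write_pssm_ascii <- function(m, path, residues = NULL) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 20)
  if (is.null(colnames(m))) colnames(m) <- AA_ALPHABET
  residues <- residues %||% rep("A", nrow(m))
  file_order <- m[, PSIBLAST_COLS, drop = FALSE]
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and ignored",
    paste0(
      "            ",
      paste(sprintf("%3s", c(PSIBLAST_COLS, PSIBLAST_COLS)),
        collapse = ""
      )
    )
  )
  for (i in seq_len(nrow(m))) {
    pct <- rep(0L, 20) # placeholder weighted-percentage block
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, residues[i]),
      paste(sprintf("%3d", file_order[i, ]), collapse = ""),
      " ",
      paste(sprintf("%3d", pct), collapse = "")
    ))
  }
  lines <- c(
    lines, "",
    "                      K         Lambda",
    "Standard Ungapped    0.1337     0.3108"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write the complete synthetic benchmark file tree
#'
#' @param sim A [generate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Files: `benchmark.tsv`, `homology.tsv`,
#'   `annotations.tsv`, `domains.tsv`, `go_index.txt`,
#'   `domain_index.txt`, `sequences.fasta`, `pssm/<id>.pssm`,
#'   `manifest.json`.
#' @export
write_benchmark_tree <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_benchmark(sim$benchmark, file.path(dir, "benchmark.tsv"))
  hom <- sim$homology
  names(hom)[names(hom) == "identity"] <- "identity_pct"
  write.table(hom, file.path(dir, "homology.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  ann <- data.frame(
    accession = names(sim$annotations),
    go_terms = vapply(sim$annotations, paste, character(1),
      collapse = ","
    ),
    stringsAsFactors = FALSE
  )
  write.table(ann, file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(sim$domains, file.path(dir, "domains.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(sim$go_index, file.path(dir, "go_index.txt"))
  writeLines(sim$domain_index, file.path(dir, "domain_index.txt"))
  write_fasta(sim$sequences, file.path(dir, "sequences.fasta"))
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in names(sim$pssms)) {
    write_pssm_ascii(
      sim$pssms[[id]], file.path(pssm_dir, paste0(id, ".pssm")),
      residues = strsplit(sim$sequences[[id]], "")[[1]]
    )
  }
  manifest <- c(
    unclass(sim$config),
    list(n_proteins = nrow(sim$benchmark), frame = sim$frame)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Build per-protein feature lists from the input tables
#'
#' For each protein id: the GO vector from its homology set (or `NULL`
#' when no homology/annotation exists), the FunD vector from its domain
#' hits, and its standardized scoring matrix from the PSSM directory (or
#' in-memory matrix list). A protein without a scoring matrix falls back
#' to GO/FunD-only routing with a notice.
#'
#' @param ids Protein identifiers.
#' @param homology Homology table ([read_homology_table()]).
#' @param annotations Annotation index ([read_annotation_index()]).
#' @param go_index GO term index (character vector).
#' @param domains Domain hit table ([read_domain_table()]).
#' @param domain_index Domain index (character vector).
#' @param pssms Directory of `<id>.pssm` files, or a named list of raw
#'   matrices.
#' @param config [ensemble_config()] for the cutoffs.
#' @param quiet Suppress missing-matrix notices.
#' @return Named list of feature lists (`go`, `fund`, `pssm`).
#' @export
build_features <- function(ids, homology, annotations, go_index,
                           domains, domain_index, pssms,
                           config = ensemble_config(), quiet = FALSE) {
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    hs <- build_homology_set(id, homology,
      e_cutoff = config$e_cutoff,
      identity_cutoff = config$identity_cutoff
    )
    gv <- suppressWarnings(go_vector(hs, annotations, go_index))
    if (!any(as.numeric(gv) != 0)) gv <- NULL
    fv <- fund_vector(id, domains, domain_index,
      e_cutoff = config$e_cutoff
    )
    if (!any(as.numeric(fv) != 0)) fv <- NULL
    raw <- if (is.list(pssms)) {
      pssms[[id]]
    } else {
      f <- file.path(pssms, paste0(id, ".pssm"))
      if (file.exists(f)) parse_pssm_ascii(f) else NULL
    }
    if (is.null(raw) && !quiet) {
      message(
        "no scoring matrix for ", id,
        "; falling back to GO/FunD-only routing"
      )
    }
    out[[id]] <- list(
      go = gv, fund = fv,
      pssm = if (!is.null(raw)) standardize_pssm(raw) else NULL
    )
  }
  out
}

#' Save a trained localizer bundle to a directory
#'
#' Plain-text serialization: one TSV of training vectors plus a gamma
#' table per engine, and a JSON of the configuration and frame.
#'
#' @param model A [train_localizer()] bundle.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_localizer <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  engines <- c(
    if (!is.null(model$go)) list(go = model$go),
    if (!is.null(model$fund)) list(fund = model$fund),
    setNames(
      model$psepssm,
      paste0("psepssm_", names(model$psepssm))
    )
  )
  for (nm in names(engines)) {
    eng <- engines[[nm]]
    df <- data.frame(
      id = eng$training$ids %||% rep(NA_character_, nrow(eng$training$x)),
      label = eng$training$y,
      eng$training$x,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    write.table(df, file.path(dir, paste0(nm, "_training.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write.table(
      data.frame(class = names(eng$gamma), gamma = as.numeric(eng$gamma)),
      file.path(dir, paste0(nm, "_gamma.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  meta <- list(
    frame = model$frame,
    engines = names(engines),
    config = unclass(model$config)
  )
  jsonlite::write_json(meta, file.path(dir, "model.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Load a localizer bundle saved with [save_localizer()]
#'
#' @param dir Bundle directory.
#' @return A `localizer` object.
#' @export
load_localizer <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
    simplifyVector = TRUE
  )
  config <- do.call(ensemble_config, meta$config[names(meta$config) %in%
    names(formals(ensemble_config))])
  model <- structure(
    list(
      frame = meta$frame, config = config,
      go = NULL, fund = NULL, psepssm = list()
    ),
    class = "localizer"
  )
  for (nm in meta$engines) {
    df <- read.delim(file.path(dir, paste0(nm, "_training.tsv")),
      check.names = FALSE, stringsAsFactors = FALSE
    )
    gm <- read.delim(file.path(dir, paste0(nm, "_gamma.tsv")),
      stringsAsFactors = FALSE
    )
    x <- as.matrix(df[, -(1:2), drop = FALSE])
    distance <- if (startsWith(nm, "psepssm")) "euclidean" else "angular"
    eng <- list(
      training = etknn_training(x, df$label,
        frame = meta$frame,
        distance = distance, ids = df$id
      ),
      gamma = setNames(gm$gamma, gm$class)
    )
    if (nm == "go") {
      model$go <- eng
    } else if (nm == "fund") {
      model$fund <- eng
    } else {
      model$psepssm[[sub("^psepssm_", "", nm)]] <- eng
    }
  }
  model
}

#' Write a prediction report TSV
#'
#' One row per query: protein id, ";"-joined predicted locations and the
#' per-location fused scores.
#'
#' @param predictions A [predict.localizer()] result.
#' @param path Output TSV path.
#' @export
write_prediction_report <- function(predictions, path) {
  scores <- attr(predictions, "scores")
  df <- data.frame(
    protein = predictions$protein,
    locations = vapply(predictions$locations, paste, character(1),
      collapse = ";"
    ),
    plan = predictions$plan,
    round(scores, 6),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
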