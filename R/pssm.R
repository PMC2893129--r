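#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the text PSSM dialect produced by PSI-BLAST (`-out_ascii_pssm`):
#' a couple of header lines, a column-header line of residue letters, one
#' line per sequence position carrying the position index, the residue and
#' (at least) 20 integer log-odds scores, then an ignorable statistics
#' footer. Only the first 20-column score block is used. Columns are
#' remapped from the file's residue order (A R N D C Q E G H I L K M F P S
#' T W Y V) to alphabetical single-letter order, the convention used by
#' every matrix in this package.
#'
#' @param x Path to a PSSM file, or a character vector of its lines.
#' @return Integer matrix, L positions x 20 amino acids, columns named by
#'   [AA_ALPHABET] order; attribute `residues` holds the per-position
#'   residue letters.
#' @export
parse_pssm_ascii <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  header_at <- NA_integer_
  file_cols <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) >= 20 && all(toks %in% c(LETTERS, letters))) {
      header_at <- i
      file_cols <- toks[seq_len(20)]
      break
    }
  }
  if (is.na(header_at)) {
    stop_mlploc("not a PSI-BLAST ASCII PSSM: no residue column header found")
  }
  scores <- list()
  residues <- character()
  expect_pos <- 1L
  for (i in seq((header_at + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break # blank line starts the statistics footer
    toks <- strsplit(ln, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", toks[1])) break # footer (K, Lambda, ...)
    if (length(toks) < 22) {
      stop_mlploc("truncated PSSM line ", i, ": ", lines[i])
    }
    row <- suppressWarnings(as.integer(toks[3:22]))
    if (anyNA(row)) {
      stop_mlploc("non-integer score on PSSM line ", i, ": ", lines[i])
    }
    scores[[expect_pos]] <- row
    residues[expect_pos] <- toks[2]
    expect_pos <- expect_pos + 1L
  }
  if (!length(scores)) stop_mlploc("PSSM contains no position rows")
  m <- do.call(rbind, scores)
  colnames(m) <- file_cols
  m <- m[, AA_ALPHABET, drop = FALSE]
  attr(m, "residues") <- residues
  m
}

#' Standardize a position-specific scoring matrix
#'
#' Converts raw integer log-odds scores row by row to zero-mean,
#' unit-scale form: each row becomes `(x - mean(x)) / sd_pop(x)` where the
#' mean and the population standard deviation (divisor 20) run over the 20
#' amino acid columns. After the transform every row has mean 0 over the
#' amino acids and the operation is idempotent. A degenerate constant row
#' (population sd 0) maps to an all-zero row.
#'
#' @param raw Numeric L x 20 matrix (a [parse_pssm_ascii()] result, or any
#'   matrix in alphabetical column order).
#' @return Numeric L x 20 matrix of class `pssm` with attribute
#'   `standardized = TRUE`.
#' @export
standardize_pssm <- function(raw) {
  m <- unclass(as.matrix(raw))
  if (ncol(m) != 20) {
    stop_mlploc("PSSM must have 20 columns, got ", ncol(m))
  }
  mu <- rowMeans(m)
  centered <- m - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  out <- centered / ifelse(sd_pop > 0, sd_pop, 1)
  out[sd_pop == 0, ] <- 0
  colnames(out) <- colnames(m) %||% AA_ALPHABET
  structure(out, class = "pssm", standardized = TRUE)
}

#' @export
print.pssm <- function(x, ...) {
  cat(
    "<pssm>", nrow(x), "positions x 20 amino acids",
    if (isTRUE(attr(x, "standardized"))) "(standardized)" else "(raw)", "\n"
  )
  invisible(x)
}

#' Mean evolution-score profile
#'
#' Column means of a (standardized) PSSM: component j is the average score
#' of the protein's residues mutating to amino acid type j — the
#' size-uniform but order-free protein representation.
#'
#' @param pssm L x 20 matrix.
#' @return Numeric 20-vector named by amino acid.
#' @export
mean_profile <- function(pssm) {
  m <- as.matrix(pssm)
  setNames(colMeans(m), colnames(m) %||% AA_ALPHABET)
}

#' Sequence-order correlation factor of a PSSM column
#'
#' The lag-`xi` correlation factor for amino acid type `j`: the mean
#' squared difference between scores of residues `xi` positions apart,
#' `theta_j(xi) = (1/(L - xi)) * sum_i (s[i, j] - s[i + xi, j])^2`. It
#' couples the `xi`-th most contiguous scores along the chain and is 0
#' exactly when the column is constant at lag `xi`.
#'
#' @param pssm L x 20 matrix.
#' @param j Column index (1..20) or amino acid letter.
#' @param xi Lag, `1 <= xi <= L - 1`.
#' @return Non-negative scalar.
#' @export
correlation_factor <- function(pssm, j, xi) {
  m <- as.matrix(pssm)
  if (is.character(j)) j <- match(j, colnames(m) %||% AA_ALPHABET)
  L <- nrow(m)
  if (xi < 1 || xi >= L) {
    stop_mlploc("lag xi must satisfy 1 <= xi <= L - 1 (L = ", L, ")")
  }
  s <- m[, j]
  mean((s[seq_len(L - xi)] - s[seq_len(L - xi) + xi])^2)
}

#' PsePSSM descriptor
#'
#' The pseudo position-specific scoring matrix representation: the 20
#' column means of the standardized PSSM followed by `lambda` blocks of 20
#' correlation factors, one block per lag `xi = 1..lambda`. Dimension is
#' `20 * (1 + lambda)`; with `lambda = 0` the descriptor degenerates to
#' the plain mean profile. `lambda` must be smaller than the sequence
#' length (and, for a benchmark whose shortest chain has 50 residues,
#' smaller than 50).
#'
#' @param pssm L x 20 matrix (standardized with [standardize_pssm()]; a raw
#'   matrix is standardized on the fly).
#' @param lambda Number of correlation tiers (non-negative integer).
#' @return Numeric vector of length `20 * (1 + lambda)` with class
#'   `psepssm_vector` and attribute `lambda`.
#' @export
psepssm_vector <- function(pssm, lambda = 0) {
  lambda <- as.integer(lambda)
  if (lambda < 0) stop_mlploc("lambda must be non-negative")
  if (!isTRUE(attr(pssm, "standardized"))) pssm <- standardize_pssm(pssm)
  m <- as.matrix(pssm)
  L <- nrow(m)
  if (lambda >= L) {
    stop_mlploc(
      "lambda (", lambda, ") must be smaller than the sequence length (",
      L, "); it must also stay below the shortest training chain"
    )
  }
  blocks <- vector("list", 1 + lambda)
  blocks[[1]] <- mean_profile(m)
  if (lambda > 0) {
    for (xi in seq_len(lambda)) {
      top <- m[seq_len(L - xi), , drop = FALSE]
      bot <- m[seq_len(L - xi) + xi, , drop = FALSE]
      theta <- colMeans((top - bot)^2)
      names(theta) <- paste0(colnames(m) %||% AA_ALPHABET, ".xi", xi)
      blocks[[xi + 1L]] <- theta
    }
  }
  structure(unlist(blocks),
    lambda = lambda,
    class = c("psepssm_vector", "numeric")
  )
}
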