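#' Build the homology set of a query protein
#'
#' Filters a pre-computed homology search table (the stand-in for a live
#' BLAST run against a reference database) down to the significant matches
#' of one query: members must pass both the expect-value and the pairwise
#' sequence-identity cutoff. The result is the set of "representative
#' proteins" whose annotations are transferred to the query.
#'
#' @param query_id Query protein identifier.
#' @param homology_table Data frame with columns `query`, `accession`,
#'   `identity` (percent) and `evalue`, as read by [read_homology_table()].
#' @param e_cutoff Maximum expect value (default `1e-3`).
#' @param identity_cutoff Minimum percent identity (default `25`).
#' @return A `homology_set`: list with `query_id` and a `members` data frame
#'   (`accession`, `identity`, `evalue`) sorted by ascending e-value. A query
#'   with no passing rows yields an empty member table — the empty-set case
#'   that routes prediction away from the GO engine.
#' @export
#' @examples
#' tab <- data.frame(
#'   query = "Q1", accession = c("A", "B"),
#'   identity = c(40, 10), evalue = c(1e-50, 1e-3)
#' )
#' build_homology_set("Q1", tab, identity_cutoff = 25)
build_homology_set <- function(query_id, homology_table,
                               e_cutoff = 1e-3, identity_cutoff = 25) {
  check_table(homology_table, c("query", "accession", "identity", "evalue"),
    what = "homology table"
  )
  rows <- homology_table[homology_table$query == query_id, , drop = FALSE]
  keep <- rows$evalue <= e_cutoff & rows$identity >= identity_cutoff
  rows <- rows[keep, , drop = FALSE]
  rows <- rows[order(rows$evalue, rows$accession), , drop = FALSE]
  structure(
    list(
      query_id = query_id,
      members = data.frame(
        accession = as.character(rows$accession),
        identity = as.numeric(rows$identity),
        evalue = as.numeric(rows$evalue),
        stringsAsFactors = FALSE,
        row.names = NULL
      )
    ),
    class = "homology_set"
  )
}

#' @export
print.homology_set <- function(x, ...) {
  cat(
    "<homology_set>", x$query_id, "with", nrow(x$members),
    "member(s)\n"
  )
  invisible(x)
}

check_table <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop_mlploc(what, " must be a data frame")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_mlploc(
      what, " is missing column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

#' GO descriptor of a protein via its homology set
#'
#' Transfers gene-ontology annotation from the members of the homology set:
#' component i of the descriptor is 1 when at least one member is annotated
#' with the i-th GO term of the index, 0 otherwise. With `weighted = TRUE`
#' the component instead holds the fraction of members annotated with the
#' term (a frequency-weighted variant of the same representation).
#'
#' @param homology_set A [build_homology_set()] result.
#' @param annotation_index Named list mapping accession to a character
#'   vector of GO term identifiers.
#' @param go_term_index Character vector of GO term ids; position in this
#'   vector is the vector-space axis.
#' @param weighted Use member-frequency weights instead of 0/1 presence.
#' @return Numeric vector of `length(go_term_index)` with class
#'   `go_vector`. Members absent from `annotation_index` are skipped with a
#'   warning. An empty homology set yields the zero vector
#'   (non-productive).
#' @export
go_vector <- function(homology_set, annotation_index, go_term_index,
                      weighted = FALSE) {
  stopifnot(inherits(homology_set, "homology_set"))
  v <- numeric(length(go_term_index))
  accs <- homology_set$members$accession
  known <- accs %in% names(annotation_index)
  if (any(!known)) {
    warning(
      "accession(s) without annotation skipped: ",
      paste(accs[!known], collapse = ", "),
      call. = FALSE
    )
  }
  accs <- accs[known]
  if (length(accs)) {
    counts <- table(factor(
      unlist(lapply(accs, function(a) {
        unique(intersect(annotation_index[[a]], go_term_index))
      }), use.names = FALSE),
      levels = go_term_index
    ))
    v <- as.numeric(counts)
    v <- if (weighted) v / length(accs) else as.numeric(v > 0)
  }
  structure(v, names = go_term_index, class = c("go_vector", "numeric"))
}

#' Is a GO descriptor productive?
#'
#' A GO descriptor is "productive" (meaningful for evidence-based
#' classification) when it is non-zero and shares at least one non-zero
#' position with at least one training descriptor — otherwise no training
#' evidence can bear on the query and the prediction must fall back to the
#' FunD/PsePSSM route.
#'
#' @param gv A [go_vector()].
#' @param training_matrix Optional matrix of training GO vectors (rows =
#'   proteins). When omitted, only the non-zero condition is checked.
#' @return Logical flag.
#' @export
is_productive <- function(gv, training_matrix = NULL) {
  v <- as.numeric(gv)
  if (!any(v != 0)) {
    return(FALSE)
  }
  if (is.null(training_matrix)) {
    return(TRUE)
  }
  stopifnot(ncol(training_matrix) == length(v))
  any(as.numeric(training_matrix %*% v) != 0)
}

#' Functional-domain descriptor
#'
#' Binary hit vector over a conserved-domain catalogue: component j is 1
#' when the protein has a domain-search hit to domain j with expect value
#' at or below the significance cutoff.
#'
#' @param protein_id Protein identifier.
#' @param domain_hit_table Data frame with columns `protein`, `domain_id`,
#'   `evalue` (a pre-computed domain-search result table).
#' @param domain_index Character vector of domain ids; position = axis.
#' @param e_cutoff Significance threshold on the expect value (default
#'   `1e-3`).
#' @return Numeric 0/1 vector of `length(domain_index)` with class
#'   `fund_vector`.
#' @export
fund_vector <- function(protein_id, domain_hit_table, domain_index,
                        e_cutoff = 1e-3) {
  check_table(domain_hit_table, c("protein", "domain_id", "evalue"),
    what = "domain hit table"
  )
  rows <- domain_hit_table[domain_hit_table$protein == protein_id, ,
    drop = FALSE
  ]
  unknown <- setdiff(unique(rows$domain_id), domain_index)
  if (length(unknown)) {
    stop_mlploc(
      "domain id(s) not in index: ", paste(unknown, collapse = ", ")
    )
  }
  hit <- unique(rows$domain_id[rows$evalue <= e_cutoff])
  v <- as.numeric(domain_index %in% hit)
  structure(v, names = domain_index, class = c("fund_vector", "numeric"))
}

#' Support set of a binary descriptor
#'
#' @param v A `go_vector` or `fund_vector`.
#' @return Integer positions of the non-zero components.
#' @export
descriptor_support <- function(v) which(as.numeric(v) != 0)
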