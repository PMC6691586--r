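#' Read a protein-protein interaction edge list
#'
#' Reads a STRING-export-style TSV with columns `proteinA`, `proteinB`,
#' `combined_score` (score in 0..1000).  Edges are undirected: the pair is
#' stored in canonical (sorted) order, duplicates collapse to one edge keeping
#' the highest score, and self loops are dropped with a warning giving their
#' count.  Only edges with `combined_score >= min_score` are retained; the
#' default 700 is the conventional "high confidence" cutoff.
#'
#' @param path TSV path.
#' @param min_score minimum combined score to keep an edge (default 700).
#' @return an `interaction_graph`: a tibble with columns `protein_a`,
#'   `protein_b` (with `protein_a < protein_b`) and `score`.
#' @export
read_interactions <- function(path, min_score = 700) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("proteinA", "proteinB", "combined_score")
  if (!all(need %in% colnames(df))) {
    abort(paste0("Interaction TSV must have columns ", paste(need, collapse = ", "), "."))
  }
  suppressWarnings(score <- as.numeric(df$combined_score))
  if (anyNA(score)) {
    abort(paste0("Malformed interaction row at line ", which(is.na(score))[1] + 1L,
                 ": combined_score \"", df$combined_score[which(is.na(score))[1]], "\"."))
  }
  if (any(is.na(df$proteinA) | is.na(df$proteinB) | df$proteinA == "" | df$proteinB == "")) {
    bad <- which(is.na(df$proteinA) | is.na(df$proteinB) | df$proteinA == "" | df$proteinB == "")[1]
    abort(paste0("Malformed interaction row at line ", bad + 1L, ": empty protein id."))
  }
  interaction_graph(df$proteinA, df$proteinB, score, min_score = min_score)
}

#' Construct an interaction graph from vectors
#'
#' @param a,b character vectors of endpoint protein ids.
#' @param score numeric confidence scores in `[0, 1000]`.
#' @inheritParams read_interactions
#' @return an `interaction_graph` tibble (see [read_interactions()]).
#' @export
interaction_graph <- function(a, b, score = rep(1000, length(a)), min_score = 0) {
  stopifnot(length(a) == length(b), length(a) == length(score))
  if (length(score) && (any(score < 0) || any(score > 1000))) {
    abort("Interaction scores must lie in [0, 1000].")
  }
  self <- a == b
  if (any(self)) warn(paste0("Dropped ", sum(self), " self-loop edge(s)."))
  a2 <- pmin(a[!self], b[!self])
  b2 <- pmax(a[!self], b[!self])
  g <- tibble(protein_a = a2, protein_b = b2, score = score[!self]) |>
    dplyr::filter(.data$score >= min_score)
  if (nrow(g) > 0) {
    g <- g |>
      dplyr::group_by(.data$protein_a, .data$protein_b) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop") |>
      dplyr::arrange(.data$protein_a, .data$protein_b)
  }
  class(g) <- c("interaction_graph", class(g))
  g
}

#' Read a drug-target table
#'
#' TSV with columns `target` and `drug` (an optional `notes` column is kept if
#' present).  When `vocabulary` is supplied, targets absent from it are
#' flagged `unmatched = TRUE` but never dropped, so a mismatching alias can be
#' diagnosed rather than silently losing a drug.
#'
#' @param path TSV path.
#' @param vocabulary optional character vector of known protein/gene ids.
#' @return a tibble with columns `target`, `drug`, `notes`, `unmatched`.
#' @export
read_drug_table <- function(path, vocabulary = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) abort("Drug table is empty.")
  if (!all(c("target", "drug") %in% colnames(df))) {
    abort("Drug TSV must have columns `target` and `drug`.")
  }
  out <- tibble(
    target = df$target,
    drug = df$drug,
    notes = if ("notes" %in% colnames(df)) df$notes else NA_character_
  )
  out$unmatched <- if (is.null(vocabulary)) FALSE else !(out$target %in% vocabulary)
  if (any(out$unmatched)) {
    inform(paste0(sum(out$unmatched), " drug-table target(s) not in the protein vocabulary (flagged)."))
  }
  out
}
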