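#' Build a process subnetwork
#'
#' Restricts the interaction graph to the proteins participating in one
#' unbalanced process.  Antibody ids are first mapped to gene symbols via
#' `alias` (interaction databases know genes, not phospho-antibodies);
#' unmapped antibodies simply find no edges and stay as flagged isolated
#' nodes.  An edge joins two member proteins when their (mapped) genes
#' interact; nodes carry the signed process weight, so correlated members
#' share a weight sign and anti-correlated members differ.
#'
#' @param proteins tibble from [process_proteins()] (columns `protein_id`,
#'   `weight`, `sign`).
#' @param graph an `interaction_graph` from [read_interactions()].
#' @param alias optional named character vector mapping protein ids to gene
#'   ids (see [apply_alias()]).
#' @param process optional process index carried into the object.
#' @return a `subnetwork`: list with `process`, `nodes` (tibble `protein_id`,
#'   `gene`, `weight`, `sign`, `degree`, `is_isolated`) and `edges` (tibble
#'   `protein_a`, `protein_b`, `score`, endpoints being protein ids).
#' @export
build_subnetwork <- function(proteins, graph, alias = NULL, process = NA_integer_) {
  stopifnot(is.data.frame(proteins), all(c("protein_id", "weight") %in% colnames(proteins)))
  if (nrow(proteins) == 0) abort("Cannot build a subnetwork from an empty protein list.")
  nodes <- tibble(
    protein_id = proteins$protein_id,
    gene = apply_alias(proteins$protein_id, alias),
    weight = proteins$weight,
    sign = as.integer(sign(proteins$weight))
  )
  # candidate edges between member proteins whose mapped genes interact
  pairs <- which(upper.tri(matrix(0, nrow(nodes), nrow(nodes))), arr.ind = TRUE)
  edges <- tibble(
    protein_a = pmin(nodes$protein_id[pairs[, 1]], nodes$protein_id[pairs[, 2]]),
    protein_b = pmax(nodes$protein_id[pairs[, 1]], nodes$protein_id[pairs[, 2]]),
    gene_a = pmin(nodes$gene[pairs[, 1]], nodes$gene[pairs[, 2]]),
    gene_b = pmax(nodes$gene[pairs[, 1]], nodes$gene[pairs[, 2]])
  ) |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::inner_join(graph, by = c(gene_a = "protein_a", gene_b = "protein_b")) |>
    dplyr::select("protein_a", "protein_b", "score") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
  deg <- table(c(edges$protein_a, edges$protein_b))
  nodes$degree <- as.integer(deg[nodes$protein_id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  nodes$is_isolated <- nodes$degree == 0L
  structure(list(process = process, nodes = nodes, edges = edges),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> process ", x$process, ": ", nrow(x$nodes), " proteins, ",
      nrow(x$edges), " edges, ", sum(x$nodes$is_isolated), " isolated\n", sep = "")
  invisible(x)
}

#' @method tidy subnetwork
#' @export
tidy.subnetwork <- function(x, ...) x$nodes

#' Rank hub proteins of a subnetwork
#'
#' Hub score = within-subnetwork degree times absolute process weight, so a
#' hub is both well connected among the co-varying proteins and strongly
#' loaded on the process.  Ties are broken by `|weight|` then protein id.
#' `score_by` switches to degree-only or weight-only ranking.
#'
#' @param s a `subnetwork`.
#' @param k number of hubs to return (`NULL` = all); if `k` exceeds the node
#'   count all nodes are returned with a warning.
#' @param score_by `"degree_weight"` (default), `"degree"` or `"weight"`.
#' @return tibble `protein_id`, `gene`, `degree`, `weight`, `hub_score`,
#'   sorted by decreasing score.
#' @export
rank_hubs <- function(s, k = NULL, score_by = c("degree_weight", "degree", "weight")) {
  stopifnot(inherits(s, "subnetwork"))
  score_by <- match.arg(score_by)
  out <- s$nodes |>
    dplyr::mutate(hub_score = switch(score_by,
      degree_weight = .data$degree * abs(.data$weight),
      degree = as.numeric(.data$degree),
      weight = abs(.data$weight)
    )) |>
    dplyr::arrange(dplyr::desc(.data$hub_score), dplyr::desc(abs(.data$weight)),
                   .data$protein_id) |>
    dplyr::select("protein_id", "gene", "degree", "weight", "hub_score")
  if (!is.null(k)) {
    if (k > nrow(out)) {
      warn(paste0("Requested ", k, " hubs but the subnetwork has ", nrow(out), " nodes; returning all."))
      k <- nrow(out)
    }
    out <- out[seq_len(k), , drop = FALSE]
  }
  out
}

#' Pairwise correlation relation of two proteins across processes
#'
#' For each requested process, two proteins are *correlated* when both
#' participate with the same weight sign, *anti-correlated* with opposite
#' signs, and *non-correlated* when either is below the weight threshold.
#'
#' @inheritParams process_proteins
#' @param processes integer vector of process indices (default all 1..m*).
#' @param protein_a,protein_b protein ids.
#' @return tibble `process`, `relation`, `sign_a`, `sign_b`.
#' @export
correlation_report <- function(d, model, protein_a, protein_b,
                               processes = seq_len(model$m_star)) {
  stopifnot(inherits(model, "significance_model"))
  for (p in c(protein_a, protein_b)) {
    if (!p %in% protein_ids(d)) abort(paste0("Unknown protein id: ", p))
  }
  purrr::map_dfr(processes, function(a) {
    thr <- model$weight_threshold[as.character(a)]
    ga <- g_col(d, a)[protein_a]; gb <- g_col(d, a)[protein_b]
    in_a <- abs(ga) >= thr; in_b <- abs(gb) >= thr
    tibble(
      process = as.integer(a),
      relation = if (!in_a || !in_b) "non-correlated"
                 else if (sign(ga) == sign(gb)) "correlated" else "anti-correlated",
      sign_a = if (in_a) as.integer(sign(ga)) else 0L,
      sign_b = if (in_b) as.integer(sign(gb)) else 0L
    )
  })
}

#' Export a subnetwork as SIF or GraphML
#'
#' SIF lines are `proteinA interacts proteinB`; isolated nodes are written as
#' single-column lines.  GraphML carries `weight`, `sign` node attributes and
#' `score` edge attributes (written via igraph).
#'
#' @param s a `subnetwork`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subnetwork_sif <- function(s, path) {
  stopifnot(inherits(s, "subnetwork"))
  lines <- c(
    sprintf("%s\tinteracts\t%s", s$edges$protein_a, s$edges$protein_b),
    s$nodes$protein_id[s$nodes$is_isolated]
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_subnetwork_sif
#' @export
write_subnetwork_graphml <- function(s, path) {
  stopifnot(inherits(s, "subnetwork"))
  g <- igraph::graph_from_data_frame(
    d = s$edges, directed = FALSE,
    vertices = as.data.frame(s$nodes[, c("protein_id", "gene", "weight", "sign")])
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
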