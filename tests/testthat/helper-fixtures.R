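# Shared fixtures and independent brute-force oracles.

# minimal decomposition object with known G / lambda (components in columns /
# rows including the steady state at index 1)
fake_decomp <- function(G, lambda, d = NULL, Y = NULL) {
  stopifnot(ncol(G) == nrow(lambda))
  comp <- as.character(seq_len(ncol(G)) - 1L)
  if (is.null(rownames(G))) rownames(G) <- paste0("p", seq_len(nrow(G)))
  if (is.null(colnames(lambda))) colnames(lambda) <- paste0("s", seq_len(ncol(lambda)))
  colnames(G) <- comp
  rownames(lambda) <- comp
  if (is.null(d)) d <- sort(sqrt(rowSums(lambda^2)), decreasing = TRUE)
  if (is.null(Y)) Y <- G %*% lambda
  structure(
    list(G = G, lambda = lambda, d = d, Y = Y, center = FALSE,
         row_means = rep(0, nrow(G)), scale_mode = "ln"),
    class = "surprisal_decomp"
  )
}

fake_model <- function(m_star, amp_threshold, weight_threshold) {
  structure(
    list(m_star = as.integer(m_star),
         amp_threshold = setNames(rep_len(amp_threshold, m_star), seq_len(m_star)),
         weight_threshold = setNames(rep_len(weight_threshold, m_star), seq_len(m_star)),
         c_amp = 2, c_w = 2, amp_method = "manual"),
    class = "significance_model"
  )
}

write_expr_tsv <- function(mat, path) {
  df <- as.data.frame(mat)
  df <- cbind(protein_id = rownames(mat), df)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

rand_barcode_matrix <- function(n, m, seed) {
  set.seed(seed)
  b <- matrix(sample(c(-1L, 0L, 1L), n * m, replace = TRUE, prob = c(0.2, 0.6, 0.2)),
              nrow = n, dimnames = list(paste0("s", seq_len(n)), as.character(seq_len(m))))
  class(b) <- c("barcode_matrix", class(b))
  b
}

# ---- brute-force oracles (kept deliberately naive) ----

# group barcodes by pairwise equality
brute_catalog_counts <- function(b) {
  keys <- character(0); counts <- integer(0)
  for (i in seq_len(nrow(b))) {
    k <- paste(b[i, ], collapse = ",")
    j <- match(k, keys)
    if (is.na(j)) { keys <- c(keys, k); counts <- c(counts, 1L) }
    else counts[j] <- counts[j] + 1L
  }
  setNames(counts, keys)
}

# scan every edge of the full list, keep those with both endpoints in nodes
brute_induced_edges <- function(edge_df, nodes) {
  keep <- logical(nrow(edge_df))
  for (i in seq_len(nrow(edge_df))) {
    keep[i] <- edge_df$protein_a[i] %in% nodes && edge_df$protein_b[i] %in% nodes
  }
  edge_df[keep, , drop = FALSE]
}

# recompute degree and score per node, full sort
brute_hub_rank <- function(nodes, edges) {
  deg <- vapply(nodes$protein_id, function(p) {
    sum(edges$protein_a == p) + sum(edges$protein_b == p)
  }, integer(1))
  score <- deg * abs(nodes$weight)
  ord <- order(-score, -abs(nodes$weight), nodes$protein_id)
  nodes$protein_id[ord]
}

# try all drug subsets in increasing size, return smallest complete cover
# (NULL if none); `covers` is a named list drug -> covered process ids
brute_min_cover <- function(covers, processes) {
  drugs <- sort(names(covers))
  for (size in seq_along(drugs)) {
    for (cc in utils::combn(length(drugs), size, simplify = FALSE)) {
      covered <- unique(unlist(covers[drugs[cc]]))
      if (all(processes %in% covered)) return(drugs[cc])
    }
  }
  NULL
}

# canonicalize an undirected edge list: sorted pairs, dedup, no loops
brute_edge_set <- function(a, b) {
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  unique(paste(a2, b2, sep = "|"))
}

# random weighted-set-cover instance with 2..6 processes
rand_cover_instance <- function(seed) {
  set.seed(seed)
  m <- sample(2:6, 1)
  nd <- sample(2:8, 1)
  cand <- purrr::map_dfr(seq_len(nd), function(j) {
    covered <- which(runif(m) < 0.45)
    if (length(covered) == 0) return(tibble::tibble())
    tibble::tibble(process = covered, drug = sprintf("d%02d", j),
                   target = sprintf("t%02d", j), protein_id = sprintf("t%02d", j),
                   hub_score = round(runif(length(covered)), 2))
  })
  list(active = tibble::tibble(process = seq_len(m), amplitude = 2), cand = cand)
}
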