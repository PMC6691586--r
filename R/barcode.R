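#' Per-sample process barcodes
#'
#' Normalizes significant amplitudes to -1/0/1: entry `alpha` of a sample's
#' barcode is the amplitude sign if process `alpha` is active in that sample
#' and 0 otherwise.  The barcode over the `m*` significant processes is the
#' sample's signaling signature; the all-zero barcode is the *null barcode*.
#'
#' @inheritParams active_processes
#' @return an integer matrix (samples x processes, entries in -1/0/1) with
#'   class `barcode_matrix`; rownames are sample ids, colnames `"1"..m*`.
#' @export
make_barcodes <- function(d, model, samples = NULL) {
  stopifnot(inherits(model, "significance_model"))
  samples <- check_samples(d, samples)
  b <- matrix(0L, nrow = length(samples), ncol = model$m_star,
              dimnames = list(samples, as.character(seq_len(model$m_star))))
  act <- active_processes(d, model, samples)
  if (nrow(act) > 0) b[cbind(act$sample_id, as.character(act$process))] <- act$sign
  class(b) <- c("barcode_matrix", class(b))
  b
}

#' @export
print.barcode_matrix <- function(x, ...) {
  cat("<barcode_matrix> ", nrow(x), " samples x ", ncol(x), " processes; ",
      sum(rowSums(x != 0) == 0), " null barcode(s)\n", sep = "")
  invisible(x)
}

#' @method tidy barcode_matrix
#' @export
tidy.barcode_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "process", values_to = "value") |>
    dplyr::mutate(process = as.integer(.data$process))
}

barcode_key <- function(b) {
  if (ncol(b) == 0) rep("", nrow(b)) else unname(apply(b, 1, paste, collapse = ","))
}

#' Build a cohort barcode catalog
#'
#' Groups identical barcodes, counts their recurrence, and (optionally)
#' tallies a per-sample label (e.g. cancer type) within each barcode.  Rows
#' are sorted by decreasing count, ties broken lexicographically on the
#' barcode string, so the catalog is deterministic.
#'
#' @param barcodes a `barcode_matrix` from [make_barcodes()].
#' @param labels optional character vector of per-sample labels, named by
#'   sample id or in row order.
#' @return a `barcode_catalog` tibble with columns `barcode` (string such as
#'   `"1,0,-1"`), `count`, `frac`, `is_null`, `sample_ids` (list-column) and,
#'   with labels, `label_counts` (list-column of named counts).  Attribute
#'   `n_samples` records the cohort size.
#' @export
build_catalog <- function(barcodes, labels = NULL) {
  if (!inherits(barcodes, "barcode_matrix")) {
    if (!is.matrix(barcodes)) abort("`barcodes` must be a barcode matrix.")
    class(barcodes) <- c("barcode_matrix", class(barcodes))
  }
  n <- nrow(barcodes)
  if (n == 0) abort("No barcodes to catalog.")
  key <- barcode_key(barcodes)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[rownames(barcodes)]
    if (length(labels) != n) abort("`labels` must match barcodes (length or names).")
  }
  df <- tibble(barcode = key, sample_id = rownames(barcodes),
               label = if (is.null(labels)) NA_character_ else as.character(labels))
  cat <- df |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      count = dplyr::n(),
      sample_ids = list(.data$sample_id),
      label_counts = list(if (all(is.na(.data$label))) NULL else table(.data$label)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      frac = .data$count / n,
      is_null = .data$barcode == paste(rep("0", ncol(barcodes)), collapse = ",")
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$barcode) |>
    dplyr::select("barcode", "count", "frac", "is_null", "sample_ids", "label_counts")
  attr(cat, "n_samples") <- n
  attr(cat, "n_processes") <- ncol(barcodes)
  class(cat) <- c("barcode_catalog", class(cat))
  cat
}

#' Classify barcode rarity
#'
#' Adds cohort-description recurrence classes: *abundant* barcodes represent at
#' least `abundant_frac` of the cohort, *rare* barcodes at most `rare_max`
#' samples, *singletons* exactly one.  Flags are independent (a singleton is
#' also rare); `rarity_class` gives one label per barcode with precedence
#' singleton > rare > abundant > intermediate.
#'
#' @param cat a `barcode_catalog`.
#' @param abundant_frac cohort fraction defining abundance (default 0.01).
#' @param rare_max maximum count of a rare barcode (default 5).
#' @return the catalog with added columns `is_abundant`, `is_rare`,
#'   `is_singleton`, `rarity_class`.
#' @export
classify_rarity <- function(cat, abundant_frac = 0.01, rare_max = 5) {
  stopifnot(inherits(cat, "barcode_catalog"))
  n <- attr(cat, "n_samples")
  out <- cat |>
    dplyr::mutate(
      is_abundant = .data$count >= abundant_frac * n,
      is_rare = .data$count <= rare_max,
      is_singleton = .data$count == 1L,
      rarity_class = dplyr::case_when(
        .data$count == 1L ~ "singleton",
        .data$count <= rare_max ~ "rare",
        .data$count >= abundant_frac * n ~ "abundant",
        TRUE ~ "intermediate"
      )
    )
  attr(out, "n_samples") <- n
  attr(out, "n_processes") <- attr(cat, "n_processes")
  class(out) <- class(cat)
  out
}

#' @method glance barcode_catalog
#' @export
glance.barcode_catalog <- function(x, ...) {
  n <- attr(x, "n_samples")
  tibble(
    n_samples = n,
    n_distinct = nrow(x),
    null_fraction = if (any(x$is_null)) x$frac[x$is_null] else 0,
    n_abundant = if ("is_abundant" %in% colnames(x)) sum(x$is_abundant) else NA_integer_,
    n_rare = if ("is_rare" %in% colnames(x)) sum(x$is_rare) else NA_integer_,
    n_singleton = if ("is_singleton" %in% colnames(x)) sum(x$is_singleton) else NA_integer_
  )
}

#' Write barcodes / catalog as TSV
#'
#' @param barcodes a `barcode_matrix`.
#' @param cat a `barcode_catalog`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  df <- as_tibble(unclass(barcodes), rownames = "sample_id")
  colnames(df)[-1] <- paste0("process_", colnames(df)[-1])
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_barcodes
#' @export
write_catalog <- function(cat, path) {
  stopifnot(inherits(cat, "barcode_catalog"))
  df <- cat |>
    dplyr::mutate(
      sample_ids = purrr::map_chr(.data$sample_ids, paste, collapse = ";"),
      label_counts = purrr::map_chr(.data$label_counts, function(t) {
        if (is.null(t)) NA_character_ else paste(names(t), unname(as.integer(t)), sep = ":", collapse = ";")
      })
    )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Add a new cohort and re-analyze the combined data
#'
#' Concatenates a new sample cohort onto the original expression matrix
#' (restricted to the shared protein vocabulary), re-runs the full
#' decomposition / plateau selection / thresholding / barcoding on the
#' combined matrix, and reports how the processes of the original analysis
#' map onto the combined ones (matched by maximum `|correlation|` of weight
#' columns over shared proteins).
#'
#' @param expr_old,expr_new [expr_matrix] objects; sample ids must not clash.
#' @param m_star optional fixed number of processes for the combined fit
#'   (default: re-selected by the plateau rule).
#' @param epsilon,frac plateau parameters, see [select_num_processes()].
#' @param c_amp,c_w threshold multipliers, see [fit_significance()].
#' @param min_overlap minimum fraction of the original protein vocabulary
#'   that must be shared (default 0.8); below it the cohorts are judged
#'   incomparable and an error is raised.
#' @param labels optional per-sample labels for the combined catalog.
#' @return a list of class `cohort_update`: `decomposition`, `model`,
#'   `barcodes`, `catalog`, `correspondence` (tibble `process_old`,
#'   `process_new`, `abs_cor`, `sign`), `new_sample_ids`, `shared_proteins`.
#' @export
add_cohort <- function(expr_old, expr_new, m_star = NULL,
                       epsilon = 0.005, frac = 0.95,
                       c_amp = 2, c_w = 2, min_overlap = 0.8,
                       labels = NULL) {
  stopifnot(inherits(expr_old, "expr_matrix"), inherits(expr_new, "expr_matrix"))
  shared <- intersect(protein_ids(expr_old), protein_ids(expr_new))
  if (length(shared) < min_overlap * length(protein_ids(expr_old))) {
    abort(paste0("Protein overlap ", length(shared), "/", length(protein_ids(expr_old)),
                 " is below the required fraction ", min_overlap, "."))
  }
  clash <- intersect(sample_ids(expr_old), sample_ids(expr_new))
  if (length(clash)) abort(paste0("Sample ids present in both cohorts: ",
                                  paste(head(clash, 3), collapse = ", "), "..."))

  Y_old <- ln_expression(expr_old)[shared, , drop = FALSE]
  Y_new <- ln_expression(expr_new)[shared, , drop = FALSE]
  d_old <- surprisal_decompose(Y_old)
  if (ncol(Y_new) == 0) {
    Y_comb <- Y_old
  } else {
    Y_comb <- cbind(Y_old, Y_new)
  }
  d_comb <- surprisal_decompose(Y_comb)

  curves_old <- r_squared_curve(d_old)
  m_old <- select_num_processes(curves_old, epsilon, frac)
  if (is.null(m_star)) {
    m_star <- select_num_processes(r_squared_curve(d_comb), epsilon, frac)
  }
  m_star <- max(1L, as.integer(m_star))
  m_old <- max(1L, m_old)

  model <- fit_significance(d_comb, m_star, c_amp, c_w)
  barcodes <- make_barcodes(d_comb, model)
  catalog <- classify_rarity(build_catalog(barcodes, labels))

  # old process -> combined process, greedy max-|cor| assignment on G columns
  n_match <- min(m_old, m_star)
  C <- abs(cor(d_old$G[, seq_len(m_old) + 1L, drop = FALSE],
               d_comb$G[, seq_len(m_star) + 1L, drop = FALSE]))
  S <- sign(cor(d_old$G[, seq_len(m_old) + 1L, drop = FALSE],
                d_comb$G[, seq_len(m_star) + 1L, drop = FALSE]))
  corr <- greedy_match(C)
  correspondence <- tibble(
    process_old = corr$row, process_new = corr$col,
    abs_cor = corr$value,
    sign = S[cbind(corr$row, corr$col)]
  ) |> dplyr::arrange(.data$process_old)

  structure(
    list(decomposition = d_comb, model = model, barcodes = barcodes,
         catalog = catalog, correspondence = correspondence,
         m_old = m_old,
         new_sample_ids = colnames(Y_new), shared_proteins = shared),
    class = "cohort_update"
  )
}

# greedy maximum-|value| bipartite assignment on a rows x cols matrix
greedy_match <- function(C) {
  C <- as.matrix(C)
  n <- min(nrow(C), ncol(C))
  rows <- integer(n); cols <- integer(n); vals <- numeric(n)
  Cw <- C
  for (i in seq_len(n)) {
    idx <- which(Cw == max(Cw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    rows[i] <- idx[1]; cols[i] <- idx[2]; vals[i] <- C[idx[1], idx[2]]
    Cw[idx[1], ] <- -Inf
    Cw[, idx[2]] <- -Inf
  }
  ord <- order(rows)
  list(row = rows[ord], col = cols[ord], value = vals[ord])
}

#' @export
print.cohort_update <- function(x, ...) {
  cat("<cohort_update> added ", length(x$new_sample_ids), " samples over ",
      length(x$shared_proteins), " shared proteins; m* = ", x$model$m_star, "\n", sep = "")
  print(x$correspondence, n = 5)
  invisible(x)
}
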