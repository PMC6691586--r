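#' Construct an expression matrix object
#'
#' An `expr_matrix` holds a proteins x samples abundance matrix together with
#' the scale its values are recorded on.  Raw abundances must be strictly
#' positive (their natural log is taken downstream); `"ln"` and `"log2"`
#' declare already-logged values.  `log2` values are converted to natural log
#' at construction so that a single internal scale (`ln`) feeds the
#' decomposition.
#'
#' @param values numeric matrix, proteins in rows, samples in columns, with
#'   unique non-empty dimnames.
#' @param scale_mode one of `"raw"`, `"ln"`, `"log2"`.
#' @param na_action `"error"` (default) rejects missing values; `"impute"`
#'   replaces each missing cell by the per-protein median (count reported via
#'   a message and stored in the object).
#'
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   (the matrix; natural-log scale if input was `log2`), `scale_mode`
#'   (`"raw"` or `"ln"` after conversion) and `n_imputed`.
#' @export
expr_matrix <- function(values,
                        scale_mode = c("raw", "ln", "log2"),
                        na_action = c("error", "impute")) {
  scale_mode <- match.arg(scale_mode)
  na_action <- match.arg(na_action)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (proteins x samples).")
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(sid) && ncol(values) == 0) sid <- colnames(values) <- character(0)
  if (is.null(pid) || is.null(sid) || any(pid == "") || any(sid == "")) {
    abort("`values` must have non-empty row (protein) and column (sample) names.")
  }
  if (anyDuplicated(pid)) {
    abort(paste0("Duplicate protein ids: ",
                 paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }

  n_imputed <- 0L
  if (anyNA(values)) {
    if (na_action == "error") {
      abort("Missing values present; use na_action = \"impute\" to median-impute per protein.")
    }
    n_imputed <- sum(is.na(values))
    for (i in seq_len(nrow(values))) {
      miss <- is.na(values[i, ])
      if (any(miss)) {
        med <- median(values[i, !miss])
        if (is.na(med)) abort(paste0("Protein ", pid[i], " has no observed values to impute from."))
        values[i, miss] <- med
      }
    }
    inform(paste0("Imputed ", n_imputed, " missing value(s) by per-protein median."))
  }
  if (any(!is.finite(values))) abort("Non-finite values in expression matrix.")
  if (scale_mode == "raw" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1, ]
    abort(paste0("Raw-mode expression must be strictly positive; offending cell: protein ",
                 pid[bad[1]], ", sample ", sid[bad[2]],
                 " (value ", values[bad[1], bad[2]], ")."))
  }
  if (scale_mode == "log2") {
    values <- values * log(2)
    scale_mode <- "ln"
  }
  structure(
    list(values = values, scale_mode = scale_mode, n_imputed = n_imputed),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " proteins x ", ncol(x$values),
      " samples, scale = ", x$scale_mode,
      if (x$n_imputed > 0) paste0(" (", x$n_imputed, " imputed)"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Protein and sample identifiers
#' @param x an `expr_matrix` or `surprisal_decomp`.
#' @return character vector of ids.
#' @export
protein_ids <- function(x) UseMethod("protein_ids")
#' @export
protein_ids.expr_matrix <- function(x) rownames(x$values)
#' @rdname protein_ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.expr_matrix <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds protein ids and whose
#' header row holds sample ids.  Every cell must parse as a number; duplicate
#' ids and (in raw mode) non-positive values are rejected with the offending
#' id or cell named.
#'
#' @param path path to a TSV file.
#' @inheritParams expr_matrix
#' @return an [expr_matrix] object.
#' @export
read_expression_matrix <- function(path,
                                   scale_mode = c("raw", "ln", "log2"),
                                   na_action = c("error", "impute")) {
  scale_mode <- match.arg(scale_mode)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2 || nrow(df) < 1) abort("Expression TSV needs >= 1 protein row and >= 1 sample column.")
  pid <- df[[1]]
  sid <- colnames(df)[-1]
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells) & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(paste0("Non-numeric cell at protein ", pid[bad[1, 1]], ", sample ",
                 sid[bad[1, 2]], ": \"", cells[bad[1, 1], bad[1, 2]], "\"."))
  }
  dimnames(num) <- list(pid, sid)
  m <- expr_matrix(num, scale_mode = scale_mode, na_action = na_action)
  inform(paste0("Read expression matrix: ", nrow(num), " proteins x ", ncol(num), " samples."))
  m
}

#' Write an expression matrix to TSV
#'
#' Values are written at full precision (`%.17g`) so a write/read round trip
#' reproduces them bit-exactly.
#'
#' @param x an [expr_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- as.data.frame(apply(x$values, 2, function(col) sprintf("%.17g", col)),
                      optional = TRUE)
  colnames(df) <- colnames(x$values)
  df <- cbind(protein_id = rownames(x$values), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Rename proteins via an alias map
#'
#' Antibody-level ids (e.g. `"pY(1068)EGFR"`) often need mapping to gene
#' symbols before interaction-database lookup.  The map is applied by exact
#' string match; ids absent from the map pass through unchanged.
#'
#' @param ids character vector of protein ids.
#' @param alias named character vector, `names(alias)` are antibody/protein ids
#'   and values the replacement (gene) ids, or `NULL` for identity.
#' @return character vector of mapped ids.
#' @export
apply_alias <- function(ids, alias = NULL) {
  if (is.null(alias)) return(ids)
  if (is.null(names(alias))) abort("`alias` must be a named character vector.")
  hit <- ids %in% names(alias)
  ids[hit] <- unname(alias[ids[hit]])
  ids
}

#' @method tidy expr_matrix
#' @export
tidy.expr_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "sample_id", values_to = "value")
}

#' @method glance expr_matrix
#' @export
glance.expr_matrix <- function(x, ...) {
  tibble(n_proteins = nrow(x$values), n_samples = ncol(x$values),
         scale_mode = x$scale_mode, n_imputed = x$n_imputed)
}

#' Natural-log expression values
#'
#' Returns the matrix fed to the surprisal decomposition: elementwise natural
#' log for raw abundances, pass-through for values already on the ln scale
#' (`log2` input was converted at load).
#'
#' @param x an [expr_matrix].
#' @return numeric matrix on the natural-log scale.
#' @export
ln_expression <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale_mode == "raw") {
    if (any(x$values <= 0)) abort("Raw values must be strictly positive for ln transform.")
    log(x$values)
  } else {
    x$values
  }
}
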