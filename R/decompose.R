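#' Surprisal-analysis decomposition of an expression matrix
#'
#' Fits the surprisal-analysis expansion of the ln-expression matrix by
#' singular value decomposition.  Writing `Y = ln X` (proteins x samples),
#' the SVD `Y = U D V'` is stored as protein weights `G = U` and sample
#' amplitudes `Lambda = D V'`, so that
#'
#'   `ln X_i(k) = sum_alpha G[i, alpha] * Lambda[alpha, k]`
#'
#' Component `alpha = 0` (the largest singular value) is the balanced steady
#' state; components `alpha >= 1` are candidate unbalanced processes, ordered
#' by decreasing singular value.  The SVD sign ambiguity is resolved per
#' component: the weight of largest magnitude is made positive and the
#' amplitude row flipped accordingly, so output is deterministic and
#' basis-independent.
#'
#' Sample-specific deviation contributions are the products
#' `G[i, alpha] * Lambda[alpha, k]`; a positive product means the protein is
#' pushed up by the process in that sample (see [direction_of_change()]).
#'
#' @param x an [expr_matrix], or a bare numeric matrix already on the ln scale
#'   (with dimnames).
#' @param center if `TRUE`, protein rows are mean-centered before the SVD
#'   (the steady state is then carried by the stored row means rather than
#'   component 0).  Default `FALSE`: the steady state is component 0.
#' @return a `surprisal_decomp` object: list with `G` (proteins x components),
#'   `lambda` (components x samples), `d` (singular values, non-increasing),
#'   `Y` (the ln matrix), `center`, `row_means`.  Components are labelled
#'   `"0"`, `"1"`, ... with `"0"` the steady state.
#' @export
surprisal_decompose <- function(x, center = FALSE) {
  Y <- if (inherits(x, "expr_matrix")) ln_expression(x) else x
  if (!is.matrix(Y) || !is.numeric(Y)) abort("Input must be an expr_matrix or numeric matrix.")
  if (is.null(rownames(Y)) || is.null(colnames(Y))) {
    rownames(Y) <- rownames(Y) %||% paste0("protein_", seq_len(nrow(Y)))
    colnames(Y) <- colnames(Y) %||% paste0("sample_", seq_len(ncol(Y)))
  }
  if (any(!is.finite(Y))) abort("Non-finite entries in ln-expression matrix.")
  if (nrow(Y) < 2 || ncol(Y) < 2) abort("Need at least 2 proteins and 2 samples.")

  row_means <- rep(0, nrow(Y))
  Yfit <- Y
  if (center) {
    row_means <- rowMeans(Y)
    Yfit <- Y - row_means
  }
  s <- svd(Yfit)
  G <- s$u
  lambda <- s$d * t(s$v)   # row alpha = d_alpha * v[, alpha]

  # sign convention: largest-|weight| entry of each G column is positive
  for (j in seq_len(ncol(G))) {
    i_max <- which.max(abs(G[, j]))
    if (G[i_max, j] < 0) {
      G[, j] <- -G[, j]
      lambda[j, ] <- -lambda[j, ]
    }
  }
  comp <- as.character(seq_len(ncol(G)) - 1L)
  dimnames(G) <- list(rownames(Y), comp)
  dimnames(lambda) <- list(comp, colnames(Y))

  structure(
    list(G = G, lambda = lambda, d = s$d, Y = Y,
         center = center, row_means = row_means,
         scale_mode = if (inherits(x, "expr_matrix")) x$scale_mode else "ln"),
    class = "surprisal_decomp"
  )
}

#' @export
print.surprisal_decomp <- function(x, ...) {
  cat("<surprisal_decomp> ", nrow(x$G), " proteins x ", ncol(x$lambda),
      " samples, ", length(x$d), " components (0 = steady state)\n", sep = "")
  cat("  singular values: ", paste(signif(head(x$d, 5), 4), collapse = ", "),
      if (length(x$d) > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
protein_ids.surprisal_decomp <- function(x) rownames(x$G)
#' @export
sample_ids.surprisal_decomp <- function(x) colnames(x$lambda)

n_components <- function(d) length(d$d)

# amplitude row of unbalanced process alpha (1-based process index = component alpha)
lambda_row <- function(d, alpha) d$lambda[alpha + 1L, ]
g_col <- function(d, alpha) d$G[, alpha + 1L]

#' Partial reconstruction from the leading components
#'
#' Sums components `0..n_processes` (steady state plus the first
#' `n_processes` unbalanced processes) and adds back row means when the
#' decomposition was centered.
#'
#' @param d a `surprisal_decomp`.
#' @param n_processes number of unbalanced processes to include
#'   (`0` = steady state only); must be `<= n_components - 1`.
#' @return numeric matrix, same shape as the input ln matrix.
#' @export
reconstruct <- function(d, n_processes) {
  stopifnot(inherits(d, "surprisal_decomp"))
  r <- n_components(d)
  if (!is.numeric(n_processes) || length(n_processes) != 1 ||
      n_processes < 0 || n_processes > r - 1) {
    abort(paste0("`n_processes` must be in 0..", r - 1, "."))
  }
  idx <- seq_len(n_processes + 1L)
  d$G[, idx, drop = FALSE] %*% d$lambda[idx, , drop = FALSE] + d$row_means
}

#' Per-sample R-squared convergence curves
#'
#' For each sample `k` and each truncation `m`, computes the squared Pearson
#' correlation across proteins between the observed ln expression and the
#' reconstruction from components `0..m`.  The curve rises towards 1 and
#' plateaus once all signal-bearing processes are included; the plateau
#' position is how the number of significant processes is chosen
#' ([select_num_processes()]).
#'
#' Orthonormality of the weight columns gives a closed form using only the
#' amplitude matrix and column statistics of `G`, so the curves cost
#' O(components x samples).
#'
#' @param d a `surprisal_decomp`.
#' @param Y optional ln matrix to compare against (defaults to the matrix the
#'   decomposition was fitted to).
#' @param samples optional character vector restricting to some sample ids.
#' @return tibble with columns `sample_id`, `n_processes` (m), `r_squared`.
#' @export
r_squared_curve <- function(d, Y = NULL, samples = NULL) {
  stopifnot(inherits(d, "surprisal_decomp"))
  Y <- Y %||% d$Y
  if (d$center) Y <- Y - d$row_means
  ids <- colnames(d$lambda)
  if (!is.null(samples)) {
    missing <- setdiff(samples, ids)
    if (length(missing)) abort(paste0("Unknown sample id(s): ", paste(missing, collapse = ", ")))
    keep <- ids %in% samples
    Y <- Y[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  lam <- d$lambda[, ids, drop = FALSE]
  n <- nrow(d$G)
  r <- n_components(d)

  Q <- crossprod(d$G, Y)                      # y . g_j per (component, sample)
  gbar <- colMeans(d$G)
  ybar <- colMeans(Y)
  Syy <- colSums(Y^2) - n * ybar^2

  cum_dot  <- apply(lam * Q, 2, cumsum)        # sum_j a_j (y . g_j)
  cum_mean <- apply(lam * gbar, 2, cumsum)     # yhat mean = sum_j a_j gbar_j
  cum_sq   <- apply(lam^2, 2, cumsum)          # ||yhat||^2 (orthonormal G)
  if (ncol(Y) == 1) {                          # apply() drops to vector
    cum_dot <- matrix(cum_dot, ncol = 1); cum_mean <- matrix(cum_mean, ncol = 1)
    cum_sq <- matrix(cum_sq, ncol = 1)
  }

  Sxy <- cum_dot - n * sweep(cum_mean, 2, ybar, `*`)
  Shh <- cum_sq - n * cum_mean^2
  Shh[Shh < 0] <- 0

  r2 <- matrix(NA_real_, nrow = r, ncol = length(ids))
  denom <- sweep(Shh, 2, Syy, `*`)
  ok <- denom > .Machine$double.eps * n
  r2[ok] <- (Sxy[ok]^2) / denom[ok]
  if (any(!ok)) {
    # zero-variance reconstruction (or observed column): 1 if residual ~ 0, else 0
    warn("Zero-variance column encountered in R-squared curve; defining R^2 by residual.")
    for (k in which(colSums(!ok) > 0)) {
      for (m in which(!ok[, k])) {
        idx <- seq_len(m)
        res <- Y[, k] - d$G[, idx, drop = FALSE] %*% lam[idx, k, drop = FALSE]
        r2[m, k] <- if (sum(res^2) <= 1e-16 * max(1, sum(Y[, k]^2))) 1 else 0
      }
    }
  }
  r2[r2 > 1] <- 1
  tibble(
    sample_id = rep(ids, each = r),
    n_processes = rep(0:(r - 1L), times = length(ids)),
    r_squared = as.vector(r2)
  )
}

#' Choose the number of significant unbalanced processes
#'
#' Scans the per-sample R-squared convergence curves for the plateau: the
#' smallest `m` such that, for at least a fraction `frac` of samples, adding
#' process `m + 1` improves R-squared by less than `epsilon`.  Components past
#' the plateau behave like noise and are excluded.
#'
#' @param curves tibble from [r_squared_curve()] over all samples.
#' @param epsilon minimum per-process R-squared gain that counts as signal
#'   (default 0.005).
#' @param frac fraction of samples that must have plateaued (default 0.95).
#' @return integer `m*`, the number of unbalanced processes (steady state not
#'   counted).  If no plateau occurs before the last component, returns
#'   `max(m)` with a warning.
#' @export
select_num_processes <- function(curves, epsilon = 0.005, frac = 0.95) {
  stopifnot(all(c("sample_id", "n_processes", "r_squared") %in% colnames(curves)))
  if (nrow(curves) == 0) abort("Empty R-squared curves.")
  gains <- curves |>
    dplyr::arrange(.data$sample_id, .data$n_processes) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(gain = dplyr::lead(.data$r_squared) - .data$r_squared) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gain))
  plateau <- gains |>
    dplyr::group_by(.data$n_processes) |>
    dplyr::summarise(frac_flat = mean(.data$gain < epsilon), .groups = "drop") |>
    dplyr::arrange(.data$n_processes)
  hit <- plateau$n_processes[plateau$frac_flat >= frac]
  if (length(hit) == 0) {
    m_max <- max(curves$n_processes)
    warn(paste0("No R-squared plateau before the last component; returning ", m_max, "."))
    return(as.integer(m_max))
  }
  as.integer(hit[1])
}

#' @method tidy surprisal_decomp
#' @export
tidy.surprisal_decomp <- function(x, matrix = c("lambda", "G", "d"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    lambda = as_tibble(x$lambda, rownames = "process") |>
      tidyr::pivot_longer(-"process", names_to = "sample_id", values_to = "amplitude") |>
      dplyr::mutate(process = as.integer(.data$process)),
    G = as_tibble(x$G, rownames = "protein_id") |>
      tidyr::pivot_longer(-"protein_id", names_to = "process", values_to = "weight") |>
      dplyr::mutate(process = as.integer(.data$process)),
    d = tibble(process = seq_along(x$d) - 1L, singular_value = x$d)
  )
}

#' @method glance surprisal_decomp
#' @export
glance.surprisal_decomp <- function(x, ...) {
  rel <- norm(x$G %*% x$lambda + x$row_means - x$Y, "F") / max(norm(x$Y, "F"), .Machine$double.eps)
  tibble(n_proteins = nrow(x$G), n_samples = ncol(x$lambda),
         n_components = length(x$d), centered = x$center,
         reconstruction_rel_error = rel)
}

#' Write a decomposition to a directory
#'
#' Writes `G.tsv`, `lambda.tsv`, `singular_values.tsv` and `manifest.json`
#' (shapes, scale mode, sign-convention tag, centering) under `dir`.
#'
#' @param d a `surprisal_decomp`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(d, dir) {
  stopifnot(inherits(d, "surprisal_decomp"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(as_tibble(d$G, rownames = "protein_id"), file.path(dir, "G.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(d$lambda, rownames = "process"), file.path(dir, "lambda.tsv"), progress = FALSE)
  readr::write_tsv(tibble(process = seq_along(d$d) - 1L, singular_value = d$d),
                   file.path(dir, "singular_values.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(n_proteins = nrow(d$G), n_samples = ncol(d$lambda),
         n_components = length(d$d), scale_mode = d$scale_mode,
         centered = d$center, sign_convention = "max-abs-weight-positive"),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
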