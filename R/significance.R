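#' Fit amplitude and weight significance thresholds
#'
#' A process is *active* in a sample when its amplitude exceeds what the noise
#' components produce; a protein *participates* in a process when its weight
#' exceeds what a null orthonormal column would give.  Both thresholds are
#' data-driven:
#'
#' * amplitude: `c_amp` times the pooled (root-mean-square) amplitude of the
#'   components beyond `m_star`, which carry noise by construction.  One value
#'   is computed from the pool and applied per process.
#' * weight: `c_w / sqrt(n_proteins)` — an orthonormal column of random
#'   direction has entries with SD `1/sqrt(n_proteins)`, so the default
#'   `c_w = 2` is a two-sided ~2 SD cut.
#'
#' When no components beyond `m_star` exist the amplitude rule falls back to a
#' per-process median-absolute-deviation scale with a warning.
#'
#' @param d a `surprisal_decomp`.
#' @param m_star number of significant unbalanced processes (e.g. from
#'   [select_num_processes()]); must be >= 1.
#' @param c_amp amplitude threshold multiplier (default 2).
#' @param c_w weight threshold multiplier (default 2).
#' @return a `significance_model`: list with `m_star`, `amp_threshold`
#'   (length `m_star`, named by process), `weight_threshold` (length
#'   `m_star`), `c_amp`, `c_w`, `amp_method`.
#' @export
fit_significance <- function(d, m_star, c_amp = 2, c_w = 2) {
  stopifnot(inherits(d, "surprisal_decomp"))
  r <- n_components(d)
  if (!is.numeric(m_star) || length(m_star) != 1 || m_star < 1 || m_star > r - 1) {
    abort(paste0("`m_star` must be in 1..", r - 1, "."))
  }
  m_star <- as.integer(m_star)
  noise_rows <- if (m_star + 2L <= r) (m_star + 2L):r else integer(0)
  if (length(noise_rows) > 0) {
    pooled <- sqrt(mean(d$lambda[noise_rows, , drop = FALSE]^2))
    amp_thr <- rep(c_amp * pooled, m_star)
    amp_method <- "pooled-noise-rms"
  } else {
    warn("No noise components beyond m_star; falling back to per-process MAD amplitude thresholds.")
    amp_thr <- vapply(seq_len(m_star), function(a) c_amp * mad(lambda_row(d, a)), numeric(1))
    amp_method <- "per-process-mad"
  }
  if (any(amp_thr <= 0)) abort("Computed non-positive amplitude threshold; degenerate decomposition.")
  names(amp_thr) <- as.character(seq_len(m_star))
  w_thr <- rep(c_w / sqrt(nrow(d$G)), m_star)
  names(w_thr) <- names(amp_thr)
  structure(
    list(m_star = m_star, amp_threshold = amp_thr, weight_threshold = w_thr,
         c_amp = c_amp, c_w = c_w, amp_method = amp_method),
    class = "significance_model"
  )
}

#' @export
print.significance_model <- function(x, ...) {
  cat("<significance_model> m* = ", x$m_star,
      ", amp threshold ~ ", signif(x$amp_threshold[1], 4),
      " (", x$amp_method, "), weight threshold ",
      signif(x$weight_threshold[1], 4), "\n", sep = "")
  invisible(x)
}

#' @method glance significance_model
#' @export
glance.significance_model <- function(x, ...) {
  tibble(m_star = x$m_star, amp_method = x$amp_method,
         c_amp = x$c_amp, c_w = x$c_w,
         weight_threshold = x$weight_threshold[1])
}

#' Write/read a significance model as JSON
#' @param model a `significance_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_significance_model` returns the model.
#' @export
write_significance_model <- function(model, path) {
  stopifnot(inherits(model, "significance_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_significance_model
#' @export
read_significance_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$m_star <- as.integer(x$m_star)
  names(x$amp_threshold) <- names(x$weight_threshold) <- as.character(seq_len(x$m_star))
  structure(x[c("m_star", "amp_threshold", "weight_threshold", "c_amp", "c_w", "amp_method")],
            class = "significance_model")
}

check_samples <- function(d, samples) {
  ids <- sample_ids(d)
  if (is.null(samples)) return(ids)
  missing <- setdiff(samples, ids)
  if (length(missing)) abort(paste0("Unknown sample id(s): ", paste(missing, collapse = ", ")))
  samples
}

#' Active processes per sample
#'
#' A process `alpha` (1..m*) is active in sample `k` when
#' `|lambda_alpha(k)| >= amp_threshold[alpha]`; its sign is the amplitude
#' sign.  The set of active processes is the sample's signaling signature.
#'
#' @param d a `surprisal_decomp`.
#' @param model a `significance_model`.
#' @param samples optional sample ids (default: all).
#' @return tibble with columns `sample_id`, `process`, `amplitude`, `sign`.
#' @export
active_processes <- function(d, model, samples = NULL) {
  stopifnot(inherits(model, "significance_model"))
  samples <- check_samples(d, samples)
  lam <- d$lambda[seq_len(model$m_star) + 1L, samples, drop = FALSE]
  act <- abs(lam) >= model$amp_threshold  # thresholds recycle down rows
  idx <- which(act, arr.ind = TRUE)
  tibble(
    sample_id = samples[idx[, 2]],
    process = as.integer(idx[, 1]),
    amplitude = lam[idx],
    sign = as.integer(sign(lam[idx]))
  ) |>
    dplyr::arrange(match(.data$sample_id, samples), .data$process)
}

#' Proteins participating in a process
#'
#' Returns the proteins whose absolute weight in process `alpha` meets the
#' weight threshold, sorted by decreasing `|weight|` (ties by protein id).
#'
#' @inheritParams active_processes
#' @param alpha process index in 1..m*.
#' @return tibble with columns `protein_id`, `weight`, `sign`.
#' @export
process_proteins <- function(d, model, alpha) {
  stopifnot(inherits(model, "significance_model"))
  if (alpha < 1 || alpha > model$m_star) abort(paste0("`alpha` must be in 1..", model$m_star, "."))
  g <- g_col(d, alpha)
  keep <- abs(g) >= model$weight_threshold[as.character(alpha)]
  if (!any(keep)) warn(paste0("No proteins pass the weight threshold for process ", alpha, "."))
  tibble(protein_id = names(g)[keep], weight = unname(g[keep]),
         sign = as.integer(sign(g[keep]))) |>
    dplyr::arrange(dplyr::desc(abs(.data$weight)), .data$protein_id)
}

#' Direction of change of a protein in a sample due to a process
#'
#' The contribution of process `alpha` to protein `i` in sample `k` is
#' `G[i, alpha] * lambda_alpha(k)`: positive means the process pushes the
#' protein up in that sample, negative down.  A protein that does not
#' participate in the process (weight below threshold) returns `"none"`.
#' The result is invariant under the SVD sign gauge, since the product of the
#' two signs is.
#'
#' @inheritParams process_proteins
#' @param sample a sample id.
#' @param protein a protein id.
#' @return `"up"`, `"down"` or `"none"`.
#' @export
direction_of_change <- function(d, model, sample, alpha, protein) {
  stopifnot(inherits(model, "significance_model"))
  check_samples(d, sample)
  if (!protein %in% protein_ids(d)) abort(paste0("Unknown protein id: ", protein))
  if (alpha < 1 || alpha > model$m_star) abort(paste0("`alpha` must be in 1..", model$m_star, "."))
  g <- g_col(d, alpha)[protein]
  if (abs(g) < model$weight_threshold[as.character(alpha)]) return("none")
  contrib <- g * lambda_row(d, alpha)[sample]
  if (contrib > 0) "up" else if (contrib < 0) "down" else "none"
}
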