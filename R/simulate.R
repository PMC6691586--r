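#' Simulate an expression matrix with planted unbalanced processes
#'
#' Generates a positive proteins x samples abundance matrix whose natural log
#' is a planted low-rank surprisal structure plus i.i.d. Gaussian noise:
#'
#'   `ln X = baseline %o% steady + sum_alpha G_alpha %o% lambda_alpha + noise`
#'
#' * the steady state is a rank-1 term: per-protein baseline ln-levels
#'   (`N(baseline_mean, baseline_sd^2)`) times a per-sample factor
#'   `1 + N(0, steady_jitter^2)`, so the dominant SVD component is the
#'   balanced state;
#' * each planted process has a sparse unit-norm weight column whose support
#'   entries have equal magnitude `1/sqrt(support size)` and random sign, so
#'   every planted member carries a clearly non-null weight (supports are
#'   disjoint by default, keeping the columns exactly orthogonal and the
#'   planted membership unambiguous; `overlap = TRUE` draws supports
#'   independently and Gram-Schmidt-orthogonalizes);
#' * process `alpha` is active in a sample with probability
#'   `activity_rate * activity_decay^(alpha - 1)` — prevalences decay across
#'   processes, as in real cohorts where the leading process is the most
#'   recurrent; the decay also separates the planted singular values so the
#'   processes are identifiable by SVD.  Samples ending up with more than
#'   `max_active` active processes are trimmed to a random
#'   `max_active`-subset.  Active amplitudes are
#'   `sign * N(amp_scale, (amp_scale/10)^2)` magnitudes (a zero-inflated
#'   two-component law, so "active" is well defined in truth); inactive
#'   amplitudes are exactly 0.  Signs are balanced across samples by a greedy
#'   scheme that keeps the planted amplitude rows mutually near-orthogonal
#'   (and sum-balanced against the steady state) — planted processes are
#'   *orthogonal* constraints, which is the identifiability premise of the
#'   SVD fit; with naive i.i.d. signs the rows acquire O(sqrt(n_samples))
#'   cross-correlations that rotate the recovered components;
#' * noise is i.i.d. `N(0, noise_sd^2)` on the ln scale, so
#'   `amp_scale / noise_sd` is the signal-to-noise ratio.
#'
#' @param n_proteins,n_samples matrix dimensions (defaults 200 x 150).
#' @param n_processes number of planted processes `P` (default 3); must be
#'   `< min(n_proteins, n_samples)`.
#' @param sparsity fraction of proteins in each process support (default
#'   0.05, i.e. 10 proteins per process at the default size).
#' @param amp_scale typical active amplitude magnitude (default 1).
#' @param noise_sd ln-scale noise SD (default 0.2, i.e. SNR 5).
#' @param max_active maximum processes active per sample (default 4).
#' @param activity_rate activation probability of process 1 (default 0.95).
#' @param activity_decay geometric decay of activation probability across
#'   processes (default 0.8).
#' @param baseline_mean,baseline_sd per-protein steady-state ln-level law.
#' @param steady_jitter SD of the per-sample steady-state factor around 1.
#' @param overlap allow overlapping process supports (stress-test mode).
#' @param seed integer seed; the output is a deterministic function of the
#'   arguments and the seed.
#' @return list with `expression` (an [expr_matrix], raw scale) and `truth`
#'   (class `synthetic_truth`): `baseline`, `steady`, `G` (proteins x P),
#'   `lambda` (P x samples), `support` (list of protein-id vectors),
#'   `active` (logical P x samples), `barcodes` (truth `barcode_matrix`),
#'   `params`.
#' @export
simulate_expression <- function(n_proteins = 200, n_samples = 150,
                                n_processes = 3, sparsity = 0.05,
                                amp_scale = 1, noise_sd = 0.2,
                                max_active = 4,
                                activity_rate = 0.95, activity_decay = 0.8,
                                baseline_mean = 6, baseline_sd = 1,
                                steady_jitter = 0.02,
                                overlap = FALSE, seed = 1) {
  P <- n_processes
  if (P >= min(n_proteins, n_samples)) abort("`n_processes` must be < min(n_proteins, n_samples).")
  if (amp_scale <= 0 || noise_sd < 0) abort("`amp_scale` must be > 0 and `noise_sd` >= 0.")
  if (n_proteins < 2 || n_samples < 2) abort("Need at least 2 proteins and 2 samples.")
  set.seed(as.integer(seed))

  pid <- sprintf("prot_%03d", seq_len(n_proteins))
  sid <- sprintf("sample_%03d", seq_len(n_samples))
  baseline <- rnorm(n_proteins, baseline_mean, baseline_sd)
  steady <- 1 + rnorm(n_samples, 0, steady_jitter)

  k_support <- max(2L, round(sparsity * n_proteins))
  G <- matrix(0, n_proteins, P)
  support <- vector("list", P)
  if (P > 0) {
    if (!overlap) {
      if (P * k_support > n_proteins) abort("Disjoint supports need n_processes * sparsity * n_proteins <= n_proteins.")
      pool <- sample(n_proteins, P * k_support)
      for (a in seq_len(P)) {
        idx <- pool[((a - 1) * k_support + 1):(a * k_support)]
        support[[a]] <- sort(idx)
        G[idx, a] <- sample(c(-1, 1), k_support, replace = TRUE)
      }
    } else {
      for (a in seq_len(P)) {
        idx <- sort(sample(n_proteins, k_support))
        support[[a]] <- idx
        G[idx, a] <- sample(c(-1, 1), k_support, replace = TRUE)
      }
    }
    # Gram-Schmidt: exact orthonormal planted weights
    for (a in seq_len(P)) {
      v <- G[, a]
      if (a > 1) v <- v - G[, seq_len(a - 1), drop = FALSE] %*%
          crossprod(G[, seq_len(a - 1), drop = FALSE], v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) abort("Degenerate planted weight column; try another seed.")
      G[, a] <- v / nv
    }
  }

  active <- matrix(FALSE, P, n_samples)
  lambda <- matrix(0, P, n_samples)
  if (P > 0) {
    # stratified design: process alpha is active in exactly
    # round(n_samples * rate * decay^(alpha-1)) randomly chosen samples, so
    # process prevalences (and hence singular-value gaps) do not fluctuate
    p_act <- pmin(1, activity_rate * activity_decay^(seq_len(P) - 1))
    for (a in seq_len(P)) {
      n_act <- max(1L, round(n_samples * p_act[a]))
      active[a, sample(n_samples, n_act)] <- TRUE
    }
    for (k in seq_len(n_samples)) {
      acts <- which(active[, k])
      if (length(acts) > max_active) {
        drop_idx <- sample(acts, length(acts) - max_active)
        active[drop_idx, k] <- FALSE
        acts <- setdiff(acts, drop_idx)
      }
      if (length(acts) > 0) {
        lambda[acts, k] <- abs(rnorm(length(acts), amp_scale, amp_scale / 10))
      }
    }
    base_sign <- matrix(sample(c(-1, 1), P * n_samples, replace = TRUE), P, n_samples)
    lambda <- balance_signs(lambda, base_sign)
  }

  lnX <- baseline %o% steady +
    (if (P > 0) G %*% lambda else 0) +
    matrix(rnorm(n_proteins * n_samples, 0, noise_sd), n_proteins, n_samples)
  dimnames(lnX) <- list(pid, sid)
  dimnames(G) <- list(pid, if (P > 0) as.character(seq_len(P)) else NULL)
  dimnames(lambda) <- list(if (P > 0) as.character(seq_len(P)) else NULL, sid)
  support <- lapply(support, function(idx) pid[idx])

  truth_barcodes <- matrix(0L, nrow = n_samples, ncol = P,
                           dimnames = list(sid, if (P > 0) as.character(seq_len(P)) else NULL))
  if (P > 0) truth_barcodes[] <- t(sign(lambda))
  storage.mode(truth_barcodes) <- "integer"
  class(truth_barcodes) <- c("barcode_matrix", class(truth_barcodes))

  truth <- structure(
    list(baseline = setNames(baseline, pid), steady = setNames(steady, sid),
         G = G, lambda = lambda, support = support, active = active,
         barcodes = truth_barcodes,
         params = list(n_proteins = n_proteins, n_samples = n_samples,
                       n_processes = P, sparsity = sparsity,
                       amp_scale = amp_scale, noise_sd = noise_sd,
                       max_active = max_active,
                       activity_rate = activity_rate, activity_decay = activity_decay,
                       baseline_mean = baseline_mean,
                       baseline_sd = baseline_sd, steady_jitter = steady_jitter,
                       overlap = overlap, seed = as.integer(seed))),
    class = "synthetic_truth"
  )
  list(expression = expr_matrix(exp(lnX), scale_mode = "raw"), truth = truth)
}

#' Simulate an additional cohort from an existing planted truth
#'
#' Draws new samples from the same generative model as an existing
#' simulation: identical protein baseline and planted weight columns, fresh
#' steady-state factors, activity draws, amplitudes and noise.  Used to test
#' incremental cohort addition: re-decomposing the combined matrix should
#' recover weight columns matching the original processes.
#'
#' @param truth a `synthetic_truth` from [simulate_expression()].
#' @param n_samples number of new samples.
#' @param seed integer seed for the new draws.
#' @param sample_prefix prefix for the new sample ids (default `"ext"`).
#' @return list with `expression` (an [expr_matrix]) and `truth` (a
#'   `synthetic_truth` sharing `baseline`, `G` and `support` with the
#'   original).
#' @export
simulate_cohort_extension <- function(truth, n_samples, seed = 1,
                                      sample_prefix = "ext") {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  set.seed(as.integer(seed))
  P <- p$n_processes
  n_proteins <- p$n_proteins
  pid <- names(truth$baseline)
  sid <- sprintf("%s_%03d", sample_prefix, seq_len(n_samples))
  steady <- 1 + rnorm(n_samples, 0, p$steady_jitter)

  active <- matrix(FALSE, P, n_samples)
  lambda <- matrix(0, P, n_samples)
  if (P > 0) {
    p_act <- pmin(1, p$activity_rate * p$activity_decay^(seq_len(P) - 1))
    for (a in seq_len(P)) {
      n_act <- max(1L, round(n_samples * p_act[a]))
      active[a, sample(n_samples, n_act)] <- TRUE
    }
    for (k in seq_len(n_samples)) {
      acts <- which(active[, k])
      if (length(acts) > p$max_active) {
        drop_idx <- sample(acts, length(acts) - p$max_active)
        active[drop_idx, k] <- FALSE
        acts <- setdiff(acts, drop_idx)
      }
      if (length(acts) > 0) {
        lambda[acts, k] <- abs(rnorm(length(acts), p$amp_scale, p$amp_scale / 10))
      }
    }
    base_sign <- matrix(sample(c(-1, 1), P * n_samples, replace = TRUE), P, n_samples)
    lambda <- balance_signs(lambda, base_sign)
  }
  lnX <- unname(truth$baseline) %o% steady +
    (if (P > 0) truth$G %*% lambda else 0) +
    matrix(rnorm(n_proteins * n_samples, 0, p$noise_sd), n_proteins, n_samples)
  dimnames(lnX) <- list(pid, sid)
  dimnames(lambda) <- list(if (P > 0) as.character(seq_len(P)) else NULL, sid)

  bar <- matrix(0L, n_samples, P,
                dimnames = list(sid, if (P > 0) as.character(seq_len(P)) else NULL))
  if (P > 0) bar[] <- as.integer(t(sign(lambda)))
  class(bar) <- c("barcode_matrix", class(bar))

  new_truth <- truth
  new_truth$steady <- setNames(steady, sid)
  new_truth$lambda <- lambda
  new_truth$active <- active
  new_truth$barcodes <- bar
  new_truth$params$n_samples <- n_samples
  new_truth$params$seed <- as.integer(seed)
  list(expression = expr_matrix(exp(lnX), scale_mode = "raw"), truth = new_truth)
}

# Assign signs to planted amplitude magnitudes so rows stay near-orthogonal.
# Rows are processed in order; for each active entry the sign minimizing the
# squared running inner products with earlier rows (plus a small penalty on
# the running row sum, the coupling to the steady state) is chosen; exact
# ties fall back to the pre-drawn random sign.
balance_signs <- function(mags, base_sign, sum_weight = 0.1) {
  P <- nrow(mags); m <- ncol(mags)
  lam <- matrix(0, P, m, dimnames = dimnames(mags))
  for (a in seq_len(P)) {
    dots <- if (a > 1) numeric(a - 1) else numeric(0)
    rsum <- 0
    for (k in seq_len(m)) {
      v <- mags[a, k]
      if (v == 0) next
      prev <- if (a > 1) lam[seq_len(a - 1), k] else numeric(0)
      cost <- function(s) sum((dots + s * v * prev)^2) + sum_weight * (rsum + s * v)^2
      cp <- cost(1); cm <- cost(-1)
      s <- if (cp < cm) 1 else if (cm < cp) -1 else base_sign[a, k]
      lam[a, k] <- s * v
      if (a > 1) dots <- dots + s * v * prev
      rsum <- rsum + s * v
    }
  }
  lam
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat("<synthetic_truth> ", p$n_proteins, " proteins x ", p$n_samples,
      " samples, P = ", p$n_processes, ", SNR = ",
      signif(p$amp_scale / max(p$noise_sd, 1e-12), 3), ", seed ", p$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset
#'
#' Writes the expression TSV and a JSON truth file (parameters, seed,
#' supports, active sets and planted amplitudes) so a simulation is fully
#' reproducible and auditable.
#'
#' @param sim output of [simulate_expression()].
#' @param matrix_path,truth_path output paths.
#' @return invisibly, `matrix_path`.
#' @export
write_simulation <- function(sim, matrix_path, truth_path) {
  write_expression_matrix(sim$expression, matrix_path)
  tr <- sim$truth
  jsonlite::write_json(
    list(params = tr$params, support = tr$support,
         baseline = as.list(tr$baseline), steady = as.list(tr$steady),
         lambda = apply(tr$lambda, 1, identity, simplify = FALSE)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(matrix_path)
}

#' Score recovery of planted structure
#'
#' Matches estimated processes (1..m*) to planted ones by greedy maximum
#' `|correlation|` of amplitude rows, aligns signs, and reports:
#'
#' * `process_count_error`: `min(1, |m* - P| / max(P, 1))`;
#' * `amplitude_cor`: mean matched `|r|` between estimated and planted
#'   amplitude rows;
#' * `membership_f1`: mean F1 of thresholded process membership vs the
#'   planted support;
#' * `barcode_accuracy`: mean agreement of estimated vs planted -1/0/1
#'   entries over matched processes and all samples.
#'
#' All metrics lie in `[0, 1]`; matching on the common subset is reported via
#' `n_matched` when `m*` and `P` differ.
#'
#' @param truth a `synthetic_truth`.
#' @param d the `surprisal_decomp` fitted to the simulated matrix.
#' @param model the `significance_model` (with its `m_star`).
#' @return one-row tibble of metrics plus `n_matched`, `m_star`, `p_true`;
#'   the process matching is attached as attribute `"matching"`.
#' @export
score_recovery <- function(truth, d, model) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(d, "surprisal_decomp"),
            inherits(model, "significance_model"))
  P <- truth$params$n_processes
  m_star <- model$m_star
  count_err <- min(1, abs(m_star - P) / max(P, 1))
  if (P == 0 || m_star == 0) {
    return(tibble(process_count_error = count_err, amplitude_cor = NA_real_,
                  membership_f1 = NA_real_, barcode_accuracy = NA_real_,
                  n_matched = 0L, m_star = m_star, p_true = P))
  }
  est_lam <- d$lambda[seq_len(m_star) + 1L, colnames(truth$lambda), drop = FALSE]
  C <- cor(t(truth$lambda), t(est_lam))
  mt <- greedy_match(abs(C))
  signs <- sign(C[cbind(mt$row, mt$col)])

  amp_cor <- mean(mt$value)

  f1 <- vapply(seq_along(mt$row), function(i) {
    est <- process_proteins(d, model, mt$col[i])$protein_id
    tru <- truth$support[[mt$row[i]]]
    tp <- length(intersect(est, tru))
    if (tp == 0) return(0)
    prec <- tp / length(est); rec <- tp / length(tru)
    2 * prec * rec / (prec + rec)
  }, numeric(1))

  est_bar <- make_barcodes(d, model)
  acc <- vapply(seq_along(mt$row), function(i) {
    est <- est_bar[colnames(truth$lambda), as.character(mt$col[i])] * signs[i]
    tru <- truth$barcodes[colnames(truth$lambda), as.character(mt$row[i])]
    mean(est == tru)
  }, numeric(1))

  out <- tibble(process_count_error = count_err,
                amplitude_cor = amp_cor,
                membership_f1 = mean(f1),
                barcode_accuracy = mean(acc),
                n_matched = length(mt$row),
                m_star = m_star, p_true = P)
  attr(out, "matching") <- tibble(process_true = mt$row, process_est = mt$col,
                                  abs_cor = mt$value, sign = signs)
  out
}
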