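# thresholds behave like the +-2 SD rule they encode, and all activity /
# membership / direction outputs are gauge-invariant and monotone

test_that("amplitude threshold recovers ~2 for standard-normal noise amplitudes", {
  set.seed(10)
  n_noise <- 100; m <- 100  # 10^4 pooled draws
  lambda <- rbind(matrix(5, 2, m), matrix(rnorm(n_noise * m), n_noise, m))
  G <- matrix(rnorm(60 * (n_noise + 2)), 60)
  d <- fake_decomp(G, lambda)
  model <- fit_significance(d, m_star = 1, c_amp = 2)
  expect_equal(unname(model$amp_threshold[1]), 2, tolerance = 0.05)
})

test_that("weight threshold is c_w / sqrt(n_proteins)", {
  set.seed(11)
  G <- qr.Q(qr(matrix(rnorm(181 * 5), 181)))[, 1:5]
  d <- fake_decomp(G, matrix(rnorm(5 * 10), 5, 10))
  model <- fit_significance(d, m_star = 2)
  expect_equal(unname(model$weight_threshold[1]), 2 / sqrt(181), tolerance = 1e-12)
  expect_equal(unname(model$weight_threshold[1]), 0.14866, tolerance = 1e-4)
})

test_that("fit_significance validates m_star and falls back to MAD without noise rows", {
  set.seed(12)
  G <- qr.Q(qr(matrix(rnorm(20 * 4), 20)))[, 1:4]
  d <- fake_decomp(G, matrix(rnorm(4 * 30), 4, 30))
  expect_error(fit_significance(d, 0), "m_star")
  expect_error(fit_significance(d, 4), "m_star")
  expect_warning(model <- fit_significance(d, 3), "MAD")
  expect_equal(model$amp_method, "per-process-mad")
  expect_true(all(model$amp_threshold > 0))
})

test_that("a sample with amplitude far above the noise floor is called active", {
  set.seed(13)
  m <- 40
  lam_sig <- rnorm(m, 0, 0.5); lam_sig[5] <- 10   # 10x the noise SD of 1
  lambda <- rbind(rep(50, m), lam_sig, matrix(rnorm(6 * m), 6, m))
  G <- qr.Q(qr(matrix(rnorm(30 * 8), 30)))[, 1:8]
  d <- fake_decomp(G, lambda)
  model <- fit_significance(d, 1)
  act <- active_processes(d, model, sample_ids(d)[5])
  expect_equal(act$process, 1L)
  expect_equal(act$sign, 1L)
})

test_that("samples with all sub-threshold amplitudes give the empty active set", {
  lambda <- rbind(rep(10, 5), rep(0.1, 5), matrix(0.5, 4, 5))
  G <- qr.Q(qr(matrix(rnorm(12 * 6), 12)))[, 1:6]
  d <- fake_decomp(G, lambda)
  model <- fake_model(1, amp_threshold = 1, weight_threshold = 0.2)
  expect_equal(nrow(active_processes(d, model)), 0L)
})

test_that("process membership is the thresholded weight list, sorted and tie-broken", {
  n <- 181
  g1 <- rep(0, n); g1[11:20] <- 3 / sqrt(n)          # planted members
  g1[1] <- 0.5 / sqrt(n)                             # below threshold
  G <- cbind(rep(1 / sqrt(n), n), g1)
  G[, 2] <- G[, 2] - G[, 1] * sum(G[, 1] * G[, 2]); G[, 2] <- G[, 2] / sqrt(sum(G[, 2]^2))
  rownames(G) <- sprintf("p%03d", seq_len(n))
  d <- fake_decomp(G, matrix(rnorm(2 * 10), 2, 10))
  model <- fake_model(1, amp_threshold = 1, weight_threshold = 2 / sqrt(n))
  pp <- process_proteins(d, model, 1)
  expect_setequal(pp$protein_id, sprintf("p%03d", 11:20))
  expect_true(all(diff(abs(pp$weight)) <= 1e-15))
  expect_warning(
    process_proteins(fake_decomp(G * 0.01, matrix(rnorm(20), 2, 10)), model, 1),
    "threshold")
})

test_that("membership recovery on planted data is near-exact across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_expression(n_proteins = 120, n_samples = 90, seed = s)
    d <- surprisal_decompose(sim$expression)
    model <- fit_significance(d, 3)
    sc <- score_recovery(sim$truth, d, model)
    sc$membership_f1
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.95)
})

test_that("direction of change is the sign of the weight-amplitude product", {
  G <- cbind(c(0.5, 0.5, 0.5), c(0.9, 0.2, -0.6))
  rownames(G) <- c("pos_w", "weak_w", "neg_w")
  lambda <- rbind(c(5, 5), c(2, -2))
  colnames(lambda) <- c("s_pos", "s_neg")
  d <- fake_decomp(G, lambda)
  model <- fake_model(1, amp_threshold = 1, weight_threshold = 0.3)
  expect_equal(direction_of_change(d, model, "s_pos", 1, "pos_w"), "up")
  expect_equal(direction_of_change(d, model, "s_neg", 1, "pos_w"), "down")
  expect_equal(direction_of_change(d, model, "s_pos", 1, "neg_w"), "down")
  expect_equal(direction_of_change(d, model, "s_neg", 1, "neg_w"), "up")
  expect_equal(direction_of_change(d, model, "s_pos", 1, "weak_w"), "none")
})

test_that("activity, membership and direction are invariant under a sign-gauge flip", {
  set.seed(14)
  Y <- matrix(rnorm(40 * 25, 5, 1), 40, 25,
              dimnames = list(paste0("p", 1:40), paste0("s", 1:25)))
  d <- surprisal_decompose(Y)
  model <- fit_significance(d, 3)
  flip <- d
  for (j in 2:4) { flip$G[, j] <- -flip$G[, j]; flip$lambda[j, ] <- -flip$lambda[j, ] }
  a1 <- active_processes(d, model); a2 <- active_processes(flip, model)
  expect_identical(a1[, c("sample_id", "process")], a2[, c("sample_id", "process")])
  for (a in 1:3) {
    expect_identical(process_proteins(d, model, a)$protein_id,
                     process_proteins(flip, model, a)$protein_id)
  }
  expect_identical(
    direction_of_change(d, model, "s1", 1, "p1"),
    direction_of_change(flip, model, "s1", 1, "p1"))
})

test_that("raising c_amp or c_w never adds activity or membership", {
  set.seed(15)
  sim <- simulate_expression(n_proteins = 80, n_samples = 60, seed = 15)
  d <- surprisal_decompose(sim$expression)
  m_lo <- fit_significance(d, 3, c_amp = 1.5, c_w = 1.5)
  m_hi <- fit_significance(d, 3, c_amp = 2.5, c_w = 2.5)
  act_lo <- active_processes(d, m_lo); act_hi <- active_processes(d, m_hi)
  expect_true(all(paste(act_hi$sample_id, act_hi$process) %in%
                  paste(act_lo$sample_id, act_lo$process)))
  for (a in 1:3) {
    expect_true(all(suppressWarnings(process_proteins(d, m_hi, a))$protein_id %in%
                    suppressWarnings(process_proteins(d, m_lo, a))$protein_id))
  }
})

test_that("noise-only data produces essentially no active process calls", {
  frac <- vapply(1:10, function(s) {
    sim <- simulate_expression(n_processes = 0, seed = s)
    d <- surprisal_decompose(sim$expression)
    m <- select_num_processes(r_squared_curve(d))
    if (m == 0) return(0)
    model <- fit_significance(d, m)
    nrow(active_processes(d, model)) / (m * 150)
  }, numeric(1))
  expect_lte(mean(frac), 0.07)
})

test_that("significance model survives a JSON round trip", {
  set.seed(16)
  G <- qr.Q(qr(matrix(rnorm(50 * 8), 50)))[, 1:8]
  d <- fake_decomp(G, matrix(rnorm(8 * 20), 8, 20))
  model <- fit_significance(d, 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_significance_model(model, path)
  back <- read_significance_model(path)
  expect_equal(back$m_star, model$m_star)
  expect_equal(back$amp_threshold, model$amp_threshold)
  expect_equal(back$weight_threshold, model$weight_threshold)
})
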