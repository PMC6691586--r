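star_subnet <- function(hub, leaves, process = 1, hub_weight = 0.5) {
  g <- interaction_graph(rep(hub, length(leaves)), leaves)
  prot <- tibble::tibble(protein_id = c(hub, leaves),
                         weight = c(hub_weight, rep(0.2, length(leaves))))
  build_subnetwork(prot, g, process = process)
}

test_that("drugs targeting a top hub become candidates; misses flag undruggable", {
  s <- star_subnet("EGFR", c("x1", "x2", "x3"))
  drugs <- tibble::tibble(target = c("EGFR", "nothere"),
                          drug = c("erlotinib", "phantom"))
  cand <- process_drug_candidates(s, drugs, k = 3)
  expect_equal(cand$drug, "erlotinib")
  expect_equal(cand$process, 1)
  # a drug whose target is outside the top-k hubs is not a candidate
  cand2 <- process_drug_candidates(s, tibble::tibble(target = "x1", drug = "leafdrug"),
                                   k = 1)
  expect_equal(nrow(cand2), 0L)
})

test_that("candidate sets equal the brute-force join of hubs and the drug table", {
  for (seed in 1:10) {
    set.seed(300 + seed)
    prots <- sprintf("T%02d", 1:30)
    g <- suppressWarnings(interaction_graph(sample(prots, 60, TRUE),
                                            sample(prots, 60, TRUE)))
    members <- tibble::tibble(protein_id = sample(prots, 12), weight = rnorm(12))
    s <- build_subnetwork(members, g, process = 1)
    drugs <- tibble::tibble(target = sample(prots, 15),
                            drug = paste0("d", 1:15))
    k <- sample(2:5, 1)
    cand <- process_drug_candidates(s, drugs, k = k)
    topk <- rank_hubs(s, k = min(k, nrow(s$nodes)))$protein_id
    oracle <- drugs$drug[drugs$target %in% topk]
    expect_setequal(cand$drug, oracle)
  }
})

test_that("one drug covering both active processes yields a single-drug plan", {
  active <- tibble::tibble(process = c(1L, 2L), amplitude = c(2, -2))
  cand <- tibble::tibble(process = c(1L, 2L, 2L),
                         drug = c("panacea", "panacea", "narrow"),
                         target = c("MEK1", "MEK1", "GLUT1"),
                         protein_id = c("MEK1", "MEK1", "GLUT1"),
                         hub_score = c(1, 1, 2))
  plan <- design_combination(active, cand, sample_id = "cellA")
  expect_true(plan$complete)
  expect_equal(plan$drugs$drug, "panacea")
  expect_equal(plan$drugs$processes[[1]], c(1L, 2L))
})

test_that("two disjointly druggable processes require a two-drug combination", {
  active <- tibble::tibble(process = c(1L, 2L), amplitude = c(3, 2))
  cand <- tibble::tibble(process = c(1L, 2L),
                         drug = c("trametinib", "2-DG"),
                         target = c("MAP2K1", "glycolysis"),
                         protein_id = c("MAP2K1", "glycolysis"),
                         hub_score = c(2, 1))
  plan <- design_combination(active, cand, sample_id = "MDA-MB-231-like")
  expect_true(plan$complete)
  expect_setequal(plan$drugs$drug, c("trametinib", "2-DG"))
})

test_that("processes with no candidates are reported uncovered, not hidden", {
  active <- tibble::tibble(process = 1:3, amplitude = c(2, 2, 2))
  cand <- tibble::tibble(process = 1L, drug = "only1", target = "A",
                         protein_id = "A", hub_score = 1)
  plan <- design_combination(active, cand)
  expect_false(plan$complete)
  expect_equal(plan$uncovered, c(2L, 3L))
  expect_equal(plan$drugs$drug, "only1")
})


test_that("greedy cover is complete iff a complete cover exists, near-optimal in size", {
  for (seed in 1:200) {
    inst <- rand_cover_instance(seed)
    plan <- design_combination(inst$active, inst$cand)
    covers <- if (nrow(inst$cand) == 0) list() else
      split(inst$cand$process, inst$cand$drug)
    best <- brute_min_cover(covers, inst$active$process)
    if (is.null(best)) {
      expect_false(plan$complete)
    } else {
      expect_true(plan$complete)
      m <- nrow(inst$active)
      expect_lte(nrow(plan$drugs), ceiling(length(best) * (1 + log(m))))
    }
  }
})

test_that("the exhaustive method returns a minimum-size complete cover", {
  for (seed in 201:240) {
    inst <- rand_cover_instance(seed)
    covers <- if (nrow(inst$cand) == 0) list() else
      split(inst$cand$process, inst$cand$drug)
    best <- brute_min_cover(covers, inst$active$process)
    plan <- design_combination(inst$active, inst$cand, method = "exhaustive")
    if (!is.null(best)) {
      expect_true(plan$complete)
      expect_equal(nrow(plan$drugs), length(best))
    } else {
      expect_false(plan$complete)
    }
  }
})

test_that("plans are deterministic with lexicographic tie-breaking", {
  active <- tibble::tibble(process = c(1L, 2L), amplitude = c(2, 2))
  cand <- tibble::tibble(process = c(1L, 2L, 1L, 2L),
                         drug = c("zeta", "zeta", "alpha", "alpha"),
                         target = letters[1:4], protein_id = letters[1:4],
                         hub_score = c(1, 1, 1, 1))
  p1 <- design_combination(active, cand)
  p2 <- design_combination(active, cand)
  expect_identical(tidy(p1), tidy(p2))
  expect_equal(p1$drugs$drug, "alpha")  # equal coverage and score -> name order
})

test_that("amplitude-boosted processes demand coverage by two drugs", {
  active <- tibble::tibble(process = c(1L, 2L), amplitude = c(6, 1.5))
  cand <- tibble::tibble(process = c(1L, 1L, 2L),
                         drug = c("first", "second", "other"),
                         target = c("A", "B", "C"), protein_id = c("A", "B", "C"),
                         hub_score = c(2, 1, 1))
  med <- c(`1` = 1.5, `2` = 1.5)
  plain <- design_combination(active, cand)
  expect_setequal(plain$drugs$drug, c("first", "other"))
  boosted <- design_combination(active, cand, boost_factor = 2,
                                cohort_median_amp = med)
  expect_equal(boosted$boosted, 1L)
  expect_setequal(boosted$drugs$drug, c("first", "second", "other"))
  expect_true(boosted$complete)
})

test_that("cohort-level planning covers every druggable active process", {
  sim <- simulate_expression(n_proteins = 90, n_samples = 60, seed = 30)
  d <- surprisal_decompose(sim$expression)
  model <- fit_significance(d, 3)
  set.seed(31)
  pid <- protein_ids(d)
  graph <- suppressWarnings(interaction_graph(sample(pid, 250, TRUE),
                                              sample(pid, 250, TRUE)))
  # drug for every protein => every process druggable
  drugs <- tibble::tibble(target = pid, drug = paste0("drug_", pid))
  plans <- design_cohort_combinations(d, model, graph, drugs)
  expect_length(plans, 60L)
  expect_true(all(vapply(plans, function(p) p$complete, logical(1))))
  act <- active_processes(d, model)
  for (k in names(plans)) {
    covered <- sort(as.integer(unique(unlist(plans[[k]]$drugs$processes))))
    expect_equal(covered, sort(act$process[act$sample_id == k]))
  }
})

test_that("plan export writes TSV and JSON mirrors", {
  active <- tibble::tibble(process = 1L, amplitude = 2)
  cand <- tibble::tibble(process = 1L, drug = "erlotinib", target = "EGFR",
                         protein_id = "EGFR", hub_score = 1)
  plans <- list(s1 = design_combination(active, cand, sample_id = "s1"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_plans(plans, tsv, js)
  expect_equal(readr::read_tsv(tsv, show_col_types = FALSE)$drug, "erlotinib")
  parsed <- jsonlite::read_json(js)
  expect_true(parsed$s1$complete)
  expect_equal(parsed$s1$drugs[[1]]$drug, "erlotinib")
})
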