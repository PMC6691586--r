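simple_graph <- function(...) {
  e <- list(...)
  interaction_graph(vapply(e, `[`, "", 1), vapply(e, `[`, "", 2))
}

test_that("subnetworks are induced subgraphs with isolated nodes retained", {
  g <- simple_graph(c("A", "B"), c("B", "D"))
  prot <- tibble::tibble(protein_id = c("A", "B", "C"), weight = c(0.5, -0.4, 0.3))
  s <- build_subnetwork(prot, g, process = 1)
  expect_equal(nrow(s$nodes), 3L)
  expect_equal(nrow(s$edges), 1L)
  expect_equal(s$edges$protein_a, "A")
  expect_true(s$nodes$is_isolated[s$nodes$protein_id == "C"])
  expect_equal(s$nodes$sign, c(1L, -1L, 1L))

  empty_g <- interaction_graph(character(0), character(0), numeric(0))
  s2 <- build_subnetwork(prot, empty_g)
  expect_true(all(s2$nodes$is_isolated))
  expect_equal(nrow(s2$edges), 0L)
})

test_that("induced edge sets match a brute-force filter on random graphs", {
  for (seed in 1:10) {
    set.seed(seed)
    prot_all <- sprintf("P%03d", 1:100)
    g <- suppressWarnings(interaction_graph(sample(prot_all, 300, TRUE),
                                            sample(prot_all, 300, TRUE)))
    members <- tibble::tibble(protein_id = sample(prot_all, 25),
                              weight = rnorm(25))
    s <- build_subnetwork(members, g)
    oracle <- brute_induced_edges(as.data.frame(g), members$protein_id)
    expect_setequal(paste(s$edges$protein_a, s$edges$protein_b),
                    paste(oracle$protein_a, oracle$protein_b))
  }
})

test_that("alias mapping connects antibodies through their gene symbols", {
  g <- simple_graph(c("EGFR", "MAPK1"))
  prot <- tibble::tibble(protein_id = c("pY(1068)EGFR", "pT(202)Y(204)MAPK", "pS(473)Akt"),
                         weight = c(0.6, 0.5, -0.4))
  alias <- c("pY(1068)EGFR" = "EGFR", "pT(202)Y(204)MAPK" = "MAPK1",
             "pS(473)Akt" = "AKT1")
  s <- build_subnetwork(prot, g, alias = alias)
  expect_equal(nrow(s$edges), 1L)
  expect_setequal(c(s$edges$protein_a, s$edges$protein_b),
                  c("pY(1068)EGFR", "pT(202)Y(204)MAPK"))
  expect_true(s$nodes$is_isolated[s$nodes$protein_id == "pS(473)Akt"])
})

test_that("the hub of a star subnetwork ranks first; ties break by weight then id", {
  g <- simple_graph(c("H", "a"), c("H", "b"), c("H", "c"), c("a", "b"))
  prot <- tibble::tibble(protein_id = c("H", "a", "b", "c"),
                         weight = c(0.3, 0.3, 0.3, 0.3))
  hubs <- rank_hubs(build_subnetwork(prot, g))
  expect_equal(hubs$protein_id[1], "H")
  # equal degree, larger |weight| wins
  g2 <- simple_graph(c("x", "y"))
  prot2 <- tibble::tibble(protein_id = c("x", "y"), weight = c(0.2, -0.3))
  expect_equal(rank_hubs(build_subnetwork(prot2, g2))$protein_id[1], "y")
  # k beyond the node count warns and returns everything
  expect_warning(all_h <- rank_hubs(build_subnetwork(prot2, g2), k = 10), "all")
  expect_equal(nrow(all_h), 2L)
})

test_that("hub ranking equals the brute-force score sort on random subnetworks", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    prot_all <- sprintf("Q%02d", 1:50)
    g <- suppressWarnings(interaction_graph(sample(prot_all, 120, TRUE),
                                            sample(prot_all, 120, TRUE)))
    members <- tibble::tibble(protein_id = sample(prot_all, 20), weight = rnorm(20))
    s <- build_subnetwork(members, g)
    expect_equal(rank_hubs(s)$protein_id, brute_hub_rank(s$nodes, s$edges))
  }
})

test_that("hub scores are invariant under a sign-gauge flip of the weights", {
  set.seed(24)
  g <- suppressWarnings(interaction_graph(sample(letters, 40, TRUE),
                                          sample(letters, 40, TRUE)))
  members <- tibble::tibble(protein_id = letters[1:12], weight = rnorm(12))
  h1 <- rank_hubs(build_subnetwork(members, g))
  members$weight <- -members$weight
  h2 <- rank_hubs(build_subnetwork(members, g))
  expect_equal(h1$protein_id, h2$protein_id)
  expect_equal(h1$hub_score, h2$hub_score)
})

test_that("pairwise relations are read off the weight signs per process", {
  # steady state + two processes with controlled signs
  G <- cbind(rep(0.5, 4), c(0.5, 0.5, 0.05, -0.5), c(0.5, -0.5, 0.5, 0.05))
  rownames(G) <- c("egfr", "mapk", "akt", "er")
  d <- fake_decomp(G, matrix(rnorm(3 * 8), 3, 8))
  model <- fake_model(2, amp_threshold = 1, weight_threshold = 0.3)
  rep1 <- correlation_report(d, model, "egfr", "mapk")
  expect_equal(rep1$relation, c("correlated", "anti-correlated"))
  rep2 <- correlation_report(d, model, "egfr", "akt")
  expect_equal(rep2$relation, c("non-correlated", "correlated"))
  rep3 <- correlation_report(d, model, "egfr", "er")
  expect_equal(rep3$relation[1], "anti-correlated")
  # below-threshold pair in process 2
  expect_equal(correlation_report(d, model, "akt", "er")$relation[2], "non-correlated")
})

test_that("subnetwork export formats round-trip node and edge counts", {
  g <- simple_graph(c("A", "B"), c("B", "C"))
  prot <- tibble::tibble(protein_id = c("A", "B", "C", "D"), weight = runif(4))
  s <- build_subnetwork(prot, g, process = 2)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_subnetwork_sif(s, sif)
  lines <- readLines(sif)
  expect_length(lines, 3L)  # two edges + one isolated node
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_subnetwork_graphml(s, gml)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(gg), 4)
  expect_equal(igraph::ecount(gg), 2)
})
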