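exact_profile <- function(graph, params, start) {
  P <- transition_operator(graph, params)
  ids <- rownames(P)
  e <- stats::setNames(numeric(length(ids)), ids)
  e[start] <- 1
  stats::setNames(
    as.numeric(solve(diag(length(ids)) - params$alpha * t(P),
                     (1 - params$alpha) * e)), ids)
}

test_that("transition operator biases steps by neighbour type weight", {
  g <- msi_graph(data.frame(
    source = c("p0", "p0"), source_type = "protein",
    target = c("p1", "f1"), target_type = c("protein", "biological_function"),
    stringsAsFactors = FALSE))
  P <- transition_operator(g, msi_params())
  expect_equal(unname(P["p0", "p1"]), 4.40 / (4.40 + 6.58))
  expect_equal(unname(P["p0", "f1"]), 6.58 / (4.40 + 6.58))
  # neighbours of a single type: uniform
  expect_equal(unname(P["f1", "p0"]), 1)
  # rows over non-isolated nodes are stochastic
  set.seed(12)
  g2 <- random_msi()
  P2 <- transition_operator(g2, msi_params())
  sums <- rowSums(P2)
  expect_true(all(abs(sums[sums > 0] - 1) < 1e-12))
})

test_that("alpha = 0 restarts every step: the profile is the start indicator", {
  g <- path3()
  pr <- diffusion_profile(g, msi_params(alpha = 0), "dr")
  expect_equal(unname(pr$visitation["dr"]), 1)
  expect_equal(sum(pr$visitation), 1)
})

test_that("diffusion profiles agree with the exact linear solve", {
  set.seed(20)
  for (rep in 1:12) {
    g <- random_msi(n_prot = sample(10:40, 1), n_fun = sample(4:12, 1))
    p <- msi_params()
    pr <- diffusion_profile(g, p, "dr")
    expect_lt(max(abs(pr$visitation - exact_profile(g, p, "dr"))), 1e-8)
    expect_equal(sum(pr$visitation), 1, tolerance = 1e-8)
    expect_true(all(pr$visitation >= 0))
  }
})

test_that("common rescaling of type weights leaves the profile unchanged", {
  set.seed(21)
  g <- random_msi()
  p1 <- msi_params()
  p2 <- msi_params(w_drug = 3.21 * 7, w_disease = 3.54 * 7,
                   w_protein = 4.40 * 7, w_function = 6.58 * 7)
  pr1 <- diffusion_profile(g, p1, "dr")
  pr2 <- diffusion_profile(g, p2, "dr")
  expect_equal(pr1$visitation, pr2$visitation, tolerance = 1e-10)
})

test_that("increasing alpha strictly decreases the start node's own mass", {
  set.seed(22)
  g <- random_msi()
  masses <- vapply(c(0.2, 0.5, 0.859, 0.95), function(a) {
    diffusion_profile(g, msi_params(alpha = a), "dr")$visitation[["dr"]]
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
})

test_that("walk errors are informative", {
  g <- path3()
  expect_error(diffusion_profile(g, msi_params(), "absent"), "not in graph")
  expect_error(msi_params(alpha = 1), "alpha")
  expect_error(msi_params(w_drug = -1), "positive")
  expect_error(rank_relevant_nodes(diffusion_profile(g, msi_params(), "dr"),
                                   diffusion_profile(g, msi_params(), "di"),
                                   g, k = 0), "k must be")
})

test_that("node ranking combines profiles geometrically with stable ties", {
  g <- path3()
  p <- msi_params()
  dp <- diffusion_profile(g, p, "dr")
  ip <- diffusion_profile(g, p, "di")
  top <- rank_relevant_nodes(dp, ip, g, k = 10)
  expect_equal(top$node, "p1")  # only eligible node; k > eligible returns all
  expect_equal(top$score, sqrt(dp$visitation[["p1"]] * ip$visitation[["p1"]]))
  # a node visited by only one profile scores zero under the geometric mean
  g2 <- msi_graph(data.frame(
    source = c("dr", "p1", "di"), source_type = c("drug", "protein", "disease"),
    target = c("p1", "p2", "p3"), target_type = c("protein", "protein", "protein"),
    stringsAsFactors = FALSE))
  dp2 <- diffusion_profile(g2, p, "dr")
  ip2 <- diffusion_profile(g2, p, "di")
  # p3 unreachable from the drug side: zero drug visitation
  expect_equal(dp2$visitation[["p3"]], 0)
  top2 <- rank_relevant_nodes(dp2, ip2, g2, k = 3)
  expect_equal(top2$score[top2$node == "p3"], 0)
  expect_equal(top2$node[3], "p3")
})

test_that("planted mechanism nodes are ranked into the top-k", {
  spec <- simulation_spec(seed = 7)
  m <- generate_msi_graph(spec)
  p <- msi_params()
  dp <- diffusion_profile(m$graph, p, m$drug)
  ip <- diffusion_profile(m$graph, p, m$disease)
  top <- rank_relevant_nodes(dp, ip, m$graph, k = p$k)
  interior <- m$planted_path[-c(1, length(m$planted_path))]
  expect_true(all(interior %in% top$node))
})

test_that("mechanism subgraph extraction matches exhaustive path enumeration", {
  g <- path3()
  sub <- extract_mechanism_subgraph(g, "dr", "di", allowed_nodes = "p1")
  expect_equal(sub$paths, list(c("dr", "p1", "di")))
  expect_equal(sort(sub$nodes), c("di", "dr", "p1"))
  # empty allowed set, no direct edge: empty subgraph with warning
  expect_warning(
    sub0 <- extract_mechanism_subgraph(g, "dr", "di", allowed_nodes = character()),
    "no path")
  expect_length(sub0$paths, 0)

  set.seed(30)
  for (rep in 1:5) {
    gr <- random_msi()
    pr <- msi_params()
    allowed <- rank_relevant_nodes(diffusion_profile(gr, pr, "dr"),
                                   diffusion_profile(gr, pr, "di"),
                                   gr, k = 8)$node
    got <- suppressWarnings(
      extract_mechanism_subgraph(gr, "dr", "di", allowed, max_path_length = 4))
    want <- simple_paths_oracle(gr$edges, "dr", "di", allowed, max_len = 4)
    key <- function(paths) sort(vapply(paths, paste, character(1), collapse = ">"))
    expect_equal(key(got$paths), key(want))
    # every interior node of every returned path is allowed
    for (pp in got$paths) {
      expect_true(all(pp[-c(1, length(pp))] %in% allowed))
    }
  }
})

test_that("extraction is invariant to allowed-node order and includes the planted path", {
  spec <- simulation_spec(seed = 7)
  m <- generate_msi_graph(spec)
  p <- msi_params()
  top <- rank_relevant_nodes(diffusion_profile(m$graph, p, m$drug),
                             diffusion_profile(m$graph, p, m$disease),
                             m$graph, k = p$k)
  s1 <- extract_mechanism_subgraph(m$graph, m$drug, m$disease, top$node)
  s2 <- extract_mechanism_subgraph(m$graph, m$drug, m$disease, rev(top$node))
  expect_equal(s1$paths, s2$paths)
  expect_true(any(vapply(s1$paths, identical, logical(1), m$planted_path)))
  expect_true(all(m$planted_path %in% s1$nodes))
})

test_that("MSI IO: typed TSV and per-class two-column files load identically", {
  dir <- withr::local_tempdir()
  g <- path3()
  typed <- file.path(dir, "msi.tsv")
  write.table(g$edges, typed, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_msi(typed)
  expect_equal(sort(names(back$nodes)), sort(names(g$nodes)))
  dp <- file.path(dir, "drug_protein.tsv")
  dip <- file.path(dir, "disease_protein.tsv")
  writeLines("dr\tp1", dp)
  writeLines("di\tp1", dip)
  back2 <- read_msi(class_files = list("drug-protein" = dp,
                                       "disease-protein" = dip))
  expect_equal(back2$nodes[order(names(back2$nodes))],
               g$nodes[order(names(g$nodes))])
})
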