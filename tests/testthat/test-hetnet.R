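two_step_schema <- data.frame(
  source_type = c("DRUG", "GENE"),
  relation = c("targets", "associates"),
  target_type = c("GENE", "DISEASE"),
  stringsAsFactors = FALSE)

test_that("metapath enumeration is forced by simple schemas", {
  mp <- enumerate_metapaths(two_step_schema, 2)
  expect_length(mp, 1)
  expect_equal(mp[[1]]$id, "DRUG-targets-GENE-associates-DISEASE")
  # no direct DRUG-DISEASE relation at length 1
  expect_length(enumerate_metapaths(two_step_schema, 1), 0)
  expect_error(enumerate_metapaths(two_step_schema, 0), "max_length")
})

test_that("metapath enumeration matches brute force on a 4-type schema", {
  schema <- data.frame(
    source_type = c("DRUG", "DRUG", "GENE", "GENE"),
    relation = c("targets", "treats", "associates", "participates"),
    target_type = c("GENE", "DISEASE", "DISEASE", "PATHWAY"),
    stringsAsFactors = FALSE)
  mp <- enumerate_metapaths(schema, 3)
  # brute force over the undirected type digraph
  steps <- rbind(schema, setNames(schema[, c(3, 2, 1)], names(schema)))
  brute <- character()
  for (i in seq_len(nrow(steps))) {
    if (steps$source_type[i] != "DRUG") next
    if (steps$target_type[i] == "DISEASE") {
      brute <- c(brute, paste("DRUG", steps$relation[i], "DISEASE", sep = "-"))
    }
    for (j in seq_len(nrow(steps))) {
      if (steps$source_type[j] != steps$target_type[i]) next
      if (steps$target_type[j] == "DISEASE") {
        brute <- c(brute, paste("DRUG", steps$relation[i], steps$target_type[i],
                                steps$relation[j], "DISEASE", sep = "-"))
      }
      for (k in seq_len(nrow(steps))) {
        if (steps$source_type[k] != steps$target_type[j]) next
        if (steps$target_type[k] == "DISEASE") {
          brute <- c(brute, paste("DRUG", steps$relation[i], steps$target_type[i],
                                  steps$relation[j], steps$target_type[j],
                                  steps$relation[k], "DISEASE", sep = "-"))
        }
      }
    }
  }
  expect_setequal(vapply(mp, `[[`, character(1), "id"), unique(brute))
})

test_that("DWPC closed cases: unit degrees give 1, no path gives 0", {
  edges <- data.frame(
    source = c("d1", "g1"), source_type = c("DRUG", "GENE"),
    relation = c("targets", "associates"),
    target = c("g1", "z1"), target_type = c("GENE", "DISEASE"),
    stringsAsFactors = FALSE)
  g <- het_graph(edges)
  mp <- enumerate_metapaths(g, 2)[[1]]
  for (w in c(0, 0.4, 1)) {
    expect_equal(dwpc(g, mp, "d1", "z1", dwpc_params(w = w)), 1)
  }
  # no conforming path: disconnect the gene
  g2 <- het_graph(rbind(edges, data.frame(
    source = "d2", source_type = "DRUG", relation = "targets",
    target = "g2", target_type = "GENE", stringsAsFactors = FALSE)))
  expect_equal(dwpc(g2, mp, "d2", "z1", dwpc_params()), 0)
  expect_error(dwpc(g, mp, "g1", "z1"), "source type")
})

test_that("DWPC with a degree-2 intermediate matches explicit degree products", {
  # d1 targets g1,g2; both associate z1: two paths, deg(d1)=2 per metaedge
  edges <- data.frame(
    source = c("d1", "d1", "g1", "g2"),
    source_type = c("DRUG", "DRUG", "GENE", "GENE"),
    relation = c("targets", "targets", "associates", "associates"),
    target = c("g1", "g2", "z1", "z1"),
    target_type = c("GENE", "GENE", "DISEASE", "DISEASE"),
    stringsAsFactors = FALSE)
  g <- het_graph(edges)
  mp <- enumerate_metapaths(g, 2)[[1]]
  w <- 0.4
  # each path: (deg_d1 * deg_gi)^-w * (deg_gi * deg_z1)^-w = (2*1)^-w * (1*2)^-w
  expect_equal(dwpc(g, mp, "d1", "z1", dwpc_params(w = w)),
               2 * (2 * 1)^(-w) * (1 * 2)^(-w), tolerance = 1e-12)
  expect_equal(dwpc(g, mp, "d1", "z1", dwpc_params(w = 0)), 2)
})

test_that("DWPC equals exhaustive enumeration on random small graphs", {
  set.seed(55)
  checked <- 0
  for (rep in 1:100) {
    gdef <- random_small_hetnet(8L)
    g <- het_graph(gdef$edges)
    mps <- enumerate_metapaths(g, 3)
    if (length(mps) == 0L) next
    w <- runif(1, 0, 1)
    for (mp in mps[seq_len(min(3, length(mps)))]) {
      got <- dwpc(g, mp, gdef$drug, gdef$disease, dwpc_params(w = w))
      want <- dwpc_oracle(gdef$edges, mp, gdef$drug, gdef$disease, w)
      expect_equal(got, want, tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 50)
})

test_that("DWPC is monotone non-increasing in w and integer at w = 0", {
  set.seed(66)
  for (rep in 1:10) {
    gdef <- random_small_hetnet(8L)
    g <- het_graph(gdef$edges)
    mps <- enumerate_metapaths(g, 3)
    if (length(mps) == 0L) next
    for (mp in mps[seq_len(min(2, length(mps)))]) {
      vals <- vapply(c(0, 0.2, 0.4, 0.8, 1.5),
                     function(w) dwpc(g, mp, gdef$drug, gdef$disease,
                                      dwpc_params(w = w)), numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
      expect_equal(vals[1], round(vals[1]))
    }
  }
})

test_that("leakage masking removes the pair's own treat edge from its features", {
  spec <- simulation_spec(seed = 17)
  het <- generate_hetnet(spec)
  mp <- enumerate_metapaths(het$graph, 3)
  treat_mp <- mp[[which(vapply(mp, `[[`, character(1), "id") ==
                          "DRUG-treats-DISEASE")]]
  pos <- het$labels[het$labels$label == "positive", ][1:3, ]
  feats <- build_features(het$graph, pos, mp)
  # the direct treats metapath must be zero for the pair's own edge
  expect_true(all(feats[["DRUG-treats-DISEASE"]] == 0))
  # and unmasked computation differs whenever the edge exists
  for (i in 1:3) {
    expect_gt(dwpc(het$graph, treat_mp, pos$drug[i], pos$disease[i],
                   dwpc_params()), 0)
  }
})

test_that("positive pairs dominate negatives on the shared-gene metapath", {
  spec <- simulation_spec(seed = 17)
  het <- generate_hetnet(spec)
  mp <- enumerate_metapaths(het$graph, 2)
  feats <- build_features(het$graph, het$labels, mp)
  f <- feats[["DRUG-targets-GENE-associates-DISEASE"]]
  wt <- wilcox.test(f[feats$label == "positive"], f[feats$label == "negative"],
                    alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 1e-6)
})

test_that("training is reproducible, separable features reach accuracy 1", {
  set.seed(2)
  n <- 60
  feats <- data.frame(drug = sprintf("d%02d", 1:n), disease = "z",
                      label = rep(c("positive", "negative"), each = n / 2),
                      sep = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
                      noise = rnorm(n), check.names = FALSE)
  m1 <- train_model(feats, seed = 42)
  m2 <- train_model(feats, seed = 42)
  expect_identical(m1$fit$wts, m2$fit$wts)
  p <- predict(m1, feats)
  expect_equal(mean((p >= 0.5) == (feats$label == "positive")), 1)
  # single-class input errors
  feats$label <- "positive"
  expect_error(train_model(feats), "both positive and negative")
})

test_that("AUC matches the pairwise counting oracle and handles ties", {
  expect_equal(auc_score(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_equal(auc_score(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  set.seed(88)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    s <- sample(round(rnorm(n), 1))  # rounding creates ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(y) || all(y)) next
    expect_equal(auc_score(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("label-shuffled features evaluate near chance", {
  spec <- simulation_spec(seed = 17)
  het <- generate_hetnet(spec)
  mp <- enumerate_metapaths(het$graph, 3)
  feats <- build_features(het$graph, het$labels, mp)
  set.seed(99)
  feats$label <- sample(feats$label)
  ev <- evaluate_holdout(feats, k_folds = 5, seed = 99)
  expect_gt(ev$auc, 0.3)
  expect_lt(ev$auc, 0.7)
})

test_that("prediction ranks candidates deterministically and flags zero rows", {
  spec <- simulation_spec(seed = 17)
  het <- generate_hetnet(spec)
  mp <- enumerate_metapaths(het$graph, 3)
  feats <- build_features(het$graph, het$labels, mp)
  model <- train_model(feats, seed = 17)
  disease <- het$labels$disease[het$labels$label == "positive"][1]
  drugs <- names(het$graph$nodes)[het$graph$nodes == "DRUG"]
  preds <- predict_treatments(model, het$graph, disease, drugs, mp)
  expect_equal(preds$rank, seq_len(nrow(preds)))
  expect_true(all(diff(preds$score) <= 0))
  expect_error(predict_treatments(model, het$graph, "no_such_disease",
                                  drugs, mp), "disease")
  # single candidate is rank 1 regardless of score
  one <- predict_treatments(model, het$graph, disease, drugs[1], mp)
  expect_equal(one$rank, 1)
})
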