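test_that("KS enrichment reproduces the closed-form end-block values", {
  ranking <- sprintf("g%02d", 1:10)
  expect_identical(ks_enrichment(c("g01", "g02"), ranking), 1 - 2 / 10)
  expect_identical(ks_enrichment(c("g09", "g10"), ranking), -(10 - 2 + 1) / 10)
  # sign flips between the two closed-form placements
  expect_gt(ks_enrichment(c("g01", "g02"), ranking), 0)
  expect_lt(ks_enrichment(c("g09", "g10"), ranking), 0)
  expect_error(ks_enrichment(character(), ranking), "non-empty")
  expect_error(ks_enrichment(c("zz"), ranking), "appear in the ranking")
  expect_error(ks_enrichment(ranking, ranking), "strict subset")
})

test_that("KS enrichment equals the brute-force double-loop oracle", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(5:50, 1)
    t <- sample(seq_len(n - 1), 1)
    ranking <- sample(sprintf("x%03d", 1:n))
    tags <- sample(ranking, t)
    expect_equal(ks_enrichment(tags, ranking), ks_oracle(tags, ranking),
                 tolerance = 1e-12)
  }
})

test_that("connectivity score composes the two closed forms and zeroes same-sign pairs", {
  n <- 20
  ranking <- sprintf("g%02d", 1:n)
  t <- 3
  sig <- tiny_signature(up = ranking[1:t], down = ranking[(n - t + 1):n])
  res <- connectivity_score(sig, ranking)
  expect_equal(res$raw_score, (1 - t / n) + (n - t + 1) / n)
  # both tag lists at the top: same sign, raw zero
  sig2 <- tiny_signature(up = ranking[1:3], down = ranking[4:6])
  res2 <- connectivity_score(sig2, ranking)
  expect_identical(res2$raw_score, 0)
  # all signature genes outside the universe
  sig3 <- tiny_signature(up = c("zz1"), down = c("zz2"))
  expect_error(connectivity_score(sig3, ranking), "universe")
})

test_that("connectivity scores on the packaged fixture equal the oracle", {
  lib <- tiny_library()
  sig <- tiny_signature()
  scored <- score_library(sig, lib)
  for (i in seq_len(nrow(scored))) {
    ranking <- instance_ranking(lib, scored$condition[i])
    ku <- ks_oracle(sig$up_genes, ranking)
    kd <- ks_oracle(sig$down_genes, ranking)
    expect_equal(scored$ks_up[i], ku, tolerance = 1e-12)
    expect_equal(scored$ks_down[i], kd, tolerance = 1e-12)
    expect_equal(scored$raw_score[i],
                 if (ku * kd > 0) 0 else ku - kd, tolerance = 1e-12)
  }
  # processing order of instances does not change per-instance scores
  rev_lib <- lib
  rev_lib$meta <- lib$meta[rev(seq_len(nrow(lib$meta))), , drop = FALSE]
  rev_lib$rankings <- lib$rankings[, rev(seq_len(ncol(lib$rankings))), drop = FALSE]
  scored_rev <- score_library(sig, rev_lib)
  m <- match(scored$condition, scored_rev$condition)
  expect_equal(scored$raw_score, scored_rev$raw_score[m])
})

test_that("score scaling maps extremes to +/-1, keeps zeros, and is idempotent", {
  res <- data.frame(drug_id = letters[1:3], condition = letters[1:3],
                    ks_up = 0, ks_down = 0,
                    raw_score = c(2, 1, -0.5), scaled_score = NA_real_)
  out <- scale_scores(res)
  expect_equal(out$scaled_score, c(1, 0.5, -1))
  # idempotence: feeding scaled scores back as raw reproduces them
  res2 <- out
  res2$raw_score <- out$scaled_score
  expect_equal(scale_scores(res2)$scaled_score, out$scaled_score)
  # all-zero input stays zero
  res$raw_score <- 0
  expect_equal(scale_scores(res)$scaled_score, rep(0, 3))
  # spans [-1, 1] when both signs present
  set.seed(9)
  res3 <- data.frame(drug_id = as.character(1:30), condition = as.character(1:30),
                     ks_up = 0, ks_down = 0, raw_score = rnorm(30),
                     scaled_score = NA_real_)
  sc <- scale_scores(res3)$scaled_score
  expect_equal(max(sc), 1)
  expect_equal(min(sc), -1)
})

test_that("per-drug condensation keeps the score of maximum magnitude with sign", {
  scored <- data.frame(
    drug_id = c("d1", "d1"), condition = c("c1", "c2"),
    ks_up = 0, ks_down = 0, raw_score = c(0.9, -0.95),
    scaled_score = c(0.9, -0.95))
  cond <- repurposeR:::condense_by_drug(scored)
  expect_equal(cond$condensed_score, -0.95)
  expect_equal(cond$best_condition, "c2")
})

test_that("configuration selection ties to split, validates inputs", {
  lib <- tiny_library()
  tab <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    log_fc = c(seq(3, 0.5, length.out = 10),
                               seq(-0.5, -3, length.out = 10)),
                    p_value = rep(1e-6, 20), adj_p = rep(1e-6, 20))
  cfgs <- list(signature_config("split", 3, 3),
               signature_config("split", 3, 3))
  # identical configs give identical scores; the split tie-break picks one
  ch <- select_configuration(tab, cfgs, "top_up", lib)
  expect_s3_class(ch, "dgem_config_choice")
  expect_equal(ch$chosen_config$mode, "split")
  expect_equal(unname(diff(ch$control_score_per_config)), 0)
  expect_error(select_configuration(tab, list(), "top_up", lib), "non-empty")
  expect_error(select_configuration(tab, cfgs, "absent_drug", lib),
               "absent_drug")
})

test_that("down-only planted reversal favours the direction-free configuration", {
  spec <- simulation_spec(seed = 11)
  tab <- generate_disease_table(spec)
  sig <- build_disease_signature(tab, signature_config("split"))
  lib <- generate_signature_library(spec, sig, reversal_directions = "down")
  cfgs <- list(signature_config("split"), signature_config("combined"))
  ch <- select_configuration(tab, cfgs, "metformin", lib)
  scores <- ch$control_score_per_config
  expect_gte(scores[["combined:500"]], scores[["split:250,250"]])
  expect_equal(ch$chosen_config$mode, "combined")
  # oracle: exhaustive evaluation of both configurations
  for (cfg in cfgs) {
    s <- build_disease_signature(tab, cfg)
    raw <- vapply(lib$meta$instance[lib$meta$drug_id == "metformin"],
                  function(inst) {
                    r <- instance_ranking(lib, inst)
                    if (cfg$mode == "split") {
                      ku <- ks_oracle(s$up_genes, r)
                      kd <- ks_oracle(s$down_genes, r)
                      if (ku * kd > 0) 0 else ku - kd
                    } else ks_oracle(s$up_genes, r)
                  }, numeric(1))
    expect_equal(unname(scores[[format(cfg)]]), max(raw), tolerance = 1e-12)
  }
})

test_that("drug ranking condenses per drug and recovers planted reversers", {
  lib <- tiny_library()
  one <- lib
  keep <- one$meta$drug_id == "reversed"
  one$meta <- one$meta[keep, , drop = FALSE]
  one$rankings <- one$rankings[, keep, drop = FALSE]
  rk1 <- rank_drugs(tiny_signature(), one)
  expect_equal(nrow(rk1), 1)
  expect_equal(rk1$rank, 1)

  spec <- simulation_spec(seed = 11)
  tab <- generate_disease_table(spec)
  sig <- build_disease_signature(tab, signature_config("split"))
  biglib <- generate_signature_library(spec, sig)
  rk <- rank_drugs(sig, biglib)
  expect_setequal(head(rk$drug_id, 5), spec$planted_therapeutic_ids)
  # planted reversal is negative under the CMap sign convention
  expect_true(all(head(rk$condensed_score, 5) < 0))
})

test_that("planted drugs rank better than background across seeds", {
  for (seed in c(1, 23, 99)) {
    spec <- simulation_spec(seed = seed)
    tab <- generate_disease_table(spec)
    sig <- build_disease_signature(tab, signature_config("split"))
    lib <- generate_signature_library(spec, sig)
    rk <- rank_drugs(sig, lib)
    planted <- rk$rank[rk$drug_id %in% spec$planted_therapeutic_ids]
    background <- rk$rank[!rk$drug_id %in% spec$planted_therapeutic_ids]
    expect_lt(mean(planted), mean(background))
  }
})
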