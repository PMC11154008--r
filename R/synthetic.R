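#' Simulation specification with planted ground truth
#'
#' One object drives every generator, so a full synthetic study - DE tables,
#' drug-signature library, knowledge graph and interactome - is a pure
#' function of this spec. Defaults define the benchmark conditions used
#' throughout the package: 2,000 genes with 40 planted effects per
#' direction, 50 drugs x 3 concentrations with 5 planted therapeutics at
#' reversal strength 0.8, a 500-node 8-type hetnet with 5% treat edges, and
#' an interactome with one planted 4-edge mechanism path.
#'
#' @param seed base RNG seed; every generator derives its stream from it.
#' @param n_genes gene-universe size.
#' @param n_planted_up,n_planted_down planted differential effects per
#'   direction.
#' @param effect_min,effect_max planted |log2 fold change| range (uniform).
#' @param noise per-observation expression noise SD; 0 gives a noiseless
#'   table.
#' @param n_per_group samples per group in the two-group model generating
#'   p-values.
#' @param n_drugs,conditions_per_drug library size.
#' @param planted_therapeutic_ids drugs given signature-reversing rankings.
#' @param reversal_strength per-gene probability rho that a planted drug
#'   reverses a disease signature gene.
#' @param library_noise SD of the jitter on ranking scores across conditions.
#' @param hetnet_sizes named integer vector of node counts per type (8
#'   types, DRUG / DISEASE / GENE among them).
#' @param treat_edge_rate fraction of drug x disease pairs planted as true
#'   treatments.
#' @param negative_ratio sampled negatives per positive.
#' @param msi_sizes named integer vector: background `drugs`, `diseases`,
#'   `proteins`, `functions`.
#' @param planted_path_length edge count of the planted drug-to-disease
#'   mechanism path (>= 2).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 2000L,
                            n_planted_up = 40L, n_planted_down = 40L,
                            effect_min = 1.5, effect_max = 3,
                            noise = 0.5, n_per_group = 10L,
                            n_drugs = 50L, conditions_per_drug = 3L,
                            planted_therapeutic_ids = c(
                              "metformin", "mebendazole", "cloperastine",
                              "demeclocycline", "tolvaptan"),
                            reversal_strength = 0.8,
                            library_noise = 0.1,
                            hetnet_sizes = c(DRUG = 60L, DISEASE = 12L,
                                             GENE = 200L, PATHWAY = 60L,
                                             PHENOTYPE = 50L, ANATOMY = 18L,
                                             SIDE_EFFECT = 50L, SYMPTOM = 50L),
                            treat_edge_rate = 0.05,
                            negative_ratio = 4L,
                            msi_sizes = c(drugs = 5L, diseases = 3L,
                                          proteins = 60L, functions = 30L),
                            planted_path_length = 4L) {
  stopifnot(n_genes > 0, n_planted_up > 0, n_planted_down > 0,
            n_drugs >= length(planted_therapeutic_ids),
            conditions_per_drug > 0,
            reversal_strength >= 0, reversal_strength <= 1,
            treat_edge_rate >= 0, planted_path_length >= 2,
            all(hetnet_sizes > 0), length(hetnet_sizes) >= 4,
            all(c("DRUG", "DISEASE", "GENE") %in% names(hetnet_sizes)))
  structure(as.list(environment()), class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<simulation_spec> seed %d: %d genes (%d up / %d down planted), ",
    "%d drugs x %d conditions (%d planted, rho = %.2f)\n"),
    x$seed, x$n_genes, x$n_planted_up, x$n_planted_down, x$n_drugs,
    x$conditions_per_drug, length(x$planted_therapeutic_ids),
    x$reversal_strength))
  invisible(x)
}

gene_ids <- function(spec) sprintf("g%04d", seq_len(spec$n_genes))

drug_ids <- function(spec) {
  planted <- spec$planted_therapeutic_ids
  extra <- spec$n_drugs - length(planted)
  c(planted, sprintf("cmpd_%03d", seq_len(extra)))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate a differential-expression table with planted effects
#'
#' Expression for each gene is drawn from a two-group Gaussian model
#' (`n_per_group` samples per group, SD `noise`); planted genes receive a
#' group-mean shift of uniform magnitude in `[effect_min, effect_max]` with
#' the planted sign. The table's `log_fc` is the observed group-mean
#' difference and `p_value` the pooled two-sample t-test, so BH behaviour
#' downstream is realistic. At `noise = 0` the observed fold changes equal
#' the planted effects and planted genes get p = 0.
#'
#' @param spec a [simulation_spec()].
#' @param contrast_id contrast label.
#' @param seed_offset integer added to the spec seed so several contrasts
#'   can be drawn from one spec.
#' @return gene table (data.frame) with attributes `planted_up`,
#'   `planted_down` and `contrast_id`.
#' @export
generate_disease_table <- function(spec, contrast_id = "disease_vs_normal",
                                   seed_offset = 0L) {
  genes <- gene_ids(spec)
  with_seed(spec$seed + seed_offset, {
    planted <- sample(genes, spec$n_planted_up + spec$n_planted_down)
    up <- planted[seq_len(spec$n_planted_up)]
    down <- setdiff(planted, up)
    effect <- stats::setNames(numeric(spec$n_genes), genes)
    effect[up] <- stats::runif(spec$n_planted_up, spec$effect_min, spec$effect_max)
    effect[down] <- -stats::runif(spec$n_planted_down, spec$effect_min, spec$effect_max)
    n <- spec$n_per_group
    if (spec$noise == 0) {
      log_fc <- unname(effect)
      p <- ifelse(effect == 0, 1, 0)
    } else {
      a <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise), ncol = n)
      b <- matrix(stats::rnorm(spec$n_genes * n, 0, spec$noise), ncol = n) + effect
      log_fc <- rowMeans(b) - rowMeans(a)
      va <- apply(a, 1L, stats::var)
      vb <- apply(b, 1L, stats::var)
      sp <- sqrt(((n - 1) * va + (n - 1) * vb) / (2 * n - 2))
      tstat <- log_fc / (sp * sqrt(2 / n))
      p <- 2 * stats::pt(-abs(tstat), df = 2 * n - 2)
    }
    tab <- data.frame(gene_id = genes, log_fc = log_fc, p_value = p,
                      stringsAsFactors = FALSE)
    attr(tab, "contrast_id") <- contrast_id
    attr(tab, "planted_up") <- up
    attr(tab, "planted_down") <- down
    tab
  })
}

#' Generate a drug-signature library with planted reversal drugs
#'
#' Every instance ranks the full gene universe by a latent score (low score
#' = top of the ranking = most up-regulated by treatment). Background drugs
#' get independent uniform scores, i.e. random permutations. For planted
#' therapeutic drugs each disease signature gene is, independently with
#' probability `reversal_strength`, pushed to the reversing end: disease
#' down-genes toward the top, disease up-genes toward the bottom. With
#' `reversal_strength = 1` and `library_noise = 0` the reversed tags occupy
#' exact end blocks, so the raw connectivity score attains its closed-form
#' maximum magnitude.
#'
#' @param spec a [simulation_spec()].
#' @param disease_signature the `disease_signature` the planted drugs
#'   reverse.
#' @param reversal_directions which tag lists are reversed; default both,
#'   `"down"` alone creates the asymmetric fixture used to exercise
#'   configuration selection.
#' @param seed_offset stream offset, as in [generate_disease_table()].
#' @return a `signature_library`.
#' @export
generate_signature_library <- function(spec, disease_signature,
                                       reversal_directions = c("up", "down"),
                                       seed_offset = 100L) {
  genes <- gene_ids(spec)
  drugs <- drug_ids(spec)
  up <- if ("up" %in% reversal_directions) {
    if (disease_signature$config$mode == "split") disease_signature$up_genes
    else names(disease_signature$direction)[disease_signature$direction == "up"]
  } else character()
  down <- if ("down" %in% reversal_directions) {
    if (disease_signature$config$mode == "split") disease_signature$down_genes
    else names(disease_signature$direction)[disease_signature$direction == "down"]
  } else character()
  with_seed(spec$seed + seed_offset, {
    cols <- list()
    meta <- list()
    for (d in drugs) {
      planted <- d %in% spec$planted_therapeutic_ids
      for (cidx in seq_len(spec$conditions_per_drug)) {
        s <- stats::runif(spec$n_genes)
        names(s) <- genes
        if (planted) {
          rev_up <- up[stats::runif(length(up)) < spec$reversal_strength]
          rev_down <- down[stats::runif(length(down)) < spec$reversal_strength]
          # up-genes to the bottom (high score), down-genes to the top (low)
          s[rev_up] <- 1 + stats::runif(length(rev_up))
          s[rev_down] <- -stats::runif(length(rev_down))
        }
        if (spec$library_noise > 0) {
          s <- s + stats::rnorm(spec$n_genes, 0, spec$library_noise)
        }
        inst <- sprintf("%s_c%d", d, cidx)
        cols[[inst]] <- rank(s, ties.method = "first")
        meta[[inst]] <- data.frame(
          instance = inst, drug_id = d, cell_context = "cellA",
          concentration = 10^(cidx - 2), stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    storage.mode(m) <- "integer"
    signature_library(m, do.call(rbind, meta))
  })
}

sample_pairs <- function(n, a, b) {
  # n distinct (a, b) index pairs, uniform without replacement
  idx <- sample(a * b, n) - 1L
  data.frame(i = idx %% a + 1L, j = idx %/% a + 1L)
}

#' Generate a typed knowledge graph with planted treatments
#'
#' Builds a random 8-type hetnet in which planted DRUG-treats-DISEASE pairs
#' are explained by shared GENE neighbours: each true pair's drug targets
#' several genes associated with its disease, so DRUG-GENE-DISEASE path
#' features carry the signal and a classifier must learn it from paths, not
#' from the treat edges themselves (which are masked during featurisation).
#'
#' @param spec a [simulation_spec()].
#' @param seed_offset stream offset.
#' @return list with `graph` (a `het_graph`), `labels` (data.frame `drug`,
#'   `disease`, `label`, `split` with an 80/20 train/holdout split of the
#'   positives and sampled negatives at `negative_ratio`:1).
#' @export
generate_hetnet <- function(spec, seed_offset = 200L) {
  sz <- spec$hetnet_sizes
  ids <- lapply(names(sz), function(ty) sprintf("%s_%03d", tolower(ty),
                                                seq_len(sz[[ty]])))
  names(ids) <- names(sz)
  # drug ids shared with the signature library so pipeline ranks join;
  # extra graph-only drugs keep generic ids
  lib_drugs <- drug_ids(spec)
  n_shared <- min(length(lib_drugs), sz[["DRUG"]])
  ids$DRUG[seq_len(n_shared)] <- lib_drugs[seq_len(n_shared)]
  with_seed(spec$seed + seed_offset, {
    edge <- function(s, st, rel, t, tt) {
      data.frame(source = s, source_type = st, relation = rel, target = t,
                 target_type = tt, stringsAsFactors = FALSE)
    }
    parts <- list()
    # background biology
    parts$targets <- do.call(rbind, lapply(ids$DRUG, function(d) {
      edge(d, "DRUG", "targets", sample(ids$GENE, sample(3:6, 1)), "GENE")
    }))
    parts$assoc <- do.call(rbind, lapply(ids$DISEASE, function(di) {
      edge(di, "DISEASE", "associates", sample(ids$GENE, 15), "GENE")
    }))
    ppi <- sample_pairs(300L, sz[["GENE"]], sz[["GENE"]])
    ppi <- ppi[ppi$i != ppi$j, , drop = FALSE]
    parts$ppi <- edge(ids$GENE[ppi$i], "GENE", "interacts", ids$GENE[ppi$j], "GENE")
    if (!is.null(ids$PATHWAY)) {
      pw <- sample_pairs(250L, sz[["GENE"]], sz[["PATHWAY"]])
      parts$pw <- edge(ids$GENE[pw$i], "GENE", "participates",
                       ids$PATHWAY[pw$j], "PATHWAY")
    }
    if (!is.null(ids$PHENOTYPE)) {
      parts$ph <- do.call(rbind, lapply(ids$DISEASE, function(di) {
        edge(di, "DISEASE", "presents", sample(ids$PHENOTYPE, 5), "PHENOTYPE")
      }))
    }
    if (!is.null(ids$SIDE_EFFECT)) {
      parts$se <- do.call(rbind, lapply(ids$DRUG, function(d) {
        edge(d, "DRUG", "causes", sample(ids$SIDE_EFFECT, 3), "SIDE_EFFECT")
      }))
    }
    if (!is.null(ids$ANATOMY)) {
      parts$an <- do.call(rbind, lapply(ids$DISEASE, function(di) {
        edge(di, "DISEASE", "localizes", sample(ids$ANATOMY, 2), "ANATOMY")
      }))
    }
    if (!is.null(ids$SYMPTOM)) {
      parts$sy <- do.call(rbind, lapply(ids$DISEASE, function(di) {
        edge(di, "DISEASE", "manifests", sample(ids$SYMPTOM, 4), "SYMPTOM")
      }))
    }
    # planted treatments explained by shared genes; the library's planted
    # therapeutics always treat the first (modelled) disease
    n_pos <- round(spec$treat_edge_rate * sz[["DRUG"]] * sz[["DISEASE"]])
    fi <- match(spec$planted_therapeutic_ids, ids$DRUG)
    forced <- data.frame(i = fi, j = rep(1L, length(fi)))
    forced <- forced[!is.na(forced$i), , drop = FALSE]
    if (n_pos + nrow(forced) > 0L) {
      pos <- sample_pairs(max(n_pos, 1L) * 2L, sz[["DRUG"]], sz[["DISEASE"]])
      pos <- rbind(forced, pos)
      pos <- pos[!duplicated(pos), , drop = FALSE]
      pos <- utils::head(pos, max(n_pos, nrow(forced)))
    } else {
      pos <- forced
    }
    n_pos <- nrow(pos)
    assoc_of <- split(parts$assoc$target, parts$assoc$source)
    if (n_pos > 0L) {
      parts$planted <- do.call(rbind, lapply(seq_len(n_pos), function(r) {
        d <- ids$DRUG[pos$i[r]]
        di <- ids$DISEASE[pos$j[r]]
        g <- sample(assoc_of[[di]], sample(3:5, 1))
        rbind(edge(d, "DRUG", "targets", g, "GENE"),
              edge(d, "DRUG", "treats", di, "DISEASE"))
      }))
    }
    edges <- do.call(rbind, parts)
    ukey <- paste(edges$relation, pmin(edges$source, edges$target),
                  pmax(edges$source, edges$target))
    edges <- edges[!duplicated(ukey), , drop = FALSE]
    rownames(edges) <- NULL
    graph <- het_graph(edges)

    pos_pairs <- data.frame(drug = ids$DRUG[pos$i], disease = ids$DISEASE[pos$j],
                            label = rep("positive", n_pos),
                            stringsAsFactors = FALSE)
    pair_key <- paste(pos_pairs$drug, pos_pairs$disease)
    n_neg <- spec$negative_ratio * max(n_pos, 1L)
    neg <- sample_pairs(min(n_neg * 3L, sz[["DRUG"]] * sz[["DISEASE"]]),
                        sz[["DRUG"]], sz[["DISEASE"]])
    neg_pairs <- data.frame(drug = ids$DRUG[neg$i], disease = ids$DISEASE[neg$j],
                            label = "negative", stringsAsFactors = FALSE)
    neg_pairs <- neg_pairs[!paste(neg_pairs$drug, neg_pairs$disease) %in% pair_key, ]
    neg_pairs <- utils::head(neg_pairs, n_neg)
    labels <- rbind(pos_pairs, neg_pairs)
    labels$split <- "train"
    hold <- unlist(lapply(c("positive", "negative"), function(cl) {
      idx <- which(labels$label == cl)
      if (length(idx) < 2L) return(integer())
      sample(idx, max(1L, round(0.2 * length(idx))))
    }))
    labels$split[hold] <- "holdout"
    rownames(labels) <- NULL
    list(graph = graph, labels = labels)
  })
}

#' Generate a multiscale interactome with a planted mechanism path
#'
#' Builds a random graph over the four MSI node types, respecting the five
#' admissible edge classes, and plants one drug-to-disease mechanism path
#' (protein at each end, biological functions in the middle) with elevated
#' connectivity: the queried drug and disease attach preferentially to the
#' planted proteins, so the planted interior nodes dominate both diffusion
#' profiles.
#'
#' @param spec a [simulation_spec()].
#' @param seed_offset stream offset.
#' @return list with `graph` (an `msi_graph`), `drug`, `disease` (the query
#'   node ids) and `planted_path` (node sequence drug -> ... -> disease).
#' @export
generate_msi_graph <- function(spec, seed_offset = 300L) {
  sz <- spec$msi_sizes
  L <- spec$planted_path_length
  prot <- sprintf("prot_%03d", seq_len(sz[["proteins"]]))
  fun <- sprintf("func_%03d", seq_len(sz[["functions"]]))
  bg_drug <- sprintf("drug_bg_%02d", seq_len(sz[["drugs"]]))
  bg_dis <- sprintf("dis_bg_%02d", seq_len(sz[["diseases"]]))
  drug <- "drug_query"
  disease <- "disease_query"
  with_seed(spec$seed + seed_offset, {
    edge <- function(s, st, t, tt) {
      data.frame(source = s, source_type = st, target = t, target_type = tt,
                 stringsAsFactors = FALSE)
    }
    # interior node types: protein at both ends, functions between
    n_int <- L - 1L
    int_types <- if (n_int == 1L) "protein" else
      c("protein", rep("biological_function", n_int - 2L), "protein")
    pool <- list(protein = prot, biological_function = fun)
    used <- c(protein = 0L, biological_function = 0L)
    interior <- character(n_int)
    for (i in seq_len(n_int)) {
      used[int_types[i]] <- used[int_types[i]] + 1L
      interior[i] <- pool[[int_types[i]]][used[int_types[i]]]
    }
    path_nodes <- c(drug, interior, disease)
    path_types <- c("drug", int_types, "disease")
    parts <- list()
    parts$planted <- do.call(rbind, lapply(seq_len(L), function(i) {
      edge(path_nodes[i], path_types[i], path_nodes[i + 1], path_types[i + 1])
    }))
    # elevated connectivity of the mechanism: both queries reach both end
    # proteins of the planted path
    p_first <- interior[1]
    p_last <- interior[n_int]
    parts$boost <- rbind(
      if (p_last != p_first) edge(drug, "drug", p_last, "protein"),
      if (p_last != p_first) edge(disease, "disease", p_first, "protein"))
    # background attachment of the queries
    bg_prot <- setdiff(prot, interior)
    parts$query_bg <- rbind(
      edge(drug, "drug", sample(bg_prot, 2), "protein"),
      edge(disease, "disease", sample(bg_prot, 4), "protein"))
    # background drugs/diseases and scaffold biology
    parts$bg_drugs <- do.call(rbind, lapply(bg_drug, function(d) {
      edge(d, "drug", sample(prot, 2), "protein")
    }))
    parts$bg_dis <- do.call(rbind, lapply(bg_dis, function(di) {
      edge(di, "disease", sample(prot, 3), "protein")
    }))
    ppi <- sample_pairs(2L * length(prot), length(prot), length(prot))
    ppi <- ppi[ppi$i != ppi$j, , drop = FALSE]
    parts$ppi <- edge(prot[ppi$i], "protein", prot[ppi$j], "protein")
    pf <- sample_pairs(length(prot), length(prot), length(fun))
    parts$pf <- edge(prot[pf$i], "protein", fun[pf$j], "biological_function")
    ff <- sample_pairs(length(fun), length(fun), length(fun))
    ff <- ff[ff$i != ff$j, , drop = FALSE]
    parts$ff <- edge(fun[ff$i], "biological_function", fun[ff$j],
                     "biological_function")
    edges <- do.call(rbind, parts)
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
    list(graph = msi_graph(edges), drug = drug, disease = disease,
         planted_path = path_nodes)
  })
}

#' Generate a synthetic pathway collection
#'
#' Random gene sets drawn from the spec's gene universe, plus - when
#' `planted_genes` is supplied - one "planted disease module" pathway made
#' of the planted differential genes, so enrichment of reversal-driven
#' overlap genes has a known answer.
#'
#' @param spec a [simulation_spec()].
#' @param planted_genes optional character vector forming the planted
#'   pathway.
#' @param n_pathways number of random background pathways.
#' @param seed_offset stream offset.
#' @return a `gene_set_collection`.
#' @export
generate_pathway_collection <- function(spec, planted_genes = NULL,
                                        n_pathways = 50L, seed_offset = 400L) {
  genes <- gene_ids(spec)
  with_seed(spec$seed + seed_offset, {
    sets <- list()
    for (i in seq_len(n_pathways)) {
      id <- sprintf("WP%04d", i)
      sets[[id]] <- list(pathway_name = sprintf("random pathway %d", i),
                         genes = sample(genes, sample(20:100, 1)))
    }
    if (!is.null(planted_genes) && length(planted_genes) > 0L) {
      sets[["WP_PLANTED"]] <- list(pathway_name = "planted disease module",
                                   genes = planted_genes)
    }
    structure(list(name = "synthetic_pathways", sets = sets),
              class = "gene_set_collection")
  })
}

#' Write every synthetic input to disk
#'
#' Materialises the formats the analysis modules read - DE tables,
#' signature-library TSV pair, hetnet and MSI edge lists - plus a
#' ground-truth manifest JSON. Byte-identical across runs with the same
#' spec.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
simulate_all <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  contrasts <- c(disease_vs_normal = 0L, progression = 1L)
  truth <- list(seed = spec$seed, contrasts = list())
  for (cn in names(contrasts)) {
    tab <- generate_disease_table(spec, cn, seed_offset = contrasts[[cn]])
    utils::write.table(tab, p(paste0(cn, ".tsv")), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth$contrasts[[cn]] <- list(planted_up = attr(tab, "planted_up"),
                                  planted_down = attr(tab, "planted_down"))
  }
  tab1 <- generate_disease_table(spec, "disease_vs_normal", seed_offset = 0L)
  sig <- build_disease_signature(tab1, signature_config("split"))
  lib <- generate_signature_library(spec, sig)
  write_signature_library(lib, p("library_ranks.tsv"), p("library_meta.tsv"))
  truth$planted_therapeutics <- spec$planted_therapeutic_ids
  gmt <- generate_pathway_collection(
    spec, planted_genes = c(attr(tab1, "planted_up"), attr(tab1, "planted_down")))
  write_gmt(gmt, p("pathways.gmt"))
  het <- generate_hetnet(spec)
  write_hetnet(het$graph, p("hetnet_edges.tsv"))
  utils::write.table(het$labels, p("hetnet_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  msi <- generate_msi_graph(spec)
  utils::write.table(msi$graph$edges, p("msi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth$msi <- list(drug = msi$drug, disease = msi$disease,
                    planted_path = msi$planted_path)
  jsonlite::write_json(truth, p("ground_truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(truth)
}
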