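#' Pipeline configuration
#'
#' Collects the file paths and stage parameters of a full discovery run.
#' `input_dir` must contain the files written by [simulate_all()] (or
#' externally prepared files in the same layout): per-contrast DE tables,
#' the library TSV pair, `pathways.gmt`, `hetnet_edges.tsv`,
#' `hetnet_labels.tsv` and `msi_edges.tsv`.
#'
#' @param input_dir directory of inputs.
#' @param out_dir directory for stage outputs and the run manifest.
#' @param contrasts contrast names (DE table file stems).
#' @param configs candidate [signature_config()]s for DGEM selection.
#' @param control_drugs control treatments anchoring configuration choice.
#' @param significance_cutoff adjusted-p cutoff for signature genes.
#' @param overlap_threshold,overlap_cap amalgamation score filter and
#'   leading-edge cap.
#' @param n_pathway_drugs how many top DGEM drugs get pathway annotation.
#' @param dwpc degree-weighting parameters ([dwpc_params()]).
#' @param msi random-walk parameters ([msi_params()]).
#' @param hetnet_disease disease node whose candidates are ranked; default
#'   the first disease node in the label file.
#' @param msi_drug,msi_disease query nodes of the mechanism stage; defaults
#'   are read from `ground_truth.json` when present.
#' @param seed seed for classifier training and evaluation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            contrasts = c("disease_vs_normal", "progression"),
                            configs = list(signature_config("split"),
                                           signature_config("combined")),
                            control_drugs = "metformin",
                            significance_cutoff = 0.05,
                            overlap_threshold = 0.5, overlap_cap = 100L,
                            n_pathway_drugs = 2L,
                            dwpc = dwpc_params(),
                            msi = msi_params(),
                            hetnet_disease = NULL,
                            msi_drug = NULL, msi_disease = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

config_files <- function(config) {
  p <- function(...) file.path(config$input_dir, ...)
  c(stats::setNames(p(paste0(config$contrasts, ".tsv")), config$contrasts),
    library_ranks = p("library_ranks.tsv"),
    library_meta = p("library_meta.tsv"),
    pathways = p("pathways.gmt"),
    hetnet_edges = p("hetnet_edges.tsv"),
    hetnet_labels = p("hetnet_labels.tsv"),
    msi_edges = p("msi_edges.tsv"))
}

#' Combine DGEM and DWPC predictions
#'
#' Outer join of the two ranked tables on drug id, with per-module rank
#' columns, a mean-of-available-ranks sort key, and a flag naming which
#' module(s) proposed each drug.
#'
#' @param dgem_ranks data.frame with `drug_id` and `rank` (e.g. from
#'   [rank_drugs()]).
#' @param dwpc_ranks data.frame with `drug_id` and `rank` (e.g. from
#'   [predict_treatments()]).
#' @return data.frame `drug_id`, `rank_dgem`, `rank_dwpc`, `combined_rank`,
#'   `modules`, ordered by the combined key (ties on drug id).
#' @export
combine_predictions <- function(dgem_ranks, dwpc_ranks) {
  a <- data.frame(drug_id = dgem_ranks$drug_id, rank_dgem = dgem_ranks$rank,
                  stringsAsFactors = FALSE)
  b <- data.frame(drug_id = dwpc_ranks$drug_id, rank_dwpc = dwpc_ranks$rank,
                  stringsAsFactors = FALSE)
  out <- merge(a, b, by = "drug_id", all = TRUE)
  out$combined_rank <- rowMeans(out[, c("rank_dgem", "rank_dwpc")], na.rm = TRUE)
  out$modules <- ifelse(is.na(out$rank_dgem), "dwpc",
                        ifelse(is.na(out$rank_dwpc), "dgem", "both"))
  out <- out[order(out$combined_rank, out$drug_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end discovery pipeline
#'
#' Executes the stages in order: disease signatures (with BH re-adjustment
#' and control-drug configuration selection), DGEM drug ranking per
#' contrast, hetnet DWPC training / evaluation / candidate ranking,
#' combination of the two ranked tables, consensus pathway enrichment for
#' the top DGEM drugs, and mechanism-subgraph extraction on the
#' interactome. All intermediates are written to `out_dir`; the returned
#' manifest records seeds, parameters and an md5 hash of every output file,
#' so reruns with an identical configuration produce identical manifests.
#' Any stage failure aborts with the stage name; files already written are
#' retained.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_discovery <- function(config) {
  files <- config_files(config)
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$out_dir, ...)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("repurposeR")),
                   seed = config$seed, stages = list())

  # --- signatures + dgem -------------------------------------------------
  dgem_tables <- list()
  choices <- list()
  lib <- stage("signatures", read_signature_library(files[["library_ranks"]],
                                                    files[["library_meta"]]))
  signatures <- list()
  for (cn in config$contrasts) {
    tab <- stage("signatures", {
      t0 <- read_gene_table(files[[cn]], contrast_id = cn)
      t0$adj_p <- adjust_pvalues_bh(t0$p_value)
      t0
    })
    choice <- stage("dgem", select_configuration(
      tab, config$configs, config$control_drugs, lib,
      significance_cutoff = config$significance_cutoff))
    sig <- stage("signatures", build_disease_signature(
      tab, choice$chosen_config,
      significance_cutoff = config$significance_cutoff, contrast_id = cn))
    signatures[[cn]] <- sig
    written <- c(written, stage("signatures", {
      write_disease_signature(sig, outp(paste0("signature_", cn, ".json")),
                              outp(paste0("signature_", cn, ".tsv")))
      outp(paste0("signature_", cn, c(".json", ".tsv")))
    }))
    ranked <- stage("dgem", rank_drugs(sig, lib))
    dgem_tables[[cn]] <- ranked
    choices[[cn]] <- choice
    written <- c(written, write_tsv(ranked, outp(paste0("dgem_", cn, ".tsv"))))
  }
  audit_path <- outp("dgem_config_choice.json")
  jsonlite::write_json(
    lapply(choices, function(ch) list(
      contrast_id = ch$contrast_id,
      chosen_config = format(ch$chosen_config),
      control_score_per_config = as.list(ch$control_score_per_config))),
    audit_path, auto_unbox = TRUE, pretty = TRUE)
  written <- c(written, audit_path)
  manifest$stages$dgem <- list(
    contrasts = config$contrasts,
    chosen_config = vapply(choices, function(ch) format(ch$chosen_config),
                           character(1)))

  # --- hetnet ------------------------------------------------------------
  het <- stage("hetnet", {
    graph <- read_hetnet(files[["hetnet_edges"]])
    labels <- utils::read.delim(files[["hetnet_labels"]],
                                stringsAsFactors = FALSE)
    metapaths <- enumerate_metapaths(graph, config$dwpc$max_metapath_length)
    feats <- build_features(graph, labels, metapaths, config$dwpc)
    evalr <- evaluate_holdout(feats, k_folds = 5L, seed = config$seed)
    train <- feats[labels$split == "train", , drop = FALSE]
    model <- train_model(train, seed = config$seed)
    disease <- config$hetnet_disease %||% labels$disease[1]
    cand <- unique(names(graph$nodes)[graph$nodes == "DRUG"])
    preds <- predict_treatments(model, graph, disease, cand, metapaths,
                                config$dwpc)
    list(metrics = evalr, preds = preds, disease = disease)
  })
  written <- c(written, write_tsv(het$preds, outp("hetnet_predictions.tsv")))
  metrics_path <- outp("hetnet_metrics.json")
  jsonlite::write_json(list(auc = het$metrics$auc, f1 = het$metrics$f1,
                            auc_sd = het$metrics$auc_sd,
                            f1_sd = het$metrics$f1_sd),
                       metrics_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, metrics_path)
  manifest$stages$hetnet <- list(disease = het$disease,
                                 auc = het$metrics$auc, f1 = het$metrics$f1)

  # --- combine -----------------------------------------------------------
  combined <- stage("combine", combine_predictions(dgem_tables[[1]], het$preds))
  written <- c(written, write_tsv(combined, outp("combined_candidates.tsv")))
  manifest$stages$combine <- list(n_candidates = nrow(combined))

  # --- pathway consensus -------------------------------------------------
  consensus <- stage("pathways", {
    gmt <- read_gmt(files[["pathways"]])
    per_contrast <- list()
    for (cn in config$contrasts) {
      sig <- signatures[[cn]]
      top_drugs <- utils::head(dgem_tables[[cn]]$drug_id, config$n_pathway_drugs)
      scored <- scale_scores(score_library(sig, lib))
      queries <- lapply(top_drugs, function(d) {
        rows <- scored[scored$drug_id == d, , drop = FALSE]
        entries <- lapply(seq_len(nrow(rows)), function(i) {
          rk <- instance_ranking(lib, rows$condition[i])
          genes <- if (rows$raw_score[i] == 0) character() else
            leading_edge_genes(sig, rk, cap = config$overlap_cap,
                               score = rows$raw_score[i])
          list(condition = rows$condition[i], score = rows$scaled_score[i],
               genes = genes)
        })
        amalgamate_signatures(d, entries, threshold = config$overlap_threshold,
                              cap = config$overlap_cap, contrast_id = cn)
      })
      genes <- unique(unlist(lapply(queries, `[[`, "genes")))
      if (length(genes)) {
        per_contrast[[cn]] <- enrich(genes, gmt, lib$gene_universe)
      }
    }
    if (length(per_contrast) == 0L) stop("no contrast produced overlap genes")
    consensus_rank(per_contrast)
  })
  written <- c(written, write_tsv(consensus, outp("pathway_consensus.tsv")))
  manifest$stages$pathways <- list(n_pathways = nrow(consensus))

  # --- msi mechanism -----------------------------------------------------
  msi_out <- stage("msi", {
    graph <- read_msi(files[["msi_edges"]])
    gt_path <- file.path(config$input_dir, "ground_truth.json")
    gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
    drug <- config$msi_drug %||% gt$msi$drug %||%
      names(graph$nodes)[graph$nodes == "drug"][1]
    disease <- config$msi_disease %||% gt$msi$disease %||%
      names(graph$nodes)[graph$nodes == "disease"][1]
    dp <- diffusion_profile(graph, config$msi, drug)
    ip <- diffusion_profile(graph, config$msi, disease)
    top <- rank_relevant_nodes(dp, ip, graph, k = config$msi$k)
    sub <- extract_mechanism_subgraph(graph, drug, disease, top$node)
    write_profile(dp, graph, outp("msi_profile_drug.tsv"))
    write_profile(ip, graph, outp("msi_profile_disease.tsv"))
    write_subgraph_json(sub, graph, outp("msi_mechanism.json"))
    write_subgraph_dot(sub, graph, outp("msi_mechanism.dot"))
    list(drug = drug, disease = disease, top = top, sub = sub)
  })
  written <- c(written, write_tsv(msi_out$top, outp("msi_top_nodes.tsv")),
               outp(c("msi_profile_drug.tsv", "msi_profile_disease.tsv",
                      "msi_mechanism.json", "msi_mechanism.dot")))
  manifest$stages$msi <- list(drug = msi_out$drug, disease = msi_out$disease,
                              n_paths = length(msi_out$sub$paths))

  # --- manifest ----------------------------------------------------------
  written <- sort(unique(written))
  hashes <- tools::md5sum(written)
  manifest$files <- as.list(stats::setNames(unname(hashes), basename(written)))
  manifest$complete_stages <- c("signatures+dgem", "hetnet", "combine",
                                "pathways", "msi")
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
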