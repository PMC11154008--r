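#' Kolmogorov-Smirnov enrichment of a tag set in a ranked gene list
#'
#' The connectivity-mapping enrichment statistic. With `t` tags among `n`
#' ranked genes and `V(j)` the ascending rank of the j-th tag, it computes
#' `a = max_j(j/t - V(j)/n)` and `b = max_j(V(j)/n - (j-1)/t)` and returns
#' `a` if `a > b`, else `-b`. Positive values mean the tags crowd the top of
#' the ranking, negative the bottom.
#'
#' @param tags character vector of gene ids (non-empty, strict subset of the
#'   ranking).
#' @param ranking ordered character vector of all gene ids in the universe,
#'   position 1 = most up-regulated by treatment.
#' @return a single number in (-1, 1\].
#' @examples
#' ks_enrichment(c("g1", "g2"), paste0("g", 1:10))  # top block: 1 - 2/10
#' @export
ks_enrichment <- function(tags, ranking) {
  t <- length(tags)
  n <- length(ranking)
  if (t == 0L) stop("tags must be non-empty", call. = FALSE)
  if (t >= n) stop("tags must be a strict subset of the universe", call. = FALSE)
  v <- match(tags, ranking)
  if (anyNA(v)) stop("all tags must appear in the ranking", call. = FALSE)
  v <- sort.int(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Connectivity score of a disease signature against one drug ranking
#'
#' In split mode, `ks_up` and `ks_down` are computed for the up- and
#' down-gene tag lists, and the raw score is `ks_up - ks_down` when the two
#' statistics disagree in sign (a drug can only mimic or reverse the whole
#' signature) and 0 when they share a sign. In combined mode the single tag
#' list is scored with one KS statistic (`ks_down` recorded as 0). Signature
#' genes absent from the library universe are dropped before scoring.
#'
#' @param signature a `disease_signature`.
#' @param ranking ordered gene list for one drug instance (see
#'   [instance_ranking()]).
#' @param drug_id,condition identifiers copied into the result row.
#' @return one-row data.frame: `drug_id`, `condition`, `ks_up`, `ks_down`,
#'   `raw_score`, `scaled_score` (NA until [scale_scores()]).
#' @export
connectivity_score <- function(signature, ranking, drug_id = NA_character_,
                               condition = NA_character_) {
  up <- intersect(signature$up_genes, ranking)
  down <- intersect(signature$down_genes, ranking)
  if (length(up) + length(down) == 0L) {
    stop("no signature gene is present in the library universe", call. = FALSE)
  }
  if (signature$config$mode == "split") {
    if (length(up) == 0L || length(down) == 0L) {
      stop("split-mode scoring needs both tag lists inside the universe",
           call. = FALSE)
    }
    ks_up <- ks_enrichment(up, ranking)
    ks_down <- ks_enrichment(down, ranking)
    raw <- if (ks_up * ks_down > 0) 0 else ks_up - ks_down
  } else {
    ks_up <- ks_enrichment(up, ranking)
    ks_down <- 0
    raw <- ks_up
  }
  data.frame(drug_id = drug_id, condition = condition,
             ks_up = ks_up, ks_down = ks_down,
             raw_score = raw, scaled_score = NA_real_,
             stringsAsFactors = FALSE)
}

#' Score every instance of a library against a disease signature
#'
#' @param signature a `disease_signature`.
#' @param library a `signature_library`.
#' @return data.frame of connectivity results, one row per instance.
#' @export
score_library <- function(signature, library) {
  rows <- lapply(seq_len(nrow(library$meta)), function(i) {
    inst <- library$meta$instance[i]
    connectivity_score(signature, instance_ranking(library, inst),
                       drug_id = library$meta$drug_id[i], condition = inst)
  })
  do.call(rbind, rows)
}

#' Scale raw connectivity scores to \[-1, 1\]
#'
#' Positive raw scores are divided by the maximum positive raw score and
#' negative scores by the magnitude of the most negative one, so the scaled
#' scores span exactly \[-1, 1\] whenever both signs occur. Zeros are left
#' unchanged. The map is idempotent.
#'
#' @param results data.frame from [score_library()] / [connectivity_score()].
#' @return the same data.frame with `scaled_score` filled in.
#' @export
scale_scores <- function(results) {
  if (nrow(results) == 0L) stop("no connectivity results to scale", call. = FALSE)
  raw <- results$raw_score
  scaled <- numeric(length(raw))
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) scaled[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) scaled[neg] <- raw[neg] / abs(min(raw[neg]))
  results$scaled_score <- scaled
  results
}

condense_by_drug <- function(scored) {
  split_rows <- split(seq_len(nrow(scored)), scored$drug_id)
  rows <- lapply(names(split_rows), function(d) {
    idx <- split_rows[[d]]
    v <- scored$raw_score[idx]
    # max |raw score| with sign retained; equal magnitudes break on condition
    o <- order(-abs(v), scored$condition[idx], method = "radix")
    best <- idx[o[1L]]
    data.frame(drug_id = d, condensed_score = scored$raw_score[best],
               condensed_scaled = scored$scaled_score[best],
               n_conditions = length(idx),
               best_condition = scored$condition[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank library drugs by condensed connectivity score
#'
#' Scores every library instance, scales across the full result set, then
#' condenses each drug to the single condition of maximum absolute raw
#' connectivity score (sign retained) and sorts drugs by descending
#' absolute condensed score; the scaled score of the chosen condition is
#' carried along for threshold-style filters. Ranking uses the raw
#' statistic because the positive and negative scaling denominators differ:
#' after scaling, the best instance of each sign sits at exactly +1 / -1
#' regardless of how strong its raw score was, which would distort a
#' magnitude ranking. Ties break lexicographically on `drug_id`.
#'
#' @param signature a `disease_signature`.
#' @param library a `signature_library`.
#' @return data.frame `drug_id`, `condensed_score` (raw),
#'   `condensed_scaled`, `n_conditions`, `best_condition`, `rank`.
#' @export
rank_drugs <- function(signature, library) {
  scored <- scale_scores(score_library(signature, library))
  cond <- condense_by_drug(scored)
  o <- order(-abs(cond$condensed_score), cond$drug_id, method = "radix")
  cond <- cond[o, , drop = FALSE]
  cond$rank <- seq_len(nrow(cond))
  rownames(cond) <- NULL
  cond
}

#' Select the disease-signature configuration using control drugs
#'
#' For each candidate configuration the signature is rebuilt from the
#' contrast table and scored against every instance of each control drug;
#' per control the scores are condensed to the maximum signed raw score
#' over its conditions, and controls are aggregated by their mean. The
#' configuration attaining the highest control score wins; exact ties go to
#' a split configuration. Comparison is on signed raw scores: scaling is
#' library-wide and so undefined over a control subset, and the signed
#' maximum expresses that the control should achieve the highest
#' connectivity score under the chosen representation - a direction-free
#' configuration can therefore beat a split one whose score is dragged
#' negative or zeroed by an uninformative direction.
#'
#' @param table differential-expression table for the contrast.
#' @param configs list of [signature_config()] objects (non-empty).
#' @param control_drugs drug ids that must exist in the library (default the
#'   study's sole control, `"metformin"`).
#' @param library a `signature_library`.
#' @param significance_cutoff passed to [build_disease_signature()].
#' @return object of class `dgem_config_choice` with `chosen_config`,
#'   `control_score_per_config` and the per-control audit trail.
#' @export
select_configuration <- function(table, configs, control_drugs, library,
                                 significance_cutoff = 0.05) {
  if (length(configs) == 0L) stop("configs must be non-empty", call. = FALSE)
  missing <- setdiff(control_drugs, library$meta$drug_id)
  if (length(missing)) {
    stop(sprintf("control drug(s) not in library: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  contrast_id <- attr(table, "contrast_id") %||% "contrast"
  labels <- vapply(configs, format, character(1))
  per_config <- numeric(length(configs))
  audit <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    sig <- build_disease_signature(table, configs[[i]],
                                   significance_cutoff = significance_cutoff,
                                   contrast_id = contrast_id)
    keep <- library$meta$drug_id %in% control_drugs
    sub <- library
    sub$meta <- library$meta[keep, , drop = FALSE]
    sub$rankings <- library$rankings[, keep, drop = FALSE]
    scored <- score_library(sig, sub)
    per_drug <- vapply(split(scored$raw_score, scored$drug_id), max, numeric(1))
    per_config[i] <- mean(per_drug)
    audit[[i]] <- per_drug
  }
  names(per_config) <- labels
  names(audit) <- labels
  # argmax with split preference on exact ties
  best <- max(per_config)
  tied <- which(per_config == best)
  modes <- vapply(configs[tied], function(cf) cf$mode, character(1))
  pick <- if (any(modes == "split")) tied[which(modes == "split")[1L]] else tied[1L]
  structure(list(contrast_id = contrast_id,
                 chosen_config = configs[[pick]],
                 control_drug_ids = control_drugs,
                 control_score_per_config = per_config,
                 per_control_scores = audit),
            class = "dgem_config_choice")
}

#' @export
print.dgem_config_choice <- function(x, ...) {
  cat(sprintf("<dgem_config_choice> %s -> %s\n", x$contrast_id,
              format(x$chosen_config)))
  for (nm in names(x$control_score_per_config)) {
    cat(sprintf("  %-16s control score %.4f\n", nm,
                x$control_score_per_config[[nm]]))
  }
  invisible(x)
}
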