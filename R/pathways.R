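#' Leading-edge genes of a drug-disease connectivity score
#'
#' Returns the signature genes that drive the KS connectivity score: for
#' each tag set the running KS statistic is evaluated and the tags at or
#' before its maximal deviation are kept (from the top of the drug ranking
#' when the positive deviation dominates, from the bottom otherwise). Tag
#' sets are pooled and ordered by the extremity of each gene's rank in the
#' drug signature (distance to the nearer end), then truncated to `cap`.
#'
#' @param signature a `disease_signature`.
#' @param ranking ordered gene list for one drug instance.
#' @param cap maximum number of genes returned (default 100).
#' @param score the pair's connectivity score if already known; computed
#'   from the inputs when `NULL`. A zero score yields an empty list with a
#'   warning (nothing drives a null score).
#' @return character vector of gene ids, most extreme first.
#' @export
leading_edge_genes <- function(signature, ranking, cap = 100L, score = NULL) {
  if (cap < 1L) stop("cap must be positive", call. = FALSE)
  if (is.null(score)) {
    score <- connectivity_score(signature, ranking)$raw_score
  }
  if (score == 0) {
    warning("connectivity score is zero; no leading-edge genes")
    return(character())
  }
  n <- length(ranking)
  edge_of <- function(tags) {
    tags <- intersect(tags, ranking)
    if (length(tags) == 0L) return(character())
    v <- sort.int(match(tags, ranking))
    t <- length(v)
    j <- seq_len(t)
    a_j <- j / t - v / n
    b_j <- v / n - (j - 1) / t
    if (max(a_j) > max(b_j)) {
      ranking[v[seq_len(which.max(a_j))]]
    } else {
      ranking[v[seq(which.max(b_j), t)]]
    }
  }
  pooled <- unique(c(edge_of(signature$up_genes), edge_of(signature$down_genes)))
  if (length(pooled) == 0L) return(character())
  r <- match(pooled, ranking)
  extremity <- pmin(r, n + 1L - r)
  pooled <- pooled[order(extremity, pooled, method = "radix")]
  pooled[seq_len(min(cap, length(pooled)))]
}

#' Amalgamate per-condition overlap genes into one drug signature
#'
#' Conditions (e.g. concentrations of the same drug) whose absolute scaled
#' connectivity score falls below `threshold` are discarded; the remaining
#' ordered gene lists are merged, each gene keeping its best (earliest, i.e.
#' most extreme) position across contributing conditions, de-duplicated and
#' truncated to `cap`.
#'
#' @param drug_id identifier of the drug.
#' @param results list of entries, each `list(condition =, score =, genes =)`
#'   with `genes` ordered most-extreme-first (see [leading_edge_genes()]).
#' @param threshold inclusive absolute-score cutoff (default 0.5).
#' @param cap maximum merged-list length (default 100).
#' @param contrast_id optional contrast identifier.
#' @return object of class `overlap_gene_set`: `drug_id`, ordered `genes`,
#'   `source_conditions` data.frame. Empty (with a warning) when no
#'   condition passes the threshold.
#' @export
amalgamate_signatures <- function(drug_id, results, threshold = 0.5,
                                  cap = 100L, contrast_id = NA_character_) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  scores <- vapply(results, function(r) r$score, numeric(1))
  keep <- abs(scores) >= threshold
  src <- data.frame(
    condition = vapply(results, function(r) as.character(r$condition), character(1)),
    scaled_score = scores, used = keep, stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning(sprintf("drug '%s': no condition reaches |score| >= %g", drug_id,
                    threshold))
    genes <- character()
  } else {
    best <- list()
    for (r in results[keep]) {
      pos <- seq_along(r$genes)
      for (i in pos) {
        g <- r$genes[i]
        if (is.null(best[[g]]) || i < best[[g]]) best[[g]] <- i
      }
    }
    genes <- names(best)
    genes <- genes[order(unlist(best), genes, method = "radix")]
    genes <- genes[seq_len(min(cap, length(genes)))]
  }
  structure(list(drug_id = drug_id, contrast_id = contrast_id, genes = genes,
                 source_conditions = src),
            class = "overlap_gene_set")
}

#' @export
print.overlap_gene_set <- function(x, ...) {
  cat(sprintf("<overlap_gene_set> %s: %d genes from %d/%d conditions\n",
              x$drug_id, length(x$genes), sum(x$source_conditions$used),
              nrow(x$source_conditions)))
  invisible(x)
}

#' Gene-set collection (GMT) handling
#'
#' `read_gmt()` parses the standard tab-separated GMT dialect (set name,
#' description, member genes); `write_gmt()` emits it.
#'
#' @param path GMT file path.
#' @param name collection label (defaults to the file stem).
#' @return `read_gmt()`: object of class `gene_set_collection` whose `sets`
#'   element maps pathway id to `list(pathway_name, genes)`.
#' @export
read_gmt <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop("GMT contains an empty gene set: ", f[1], call. = FALSE)
    if (f[1] %in% names(sets)) stop("duplicate pathway id: ", f[1], call. = FALSE)
    sets[[f[1]]] <- list(pathway_name = f[2], genes = genes)
  }
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a `gene_set_collection`.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$pathway_name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(collection)
}

#' Pathway over-representation of an overlap gene set
#'
#' One-sided hypergeometric (Fisher-exact) over-representation test of the
#' query against every pathway in the collection, restricted to a background
#' gene universe, with Benjamini-Hochberg adjustment across tested pathways.
#' This is the local, deterministic stand-in for web enrichment services.
#'
#' @param query an `overlap_gene_set` or plain character vector of gene ids.
#' @param collection a `gene_set_collection`.
#' @param universe background gene ids (e.g. the drug-library universe).
#' @return data.frame ordered by ascending p (ties on pathway id):
#'   `pathway_id`, `pathway_name`, `overlap_count`, `p_value`, `adj_p`,
#'   `rank`.
#' @export
enrich <- function(query, collection, universe) {
  if (inherits(query, "overlap_gene_set")) query <- query$genes
  query <- intersect(unique(query), universe)
  if (length(query) == 0L) stop("query is empty within the universe", call. = FALSE)
  n_u <- length(universe)
  rows <- lapply(names(collection$sets), function(id) {
    genes <- intersect(collection$sets[[id]]$genes, universe)
    if (length(genes) == 0L) return(NULL)  # untestable against this universe
    k <- length(intersect(query, genes))
    p <- stats::phyper(k - 1L, length(genes), n_u - length(genes),
                       length(query), lower.tail = FALSE)
    data.frame(pathway_id = id,
               pathway_name = collection$sets[[id]]$pathway_name,
               overlap_count = k, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway overlaps the universe", call. = FALSE)
  res$adj_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$pathway_id, method = "radix"), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Consensus pathway ranking across disease contrasts
#'
#' Pathways are ordered by their mean enrichment rank over the contrasts in
#' which they were tested; per-contrast ranks are retained for plotting.
#'
#' @param per_contrast named list mapping contrast id to an [enrich()]
#'   result table.
#' @return data.frame `pathway_id`, one `rank_<contrast>` column per
#'   contrast, `mean_rank`, `n_contrasts_present`, ordered by mean rank
#'   (ties on pathway id).
#' @export
consensus_rank <- function(per_contrast) {
  if (length(per_contrast) == 0L) stop("need at least one contrast", call. = FALSE)
  ids <- sort(unique(unlist(lapply(per_contrast, `[[`, "pathway_id"))))
  ranks <- sapply(per_contrast, function(tab) {
    tab$rank[match(ids, tab$pathway_id)]
  })
  ranks <- matrix(ranks, nrow = length(ids),
                  dimnames = list(NULL, paste0("rank_", names(per_contrast))))
  out <- data.frame(pathway_id = ids, ranks, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$mean_rank <- rowMeans(ranks, na.rm = TRUE)
  out$n_contrasts_present <- rowSums(!is.na(ranks))
  out <- out[order(out$mean_rank, out$pathway_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
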