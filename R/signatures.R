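#' Benjamini-Hochberg adjustment of raw p-values
#'
#' Step-up false-discovery-rate correction. Differential-expression tables
#' assembled from several sources are re-adjusted jointly before signature
#' construction so that the significance cutoff has a uniform FDR meaning.
#'
#' @param p_values numeric vector of raw p-values, all in \[0, 1\].
#' @return numeric vector of adjusted p-values, input order preserved.
#' @examples
#' adjust_pvalues_bh(c(0.01, 0.02, 0.03))
#' @export
adjust_pvalues_bh <- function(p_values) {
  if (length(p_values) == 0L) stop("p_values must be non-empty", call. = FALSE)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signature configuration
#'
#' A disease signature is cut from a differential-expression table under one
#' of two configurations: `split` takes the top `n_up` most up- and `n_down`
#' most down-regulated significant genes as two directed tag lists;
#' `combined` takes the top `n_combined` significant genes by absolute log
#' fold change regardless of direction, as a single tag list. Defaults are
#' 250/250 and 500 respectively.
#'
#' @param mode `"split"` or `"combined"`.
#' @param n_up,n_down top-list sizes for split mode.
#' @param n_combined top-list size for combined mode.
#' @return an object of class `signature_config`.
#' @export
signature_config <- function(mode = c("split", "combined"),
                             n_up = 250L, n_down = 250L, n_combined = 500L) {
  mode <- match.arg(mode)
  if (mode == "split" && (n_up < 1L || n_down < 1L)) {
    stop("split mode requires n_up > 0 and n_down > 0", call. = FALSE)
  }
  if (mode == "combined" && n_combined < 1L) {
    stop("combined mode requires n_combined > 0", call. = FALSE)
  }
  structure(list(mode = mode, n_up = as.integer(n_up),
                 n_down = as.integer(n_down),
                 n_combined = as.integer(n_combined)),
            class = "signature_config")
}

#' @export
format.signature_config <- function(x, ...) {
  if (x$mode == "split") sprintf("split:%d,%d", x$n_up, x$n_down)
  else sprintf("combined:%d", x$n_combined)
}

#' @export
print.signature_config <- function(x, ...) {
  cat("<signature_config> ", format(x), "\n", sep = "")
  invisible(x)
}

validate_gene_table <- function(table) {
  needed <- c("gene_id", "log_fc", "p_value")
  if (!is.data.frame(table) || !all(needed %in% names(table))) {
    stop("gene table needs columns gene_id, log_fc, p_value", call. = FALSE)
  }
  if (nrow(table) == 0L) stop("gene table is empty", call. = FALSE)
  if (anyDuplicated(table$gene_id)) {
    stop("gene_id must be unique within a gene table", call. = FALSE)
  }
  if (any(table$p_value < 0 | table$p_value > 1, na.rm = TRUE)) {
    stop("p_value outside [0, 1]", call. = FALSE)
  }
  invisible(table)
}

#' Build a disease signature from a differential-expression table
#'
#' Cuts the ordered up/down (or combined) tag lists used by connectivity
#' matching. Genes must pass `adj_p < significance_cutoff`; within a
#' direction genes are ranked by log-fold-change magnitude. Ties at the
#' boundary break lexicographically on `gene_id` so output is bit-stable.
#'
#' @param table data.frame with `gene_id`, `log_fc`, `p_value` and optionally
#'   `adj_p`; if `adj_p` is absent it is computed with [adjust_pvalues_bh()].
#' @param config a [signature_config()].
#' @param significance_cutoff adjusted-p threshold defining "significantly"
#'   regulated (default 0.05).
#' @param contrast_id identifier carried through to outputs.
#' @return object of class `disease_signature` with ordered `up_genes` and
#'   `down_genes` (the latter empty in combined mode, where `up_genes` holds
#'   the combined tag list and `direction` records per-gene sign).
#' @export
build_disease_signature <- function(table, config = signature_config(),
                                    significance_cutoff = 0.05,
                                    contrast_id = attr(table, "contrast_id") %||% "contrast") {
  validate_gene_table(table)
  if (is.null(table$adj_p)) table$adj_p <- adjust_pvalues_bh(table$p_value)
  sig <- table[!is.na(table$adj_p) & table$adj_p < significance_cutoff, , drop = FALSE]

  # lexicographic gene_id tie-break: order by (-|lfc|, gene_id)
  pick_top <- function(df, n) {
    if (nrow(df) == 0L) return(character())
    o <- order(-abs(df$log_fc), df$gene_id, method = "radix")
    df$gene_id[o][seq_len(min(n, nrow(df)))]
  }

  if (config$mode == "split") {
    up_pool <- sig[sig$log_fc > 0, , drop = FALSE]
    down_pool <- sig[sig$log_fc < 0, , drop = FALSE]
    if (nrow(up_pool) == 0L) {
      stop(sprintf("contrast '%s': no significant up-regulated genes", contrast_id),
           call. = FALSE)
    }
    if (nrow(down_pool) == 0L) {
      stop(sprintf("contrast '%s': no significant down-regulated genes", contrast_id),
           call. = FALSE)
    }
    up <- pick_top(up_pool, config$n_up)
    down <- pick_top(down_pool, config$n_down)
    direction <- stats::setNames(rep(c("up", "down"), c(length(up), length(down))),
                                 c(up, down))
  } else {
    if (nrow(sig) == 0L) {
      stop(sprintf("contrast '%s': no significant genes for combined signature",
                   contrast_id), call. = FALSE)
    }
    up <- pick_top(sig, config$n_combined)
    down <- character()
    direction <- stats::setNames(ifelse(sig$log_fc[match(up, sig$gene_id)] >= 0,
                                        "up", "down"), up)
  }
  structure(list(contrast_id = contrast_id, config = config,
                 up_genes = up, down_genes = down, direction = direction),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat(sprintf("<disease_signature> %s [%s] %d up / %d down genes\n",
              x$contrast_id, format(x$config),
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a differential-expression table
#'
#' Expects a TSV with header `gene_id  log_fc  p_value` and optionally
#' `adj_p`, one file per disease contrast.
#'
#' @param path TSV path.
#' @param contrast_id optional id; defaults to the file stem.
#' @return validated data.frame with a `contrast_id` attribute.
#' @export
read_gene_table <- function(path, contrast_id = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$gene_id <- as.character(tab$gene_id)
  validate_gene_table(tab)
  attr(tab, "contrast_id") <- contrast_id %||%
    sub("\\.[^.]*$", "", basename(path))
  tab
}

#' Write a disease signature to disk
#'
#' Emits both a JSON record (contrast, configuration, ordered gene lists) and
#' a two-column TSV (`gene_id`, `direction`).
#'
#' @param signature a `disease_signature`.
#' @param json_path,tsv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the signature.
#' @export
write_disease_signature <- function(signature, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(contrast_id = signature$contrast_id,
           config = unclass(signature$config),
           up_genes = signature$up_genes,
           down_genes = signature$down_genes),
      json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    genes <- c(signature$up_genes, signature$down_genes)
    utils::write.table(
      data.frame(gene_id = genes,
                 direction = unname(signature$direction[genes])),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(signature)
}
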