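#' Drug-signature library
#'
#' A library holds one full gene ranking per drug x condition instance over a
#' shared gene universe (rank 1 = most up-regulated by treatment), mirroring
#' the processed CMap/LINCS layout that connectivity matching consumes.
#'
#' @param rankings integer matrix, rows = genes of the universe (rownames =
#'   gene ids), columns = signature instances; each column is a permutation
#'   of 1..nrow assigning ranks to genes.
#' @param meta data.frame with one row per instance: `instance`, `drug_id`,
#'   `cell_context`, `concentration` (and optionally `replicate`).
#' @return object of class `signature_library`.
#' @export
signature_library <- function(rankings, meta) {
  if (is.null(rownames(rankings))) stop("rankings needs gene-id rownames", call. = FALSE)
  if (!all(c("instance", "drug_id") %in% names(meta))) {
    stop("meta needs columns instance and drug_id", call. = FALSE)
  }
  if (ncol(rankings) != nrow(meta) ||
      !identical(colnames(rankings), as.character(meta$instance))) {
    stop("rankings columns must match meta$instance, in order", call. = FALSE)
  }
  n <- nrow(rankings)
  ok <- apply(rankings, 2L, function(r) identical(sort(as.integer(r)), seq_len(n)))
  if (!all(ok)) {
    stop("every instance ranking must be a permutation of the gene universe",
         call. = FALSE)
  }
  structure(list(gene_universe = rownames(rankings),
                 rankings = rankings, meta = meta),
            class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("<signature_library> %d genes, %d instances, %d drugs\n",
              length(x$gene_universe), ncol(x$rankings),
              length(unique(x$meta$drug_id))))
  invisible(x)
}

#' Instance ranking as an ordered gene list
#'
#' @param library a `signature_library`.
#' @param instance instance (column) identifier.
#' @return character vector of gene ids ordered by treatment rank
#'   (position 1 = most up-regulated).
#' @export
instance_ranking <- function(library, instance) {
  r <- library$rankings[, as.character(instance)]
  library$gene_universe[order(r)]
}

#' Read a drug-signature library from its TSV pair
#'
#' `rank_path` is a wide TSV (first column `gene_id`, remaining columns =
#' instances, cells = ranks); `meta_path` is a TSV with columns `instance`,
#' `drug_id`, `cell_context`, `concentration`.
#'
#' @param rank_path,meta_path file paths.
#' @return a `signature_library`.
#' @export
read_signature_library <- function(rank_path, meta_path) {
  wide <- utils::read.delim(rank_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(wide[[1]])
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta$instance <- as.character(meta$instance)
  signature_library(m, meta)
}

#' Write a drug-signature library to its TSV pair
#'
#' @param library a `signature_library`.
#' @param rank_path,meta_path output paths.
#' @return invisibly, the library.
#' @export
write_signature_library <- function(library, rank_path, meta_path) {
  wide <- data.frame(gene_id = library$gene_universe,
                     library$rankings, check.names = FALSE)
  utils::write.table(wide, rank_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(library$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(library)
}
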