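#' Typed heterogeneous graph (hetnet)
#'
#' A multigraph whose nodes carry one of several semantic types (DRUG,
#' DISEASE, GENE, ...) and whose edges carry a relation. Edges are stored as
#' a typed edge list and are traversable in both directions; the metagraph
#' (schema) is derived from the distinct (type, relation, type) triples.
#'
#' @param edges data.frame with columns `source`, `source_type`, `relation`,
#'   `target`, `target_type`.
#' @return object of class `het_graph` with `nodes` (id -> type), `edges`,
#'   `schema` and directional adjacency lists per metaedge.
#' @export
het_graph <- function(edges) {
  needed <- c("source", "source_type", "relation", "target", "target_type")
  if (!all(needed %in% names(edges))) {
    stop("edge list needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  edges <- as.data.frame(lapply(edges[needed], as.character),
                         stringsAsFactors = FALSE)
  if (any(edges$source == edges$target)) stop("self-loops are not allowed", call. = FALSE)
  types <- c(stats::setNames(edges$source_type, edges$source),
             stats::setNames(edges$target_type, edges$target))
  types <- types[!duplicated(names(types))]
  if (any(types[edges$source] != edges$source_type) ||
      any(types[edges$target] != edges$target_type)) {
    stop("a node appears with two different types", call. = FALSE)
  }
  schema <- unique(edges[, c("source_type", "relation", "target_type")])
  rownames(schema) <- NULL
  # directional adjacency: key "A|rel|B" lists, per node of type A, its
  # B-typed neighbours through rel (both storage directions folded in)
  fwd_key <- paste(edges$source_type, edges$relation, edges$target_type, sep = "|")
  rev_key <- paste(edges$target_type, edges$relation, edges$source_type, sep = "|")
  adj <- new.env(parent = emptyenv())
  add <- function(key, from, to) {
    m <- adj[[key]]
    if (is.null(m)) m <- list()
    m[[from]] <- c(m[[from]], to)
    adj[[key]] <- m
  }
  for (i in seq_len(nrow(edges))) {
    add(fwd_key[i], edges$source[i], edges$target[i])
    add(rev_key[i], edges$target[i], edges$source[i])
  }
  structure(list(nodes = types, edges = edges, schema = schema, adj = adj),
            class = "het_graph")
}

#' @export
print.het_graph <- function(x, ...) {
  cat(sprintf("<het_graph> %d nodes (%d types), %d edges (%d metaedges)\n",
              length(x$nodes), length(unique(x$nodes)), nrow(x$edges),
              nrow(x$schema)))
  invisible(x)
}

#' Read a typed edge list
#'
#' TSV dialect `source_id  source_type  relation  target_id  target_type`.
#'
#' @param path TSV path.
#' @return a `het_graph`.
#' @export
read_hetnet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab)[1:5] <- c("source", "source_type", "relation", "target", "target_type")
  het_graph(tab)
}

#' @rdname read_hetnet
#' @param graph a `het_graph`.
#' @export
write_hetnet <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(graph)
}

neighbours_via <- function(graph, node, from_type, relation, to_type) {
  m <- graph$adj[[paste(from_type, relation, to_type, sep = "|")]]
  if (is.null(m)) character() else m[[node]] %||% character()
}

#' Remove one specific edge from a hetnet
#'
#' Used for leakage masking: the DRUG-treats-DISEASE edge of the pair being
#' featurised must not contribute to its own features (nor to the degrees
#' entering the degree weighting).
#'
#' @param graph a `het_graph`.
#' @param source,relation,target the edge to drop (either stored direction).
#' @return a `het_graph` without that edge (unchanged if absent).
#' @export
mask_edge <- function(graph, source, relation, target) {
  e <- graph$edges
  hit <- e$relation == relation &
    ((e$source == source & e$target == target) |
       (e$source == target & e$target == source))
  if (!any(hit)) return(graph)
  het_graph(e[!hit, , drop = FALSE])
}

#' DWPC parameters
#'
#' @param w damping exponent applied to the metaedge-specific degrees along
#'   a path (default 0.4); `w = 0` recovers the raw path count.
#' @param max_metapath_length maximum metapath edge count (default 3).
#' @return object of class `dwpc_params`.
#' @export
dwpc_params <- function(w = 0.4, max_metapath_length = 3L) {
  if (w < 0) stop("w must be >= 0", call. = FALSE)
  structure(list(w = w, max_metapath_length = as.integer(max_metapath_length)),
            class = "dwpc_params")
}

metapath_id <- function(mp) {
  parts <- mp$types[1]
  for (i in seq_along(mp$relations)) {
    parts <- c(parts, mp$relations[i], mp$types[i + 1])
  }
  paste(parts, collapse = "-")
}

#' Enumerate DRUG-to-DISEASE metapaths of a schema
#'
#' All type-consistent metapaths starting at DRUG and ending at DISEASE with
#' at most `max_length` edges, walking schema metaedges in either direction.
#' Order is deterministic: by length, then lexicographic id.
#'
#' @param schema data.frame (`source_type`, `relation`, `target_type`) or a
#'   `het_graph` (whose schema is used).
#' @param max_length maximum edge count (>= 1).
#' @param start,end endpoint node types (defaults DRUG, DISEASE).
#' @return list of metapaths; each has `types` (length edges+1),
#'   `relations` (length edges) and an `id` string.
#' @export
enumerate_metapaths <- function(schema, max_length = 3L,
                                start = "DRUG", end = "DISEASE") {
  if (inherits(schema, "het_graph")) schema <- schema$schema
  if (max_length < 1L) stop("max_length must be >= 1", call. = FALSE)
  # undirected metaedges, traversable both ways
  steps <- unique(rbind(
    schema[, c("source_type", "relation", "target_type")],
    stats::setNames(schema[, c("target_type", "relation", "source_type")],
                    c("source_type", "relation", "target_type"))))
  out <- list()
  grow <- function(types, relations) {
    if (length(relations) > 0L && types[length(types)] == end) {
      mp <- list(types = types, relations = relations)
      mp$id <- metapath_id(mp)
      out[[length(out) + 1L]] <<- mp
    }
    if (length(relations) >= max_length) return()
    here <- steps[steps$source_type == types[length(types)], , drop = FALSE]
    for (i in seq_len(nrow(here))) {
      grow(c(types, here$target_type[i]), c(relations, here$relation[i]))
    }
  }
  grow(start, character())
  ids <- vapply(out, `[[`, character(1), "id")
  lens <- vapply(out, function(m) length(m$relations), integer(1))
  out[order(lens, ids, method = "radix")]
}

#' Degree-weighted path count
#'
#' Sums, over all simple (node-disjoint) paths from `source` to `target`
#' conforming to the metapath, the product of metaedge-specific endpoint
#' degrees raised to `-w`: each traversed edge (u, v) contributes
#' `(d_out(u) * d_in(v))^-w`, where `d_out`/`d_in` are u's and v's degrees
#' restricted to that metaedge and traversal direction. Down-weights paths
#' through hubs; `w = 0` gives the plain conforming-path count.
#'
#' @param graph a `het_graph`.
#' @param metapath one element of [enumerate_metapaths()].
#' @param source,target node ids with the metapath's endpoint types.
#' @param params a [dwpc_params()].
#' @return a non-negative number; 0 when no conforming path exists.
#' @export
dwpc <- function(graph, metapath, source, target, params = dwpc_params()) {
  tp <- graph$nodes
  if (is.na(tp[source]) || tp[[source]] != metapath$types[1]) {
    stop("source type does not match the metapath start", call. = FALSE)
  }
  if (is.na(tp[target]) || tp[[target]] != metapath$types[length(metapath$types)]) {
    stop("target type does not match the metapath end", call. = FALSE)
  }
  w <- params$w
  L <- length(metapath$relations)
  deg <- function(node, from_type, rel, to_type) {
    length(neighbours_via(graph, node, from_type, rel, to_type))
  }
  total <- 0
  walk <- function(u, step, visited, prod) {
    ft <- metapath$types[step]
    tt <- metapath$types[step + 1]
    rel <- metapath$relations[step]
    nb <- neighbours_via(graph, u, ft, rel, tt)
    if (step == L) {
      nb <- nb[nb == target]
    } else {
      nb <- setdiff(nb, c(visited, target))
    }
    if (length(nb) == 0L) return()
    d_u <- deg(u, ft, rel, tt)
    for (v in nb) {
      contrib <- prod * (d_u * deg(v, tt, rel, ft))^(-w)
      if (step == L) {
        total <<- total + contrib
      } else {
        walk(v, step + 1L, c(visited, v), contrib)
      }
    }
  }
  walk(source, 1L, source, 1)
  total
}

#' DWPC feature matrix for drug-disease pairs
#'
#' One row per pair, one column per metapath. The pair's own treats edge (if
#' present in the graph) is masked during its feature computation so known
#' treatments never leak into their own features.
#'
#' @param graph a `het_graph`.
#' @param pairs data.frame with `drug`, `disease` and a `label` column in
#'   `{"positive", "negative", "unlabeled"}`.
#' @param metapaths list from [enumerate_metapaths()].
#' @param params a [dwpc_params()].
#' @param treat_relation relation name of treatment edges (default "treats").
#' @return data.frame: `drug`, `disease`, `label`, then one numeric column
#'   per metapath id.
#' @export
build_features <- function(graph, pairs, metapaths, params = dwpc_params(),
                           treat_relation = "treats") {
  ids <- vapply(metapaths, `[[`, character(1), "id")
  feat <- matrix(0, nrow = nrow(pairs), ncol = length(metapaths),
                 dimnames = list(NULL, ids))
  for (i in seq_len(nrow(pairs))) {
    g <- mask_edge(graph, pairs$drug[i], treat_relation, pairs$disease[i])
    for (j in seq_along(metapaths)) {
      feat[i, j] <- dwpc(g, metapaths[[j]], pairs$drug[i], pairs$disease[i],
                         params)
    }
  }
  cbind(pairs[, c("drug", "disease", "label")],
        as.data.frame(feat, check.names = FALSE))
}

feature_columns <- function(features) {
  setdiff(names(features), c("drug", "disease", "label"))
}

#' Train the treatment classifier on DWPC features
#'
#' Features are standardised (constant columns pass through) and a
#' single-hidden-layer feed-forward network with logistic output is fitted
#' by [nnet::nnet()] under the given seed, so training is reproducible.
#'
#' @param features data.frame from [build_features()] with labels
#'   `"positive"`/`"negative"`.
#' @param seed RNG seed for weight initialisation.
#' @param hidden hidden-layer size (default 16).
#' @param decay,maxit weight decay and iteration cap passed to nnet.
#' @return object of class `treatment_model`.
#' @export
train_model <- function(features, seed = 1L, hidden = 16L,
                        decay = 1e-3, maxit = 500L) {
  lab <- features$label
  if (length(unique(lab[lab != "unlabeled"])) < 2L) {
    stop("training needs both positive and negative labels", call. = FALSE)
  }
  use <- lab %in% c("positive", "negative")
  x <- as.matrix(features[use, feature_columns(features), drop = FALSE])
  y <- as.numeric(lab[use] == "positive")
  centre <- colMeans(x)
  spread <- apply(x, 2L, stats::sd)
  spread[spread == 0] <- 1
  xs <- scale(x, centre, spread)
  set.seed(seed)
  fit <- nnet::nnet(xs, y, size = hidden, decay = decay, maxit = maxit,
                    entropy = TRUE, trace = FALSE)
  structure(list(fit = fit, centre = centre, spread = spread,
                 feature_names = colnames(x),
                 meta = list(seed = seed, hidden = hidden, decay = decay,
                             maxit = maxit, n_pos = sum(y), n_neg = sum(1 - y))),
            class = "treatment_model")
}

#' @export
print.treatment_model <- function(x, ...) {
  cat(sprintf(
    "<treatment_model> %d features -> %d hidden units (seed %d, %d pos / %d neg)\n",
    length(x$feature_names), x$meta$hidden, x$meta$seed, x$meta$n_pos,
    x$meta$n_neg))
  invisible(x)
}

#' @export
predict.treatment_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  xs <- scale(x, object$centre, object$spread)
  as.numeric(stats::predict(object$fit, xs))
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Ties contribute 1/2, so constant scores give exactly 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels logical or 0/1 vector, TRUE/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels)
  if (tp == 0L) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(labels)
  2 * prec * rec / (prec + rec)
}

#' Held-out evaluation of the treatment classifier
#'
#' Stratified k-fold cross-validation: each fold's positives and negatives
#' are held out, the model is retrained on the rest, and AUC / F1 (at the
#' 0.5 probability threshold) are computed on the held-out fold. Because
#' every pair's own treats edge is masked in [build_features()], held-out
#' treatment edges never inform their own features.
#'
#' @param features labelled feature table from [build_features()].
#' @param k_folds number of folds (default 5).
#' @param seed seed controlling fold assignment and per-fold training.
#' @param ... passed to [train_model()].
#' @return list with `auc`, `f1` (means), `auc_sd`, `f1_sd` and a
#'   `per_fold` data.frame.
#' @export
evaluate_holdout <- function(features, k_folds = 5L, seed = 1L, ...) {
  use <- features$label %in% c("positive", "negative")
  feats <- features[use, , drop = FALSE]
  pos <- which(feats$label == "positive")
  neg <- which(feats$label == "negative")
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("evaluation needs both classes", call. = FALSE)
  }
  if (length(pos) < k_folds || length(neg) < k_folds) {
    stop("too few labelled pairs for the requested number of folds", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(feats))
  fold[pos] <- sample(rep_len(seq_len(k_folds), length(pos)))
  fold[neg] <- sample(rep_len(seq_len(k_folds), length(neg)))
  per_fold <- lapply(seq_len(k_folds), function(f) {
    train <- feats[fold != f, , drop = FALSE]
    test <- feats[fold == f, , drop = FALSE]
    model <- train_model(train, seed = seed + f, ...)
    p <- stats::predict(model, test)
    y <- test$label == "positive"
    data.frame(fold = f, n_test = nrow(test),
               auc = auc_score(p, y), f1 = f1_score(p, y))
  })
  per_fold <- do.call(rbind, per_fold)
  list(auc = mean(per_fold$auc), f1 = mean(per_fold$f1),
       auc_sd = stats::sd(per_fold$auc), f1_sd = stats::sd(per_fold$f1),
       per_fold = per_fold)
}

connected_to <- function(graph, node) {
  # BFS over the untyped undirected edge list
  e <- graph$edges
  seen <- node
  frontier <- node
  while (length(frontier)) {
    nb <- c(e$target[e$source %in% frontier], e$source[e$target %in% frontier])
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  seen
}

#' Rank candidate drugs for a disease
#'
#' Candidates are restricted to drugs connected to the disease in the graph,
#' featurised with the treats-edge mask, scored by the trained classifier
#' and ranked by descending score (ties on drug id). Candidates whose DWPC
#' features are all zero are still scored but flagged.
#'
#' @param model a `treatment_model`.
#' @param graph a `het_graph`.
#' @param disease disease node id (must exist in the graph).
#' @param candidate_drugs drug node ids to consider.
#' @param metapaths,params as in [build_features()].
#' @return data.frame `drug_id`, `score`, `rank`, `disconnected_features`.
#' @export
predict_treatments <- function(model, graph, disease, candidate_drugs,
                               metapaths, params = dwpc_params()) {
  if (is.na(graph$nodes[disease])) stop("disease not in graph: ", disease, call. = FALSE)
  comp <- connected_to(graph, disease)
  cand <- intersect(candidate_drugs, comp)
  if (length(cand) == 0L) {
    return(data.frame(drug_id = character(), score = numeric(),
                      rank = integer(), disconnected_features = logical()))
  }
  pairs <- data.frame(drug = cand, disease = disease, label = "unlabeled",
                      stringsAsFactors = FALSE)
  feats <- build_features(graph, pairs, metapaths, params)
  fc <- as.matrix(feats[, feature_columns(feats), drop = FALSE])
  score <- stats::predict(model, feats)
  out <- data.frame(drug_id = cand, score = score,
                    disconnected_features = rowSums(fc != 0) == 0L,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug_id, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("drug_id", "score", "rank", "disconnected_features")]
}
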