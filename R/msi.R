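MSI_TYPES <- c("drug", "disease", "protein", "biological_function")

msi_edge_class <- function(type_a, type_b) {
  paste(sort(c(type_a, type_b)), collapse = "--")
}

MSI_ALLOWED_CLASSES <- c(
  msi_edge_class("drug", "protein"),
  msi_edge_class("disease", "protein"),
  msi_edge_class("protein", "protein"),
  msi_edge_class("protein", "biological_function"),
  msi_edge_class("biological_function", "biological_function"))

#' Multiscale-interactome graph
#'
#' An undirected graph over drugs, diseases, proteins and biological
#' functions whose edges fall in the five admissible classes: drug-protein,
#' disease-protein, protein-protein, protein-function and function-function.
#'
#' @param edges data.frame with columns `source`, `source_type`, `target`,
#'   `target_type`; types must be one of `drug`, `disease`, `protein`,
#'   `biological_function`.
#' @return object of class `msi_graph` with `nodes` (id -> type), `edges`
#'   (with a derived `class` column) and an adjacency list.
#' @export
msi_graph <- function(edges) {
  needed <- c("source", "source_type", "target", "target_type")
  if (!all(needed %in% names(edges))) {
    stop("edge list needs columns ", paste(needed, collapse = ", "), call. = FALSE)
  }
  edges <- as.data.frame(lapply(edges[needed], as.character),
                         stringsAsFactors = FALSE)
  if (!all(c(edges$source_type, edges$target_type) %in% MSI_TYPES)) {
    stop("node types must be one of: ", paste(MSI_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$source == edges$target)) stop("self-loops are not allowed", call. = FALSE)
  cls <- mapply(msi_edge_class, edges$source_type, edges$target_type,
                USE.NAMES = FALSE)
  bad <- !cls %in% MSI_ALLOWED_CLASSES
  if (any(bad)) {
    stop("inadmissible edge class: ", paste(unique(cls[bad]), collapse = ", "),
         call. = FALSE)
  }
  edges$class <- cls
  types <- c(stats::setNames(edges$source_type, edges$source),
             stats::setNames(edges$target_type, edges$target))
  types <- types[!duplicated(names(types))]
  if (any(types[edges$source] != edges$source_type) ||
      any(types[edges$target] != edges$target_type)) {
    stop("a node appears with two different types", call. = FALSE)
  }
  adj <- split(c(edges$target, edges$source), c(edges$source, edges$target))
  adj <- lapply(adj, unique)
  structure(list(nodes = types, edges = edges, adj = adj),
            class = "msi_graph")
}

#' @export
print.msi_graph <- function(x, ...) {
  tb <- table(x$nodes)
  cat(sprintf("<msi_graph> %d nodes (%s), %d edges\n", length(x$nodes),
              paste(sprintf("%s: %d", names(tb), tb), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Read a multiscale-interactome edge list
#'
#' Accepts the typed TSV dialect `source  source_type  [relation]  target
#' target_type` (the relation column, if present, is ignored: MSI edge
#' classes follow from endpoint types), or - via `class_files` - a named
#' list of plain two-column edge lists, one per edge class, with names like
#' `"drug-protein"` determining both endpoint types.
#'
#' @param path typed edge-list TSV.
#' @param class_files alternatively, named list of two-column TSV paths; the
#'   name `"a-b"` types the first column as `a` and the second as `b`.
#' @return an `msi_graph`.
#' @export
read_msi <- function(path = NULL, class_files = NULL) {
  if (!is.null(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    needed <- c("source", "source_type", "target", "target_type")
    if (!all(needed %in% names(tab))) {
      # headerless/positional dialect: source type [relation] target type
      if (ncol(tab) == 5L) tab <- tab[, -3]
      names(tab) <- needed
    }
    return(msi_graph(tab[needed]))
  }
  stopifnot(!is.null(class_files))
  parts <- lapply(names(class_files), function(cls) {
    ty <- strsplit(cls, "-", fixed = TRUE)[[1]]
    two <- utils::read.delim(class_files[[cls]], header = FALSE,
                             stringsAsFactors = FALSE)
    data.frame(source = as.character(two[[1]]), source_type = ty[1],
               target = as.character(two[[2]]), target_type = ty[2],
               stringsAsFactors = FALSE)
  })
  msi_graph(do.call(rbind, parts))
}

#' Parameters of the biased random walk with restart
#'
#' The walk steps from a node to a neighbour with probability proportional
#' to the weight of the neighbour's type, and continues (rather than
#' restarting at the start node) with probability `alpha`. Defaults are the
#' published multiscale-interactome optima: w_drug = 3.21, w_disease = 3.54,
#' w_protein = 4.40, w_function = 6.58, alpha = 0.859; `k` = 10 nodes are
#' kept when ranking mechanism candidates.
#'
#' @param w_drug,w_disease,w_protein,w_function positive type weights.
#' @param alpha continuation probability in \[0, 1).
#' @param k top-k size for mechanism ranking.
#' @param tol max-norm convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @return object of class `msi_params`.
#' @export
msi_params <- function(w_drug = 3.21, w_disease = 3.54, w_protein = 4.40,
                       w_function = 6.58, alpha = 0.859, k = 10L,
                       tol = 1e-10, max_iter = 10000L) {
  w <- c(drug = w_drug, disease = w_disease, protein = w_protein,
         biological_function = w_function)
  if (any(w <= 0)) stop("type weights must be positive", call. = FALSE)
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  structure(list(weights = w, alpha = alpha, k = as.integer(k), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "msi_params")
}

#' Row-stochastic transition operator of the biased walk
#'
#' From node u the walk moves to neighbour v with probability
#' `w_type(v) / sum of w_type over u's neighbours`. Rows of non-isolated
#' nodes sum to one; isolated nodes keep an all-zero row and fail at walk
#' time. Rescaling all four weights by a common factor leaves the operator
#' unchanged.
#'
#' @param graph an `msi_graph`.
#' @param params an [msi_params()].
#' @return dense row-stochastic matrix with node-id dimnames.
#' @export
transition_operator <- function(graph, params = msi_params()) {
  ids <- names(graph$nodes)
  n <- length(ids)
  if (n == 0L) stop("graph is empty", call. = FALSE)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  wt <- params$weights[graph$nodes]
  names(wt) <- ids
  for (u in ids) {
    nb <- graph$adj[[u]]
    if (is.null(nb) || length(nb) == 0L) next
    P[u, nb] <- wt[nb] / sum(wt[nb])
  }
  P
}

#' Diffusion profile of a drug or disease node
#'
#' Solves the restart-walk fixed point `r = (1 - alpha) e_start +
#' alpha t(P) r` by power iteration from the uniform vector, converging in
#' max-norm. The result is the stationary visitation distribution of the
#' biased walk: where the start node's influence propagates through
#' proteins and biological functions.
#'
#' @param graph an `msi_graph`.
#' @param params an [msi_params()].
#' @param start node id (must be present and non-isolated).
#' @return object of class `diffusion_profile` with `start_node` and a
#'   named `visitation` probability vector over all nodes.
#' @export
diffusion_profile <- function(graph, params = msi_params(), start) {
  ids <- names(graph$nodes)
  if (!start %in% ids) stop("start node not in graph: ", start, call. = FALSE)
  if (is.null(graph$adj[[start]]) || length(graph$adj[[start]]) == 0L) {
    stop("start node is isolated: ", start, call. = FALSE)
  }
  # restrict to the start node's connected component: the walk can never
  # leave it, so the profile's support must not either
  comp <- start
  frontier <- start
  while (length(frontier)) {
    nb <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    frontier <- setdiff(nb, comp)
    comp <- c(comp, frontier)
  }
  P <- transition_operator(graph, params)[comp, comp, drop = FALSE]
  tP <- t(P)
  e <- stats::setNames(numeric(length(comp)), comp)
  e[start] <- 1
  alpha <- params$alpha
  r <- rep(1 / length(comp), length(comp))
  for (it in seq_len(params$max_iter)) {
    r_new <- (1 - alpha) * e + alpha * as.numeric(tP %*% r)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < params$tol) {
      full <- stats::setNames(numeric(length(ids)), ids)
      full[comp] <- r
      return(structure(list(start_node = start, visitation = full),
                       class = "diffusion_profile"))
    }
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
               params$max_iter, delta), call. = FALSE)
}

#' @export
print.diffusion_profile <- function(x, ...) {
  top <- sort(x$visitation, decreasing = TRUE)[1:min(5, length(x$visitation))]
  cat(sprintf("<diffusion_profile> from %s over %d nodes; top: %s\n",
              x$start_node, length(x$visitation),
              paste(sprintf("%s=%.3g", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Write a diffusion profile as TSV
#'
#' Columns `node`, `type`, `probability`, descending probability.
#'
#' @param profile a `diffusion_profile`.
#' @param graph the `msi_graph` it was computed on (for node types).
#' @param path output TSV path.
#' @export
write_profile <- function(profile, graph, path) {
  v <- profile$visitation
  o <- order(-v, names(v), method = "radix")
  utils::write.table(
    data.frame(node = names(v)[o], type = unname(graph$nodes[names(v)[o]]),
               probability = unname(v[o])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' Rank mechanism-relevant proteins and biological functions
#'
#' Combines the drug and disease diffusion profiles over nodes of the
#' requested types and returns the top-k. The default combination is the
#' geometric mean of the two visitation probabilities, which rewards nodes
#' prominent in both profiles (a node visited by only one profile scores
#' zero); arithmetic mean and minimum are available alternatives. Ties
#' break on node id.
#'
#' @param drug_profile,disease_profile `diffusion_profile`s over the same
#'   graph.
#' @param graph the `msi_graph`.
#' @param types node types eligible for ranking.
#' @param k how many nodes to return (>= 1).
#' @param combine combination rule.
#' @return data.frame `node`, `type`, `score`, ordered by descending score.
#' @export
rank_relevant_nodes <- function(drug_profile, disease_profile, graph,
                                types = c("protein", "biological_function"),
                                k = 10L,
                                combine = c("geometric", "arithmetic", "min")) {
  combine <- match.arg(combine)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!identical(sort(names(drug_profile$visitation)),
                 sort(names(disease_profile$visitation)))) {
    stop("profiles must cover the same node set", call. = FALSE)
  }
  eligible <- names(graph$nodes)[graph$nodes %in% types]
  a <- drug_profile$visitation[eligible]
  b <- disease_profile$visitation[eligible]
  score <- switch(combine,
                  geometric = sqrt(a * b),
                  arithmetic = (a + b) / 2,
                  min = pmin(a, b))
  o <- order(-score, eligible, method = "radix")
  o <- o[seq_len(min(k, length(o)))]
  data.frame(node = eligible[o], type = unname(graph$nodes[eligible[o]]),
             score = unname(score[o]), stringsAsFactors = FALSE)
}

#' Extract the mechanism subgraph linking a drug to a disease
#'
#' Enumerates all simple drug-to-disease paths of at most `max_path_length`
#' edges whose interior nodes all lie in `allowed_nodes` (typically the
#' top-k ranked proteins and functions) and returns their union as a
#' subgraph for rendering.
#'
#' @param graph an `msi_graph`.
#' @param drug,disease node ids.
#' @param allowed_nodes permitted interior nodes.
#' @param max_path_length maximum path edge count (default 6).
#' @return object of class `mechanism_subgraph`: `paths` (list of node
#'   sequences), `nodes`, `edges` (subset of the graph's edges) and the
#'   query metadata. Empty with a warning when no path qualifies.
#' @export
extract_mechanism_subgraph <- function(graph, drug, disease, allowed_nodes,
                                       max_path_length = 6L) {
  ids <- names(graph$nodes)
  if (!drug %in% ids) stop("drug not in graph: ", drug, call. = FALSE)
  if (!disease %in% ids) stop("disease not in graph: ", disease, call. = FALSE)
  keep <- unique(c(drug, disease, intersect(allowed_nodes, ids)))
  e <- graph$edges
  sub <- e[e$source %in% keep & e$target %in% keep, , drop = FALSE]
  paths <- list()
  if (nrow(sub) > 0L) {
    g <- igraph::graph_from_data_frame(sub[, c("source", "target")],
                                       directed = FALSE,
                                       vertices = sort(keep))
    if (drug %in% igraph::V(g)$name && disease %in% igraph::V(g)$name) {
      raw <- igraph::all_simple_paths(g, from = drug, to = disease,
                                      cutoff = max_path_length)
      paths <- lapply(raw, function(p) igraph::V(g)$name[p])
      # deterministic path order: by length then lexicographic node sequence
      key <- vapply(paths, paste, character(1), collapse = "\r")
      paths <- paths[order(lengths(paths), key, method = "radix")]
    }
  }
  if (length(paths) == 0L) {
    warning(sprintf("no path of length <= %d links %s to %s inside the allowed set",
                    max_path_length, drug, disease))
    node_set <- character()
    edge_set <- sub[0, , drop = FALSE]
  } else {
    node_set <- sort(unique(unlist(paths)))
    used <- unique(unlist(lapply(paths, function(p) {
      paste(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]), sep = "\r")
    })))
    ekey <- paste(pmin(sub$source, sub$target), pmax(sub$source, sub$target),
                  sep = "\r")
    edge_set <- sub[ekey %in% used, , drop = FALSE]
    edge_set <- edge_set[!duplicated(paste(pmin(edge_set$source, edge_set$target),
                                           pmax(edge_set$source, edge_set$target),
                                           sep = "\r")), , drop = FALSE]
    rownames(edge_set) <- NULL
  }
  structure(list(drug = drug, disease = disease, allowed_nodes = allowed_nodes,
                 max_path_length = as.integer(max_path_length),
                 paths = paths, nodes = node_set, edges = edge_set),
            class = "mechanism_subgraph")
}

#' @export
print.mechanism_subgraph <- function(x, ...) {
  cat(sprintf("<mechanism_subgraph> %s -> %s: %d path(s), %d nodes, %d edges\n",
              x$drug, x$disease, length(x$paths), length(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Serialise a mechanism subgraph
#'
#' `write_subgraph_json()` emits a graph-JSON document (nodes with types,
#' edges with classes, and the contributing paths); `write_subgraph_dot()`
#' emits Graphviz DOT for rendering.
#'
#' @param subgraph a `mechanism_subgraph`.
#' @param graph the `msi_graph` it came from.
#' @param path output path.
#' @export
write_subgraph_json <- function(subgraph, graph, path) {
  jsonlite::write_json(
    list(drug = subgraph$drug, disease = subgraph$disease,
         nodes = lapply(subgraph$nodes, function(n)
           list(id = n, type = unname(graph$nodes[[n]]))),
         edges = lapply(seq_len(nrow(subgraph$edges)), function(i)
           list(source = subgraph$edges$source[i],
                target = subgraph$edges$target[i],
                class = subgraph$edges$class[i])),
         paths = subgraph$paths),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(subgraph)
}

#' @rdname write_subgraph_json
#' @export
write_subgraph_dot <- function(subgraph, graph, path) {
  lines <- c("graph mechanism {",
             sprintf('  "%s" [type="%s"];', subgraph$nodes,
                     graph$nodes[subgraph$nodes]),
             sprintf('  "%s" -- "%s";', subgraph$edges$source,
                     subgraph$edges$target),
             "}")
  writeLines(lines, path)
  invisible(subgraph)
}
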