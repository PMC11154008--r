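# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: literal double loops and explicit enumerations only.

# KS enrichment: literal evaluation of the two maxima
ks_oracle <- function(tags, ranking) {
  n <- length(ranking)
  t <- length(tags)
  v <- sort(match(tags, ranking))
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - v[j] / n)
    b <- max(b, v[j] / n - (j - 1) / t)
  }
  if (a > b) a else -b
}

# leading edge: tags at or before the argmax of the dominant running deviation
leading_edge_oracle <- function(tags, ranking) {
  n <- length(ranking)
  v <- sort(match(intersect(tags, ranking), ranking))
  t <- length(v)
  if (t == 0L) return(character())
  a <- vapply(seq_len(t), function(j) j / t - v[j] / n, numeric(1))
  b <- vapply(seq_len(t), function(j) v[j] / n - (j - 1) / t, numeric(1))
  if (max(a) > max(b)) ranking[v[1:which.max(a)]]
  else ranking[v[which.max(b):t]]
}

# hypergeometric upper-tail by direct summation of point masses
hyper_tail_oracle <- function(overlap, n_pathway, n_universe, n_query) {
  ks <- overlap:min(n_pathway, n_query)
  sum(stats::dhyper(ks, n_pathway, n_universe - n_pathway, n_query))
}

# AUC by exhaustive positive-negative pair comparison
auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# DWPC by exhaustive enumeration over the raw edge list. Works directly on
# the edge data.frame; never touches the package's adjacency structures.
dwpc_oracle <- function(edges, metapath, source, target, w) {
  step_neighbours <- function(node, ft, rel, tt) {
    out <- c(
      edges$target[edges$source == node & edges$source_type == ft &
                     edges$relation == rel & edges$target_type == tt],
      edges$source[edges$target == node & edges$target_type == ft &
                     edges$relation == rel & edges$source_type == tt])
    out
  }
  L <- length(metapath$relations)
  total <- 0
  recurse <- function(path, prod) {
    step <- length(path)
    if (step == L + 1L) {
      if (path[step] == target) total <<- total + prod
      return()
    }
    ft <- metapath$types[step]
    tt <- metapath$types[step + 1L]
    rel <- metapath$relations[step]
    u <- path[step]
    for (v in step_neighbours(u, ft, rel, tt)) {
      if (v %in% path) next
      d_u <- length(step_neighbours(u, ft, rel, tt))
      d_v <- length(step_neighbours(v, tt, rel, ft))
      recurse(c(path, v), prod * (d_u * d_v)^(-w))
    }
  }
  recurse(source, 1)
  total
}

# all simple paths between two nodes over an undirected edge data.frame,
# with interior nodes restricted to an allowed set
simple_paths_oracle <- function(edges, from, to, allowed, max_len) {
  nb <- function(u) unique(c(edges$target[edges$source == u],
                             edges$source[edges$target == u]))
  found <- list()
  recurse <- function(path) {
    u <- path[length(path)]
    if (u == to) {
      found[[length(found) + 1L]] <<- path
      return()
    }
    if (length(path) > max_len) return()
    for (v in nb(u)) {
      if (v %in% path) next
      if (v != to && !v %in% allowed) next
      recurse(c(path, v))
    }
  }
  recurse(from)
  found
}

# random small typed graph for DWPC oracle comparisons
random_small_hetnet <- function(n_nodes = 8L) {
  types <- c("DRUG", "GENE", "DISEASE")
  repeat {
    ty <- c("DRUG", "DISEASE", sample(types, n_nodes - 2L, replace = TRUE))
    ids <- sprintf("n%02d", seq_len(n_nodes))
    rel_for <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "~")
      switch(key,
             "DRUG~GENE" = "targets", "DISEASE~GENE" = "associates",
             "GENE~GENE" = "interacts", "DISEASE~DRUG" = "treats",
             "DRUG~DRUG" = NA_character_, "DISEASE~DISEASE" = NA_character_)
    }
    cand <- utils::combn(n_nodes, 2L)
    keep <- sample(ncol(cand), min(ncol(cand), n_nodes + sample(2:6, 1)))
    rows <- lapply(keep, function(k) {
      i <- cand[1, k]; j <- cand[2, k]
      rel <- rel_for(ty[i], ty[j])
      if (is.na(rel)) return(NULL)
      data.frame(source = ids[i], source_type = ty[i], relation = rel,
                 target = ids[j], target_type = ty[j],
                 stringsAsFactors = FALSE)
    })
    e <- do.call(rbind, rows)
    if (!is.null(e) && nrow(e) >= 3L &&
        ids[1] %in% c(e$source, e$target) &&
        ids[2] %in% c(e$source, e$target)) {
      return(list(edges = e, drug = ids[1], disease = ids[2]))
    }
  }
}

# 20-gene, 4-drug library fixture used across DGEM tests
tiny_library <- function() {
  genes <- sprintf("g%02d", 1:20)
  perms <- list(
    top_up = c(1:20),                       # identity: g01..g20
    reversed = c(20:1),                     # g01 ranked last
    d3 = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14, 13, 16, 15, 18, 17, 20, 19),
    d4 = c(11:20, 1:10))
  m <- vapply(perms, function(p) as.integer(p), integer(20))
  rownames(m) <- genes
  colnames(m) <- paste0(names(perms), "_c1")
  meta <- data.frame(instance = colnames(m),
                     drug_id = names(perms),
                     cell_context = "cellA", concentration = 1,
                     stringsAsFactors = FALSE)
  signature_library(m, meta)
}

tiny_signature <- function(up = sprintf("g%02d", 1:3),
                           down = sprintf("g%02d", 18:20)) {
  structure(list(contrast_id = "tiny", config = signature_config("split", 3, 3),
                 up_genes = up, down_genes = down,
                 direction = stats::setNames(
                   rep(c("up", "down"), c(length(up), length(down))),
                   c(up, down))),
            class = "disease_signature")
}

# drug - protein - disease path graph
path3 <- function() {
  msi_graph(data.frame(
    source = c("dr", "p1"), source_type = c("drug", "protein"),
    target = c("p1", "di"), target_type = c("protein", "disease"),
    stringsAsFactors = FALSE))
}

# random interactome around a "dr" drug and "di" disease query pair
random_msi <- function(n_prot = 20, n_fun = 8) {
  prot <- sprintf("p%02d", 1:n_prot)
  fun <- sprintf("f%02d", 1:n_fun)
  e <- rbind(
    data.frame(source = "dr", source_type = "drug",
               target = sample(prot, 3), target_type = "protein"),
    data.frame(source = "di", source_type = "disease",
               target = sample(prot, 3), target_type = "protein"),
    data.frame(source = sample(prot, 2 * n_prot, TRUE), source_type = "protein",
               target = sample(prot, 2 * n_prot, TRUE), target_type = "protein"),
    data.frame(source = sample(prot, n_prot, TRUE), source_type = "protein",
               target = sample(fun, n_prot, TRUE),
               target_type = "biological_function"),
    data.frame(source = sample(fun, n_fun, TRUE),
               source_type = "biological_function",
               target = sample(fun, n_fun, TRUE),
               target_type = "biological_function"))
  e <- e[e$source != e$target, , drop = FALSE]
  key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
  msi_graph(e[!duplicated(key), , drop = FALSE])
}
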