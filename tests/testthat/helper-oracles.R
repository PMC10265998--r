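# Independent brute-force oracles and small fixture builders used across
# the suite. Each oracle is deliberately naive (enumeration / per-element
# loops / a different library) so it shares no code path with the
# implementation it checks.

# Exact two-sample KS p-value by full enumeration of all label
# assignments of the pooled (tie-free) sample.
ks_perm_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- sort(c(a, b))
  d_of <- function(idx_a) {
    la <- seq_len(n + m) %in% idx_a
    max(abs(cumsum(la) / n - cumsum(!la) / m))
  }
  obs <- d_of(which(pooled %in% a))
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2, d_of)
  mean(ds >= obs - 1e-12)
}

# Brute-force nearest-station assignment: per-cell loop over stations
# with strict-< comparison on id-sorted stations (ties keep the first,
# i.e. smallest station_id).
zones_oracle <- function(cells, stations) {
  st <- stations[order(stations$station_id), ]
  vapply(seq_len(nrow(cells)), function(i) {
    d <- sqrt((cells$x_m[i] - st$x_m)^2 + (cells$y_m[i] - st$y_m)^2)
    best <- 1L
    for (j in seq_along(d)) if (d[j] < d[best]) best <- j
    st$station_id[best]
  }, character(1))
}

# Random DAG on a shuffled node order: edges only forward along the
# permutation, so acyclicity is guaranteed by construction.
random_dag <- function(n_nodes, p_edge = 0.4, p_ce = 0.15) {
  nodes <- sample(paste0("v", seq_len(n_nodes)))
  edges <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      if (runif(1) < p_edge) edges[[length(edges) + 1]] <- c(nodes[i], nodes[j])
    }
  }
  if (length(edges) == 0) edges[[1]] <- c(nodes[1], nodes[2])
  em <- do.call(rbind, edges)
  ce <- list()
  for (i in seq_len(n_nodes - 1)) {
    for (j in seq(i + 1, n_nodes)) {
      adj <- any(em[, 1] == nodes[i] & em[, 2] == nodes[j]) ||
        any(em[, 1] == nodes[j] & em[, 2] == nodes[i])
      if (!adj && runif(1) < p_ce) ce[[length(ce) + 1]] <- c(nodes[i], nodes[j])
    }
  }
  causal_graph(em, correlated_errors = ce, group = "site")
}

# Basis-set oracle built on igraph: enumerate all unordered node pairs,
# keep the non-adjacent, non-correlated, not-both-exogenous ones, and
# condition on the union of both nodes' igraph-derived parents.
basis_oracle <- function(graph) {
  ig <- igraph::graph_from_edgelist(as.matrix(graph$edges), directed = TRUE)
  missing <- setdiff(graph$nodes, igraph::V(ig)$name)
  if (length(missing) > 0) ig <- igraph::add_vertices(ig, length(missing),
                                                      name = missing)
  stopifnot(igraph::is_dag(ig))
  parents <- function(v) {
    sort(names(igraph::neighbors(ig, v, mode = "in")))
  }
  endo <- unique(graph$edges$to)
  ce_key <- if (nrow(graph$correlated_errors) > 0) {
    apply(graph$correlated_errors, 1, function(p) paste(sort(p), collapse = "|"))
  } else {
    character(0)
  }
  nodes <- sort(graph$nodes)
  out <- list()
  for (i in seq_len(length(nodes) - 1)) {
    for (j in seq(i + 1, length(nodes))) {
      a <- nodes[i]; b <- nodes[j]
      if (igraph::are_adjacent(ig, a, b) ||
          igraph::are_adjacent(ig, b, a)) next
      if (paste(sort(c(a, b)), collapse = "|") %in% ce_key) next
      if (!(a %in% endo) && !(b %in% endo)) next
      out[[length(out) + 1]] <- list(
        pair = sort(c(a, b)),
        conditioning = setdiff(sort(union(parents(a), parents(b))), c(a, b))
      )
    }
  }
  out
}

# Key a claim set on unordered pair + conditioning for oracle comparison.
claim_keys <- function(pairs, conditionings) {
  sort(vapply(seq_along(pairs), function(i) {
    paste(paste(sort(pairs[[i]]), collapse = "|"),
          paste(conditionings[[i]], collapse = ","), sep = "::")
  }, character(1)))
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
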