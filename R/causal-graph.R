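# Directed-acyclic causal graph specification: nodes, directed edges,
# correlated-error pairs, lag-interaction declarations and the grouping
# variable shared by every local equation.

#' Construct a causal graph for piecewise SEM
#'
#' The graph lists directed causal paths among observed variables.
#' Nodes with at least one incoming edge are endogenous (each gets one
#' mixed-model equation); the rest are exogenous. Correlated-error pairs
#' assert dependence without direction and are excluded from
#' independence testing. Lag interactions declare drivers whose effect
#' on a target is moderated by the previous year's scaled cover.
#'
#' @param edges Two-column matrix/data frame (from, to) or list of
#'   length-2 character vectors.
#' @param correlated_errors List of unordered node pairs (length-2
#'   character vectors).
#' @param lag_interactions Named list: for each target node, the drivers
#'   whose effect interacts with the previous-year cover variable.
#' @param group Name of the grouping (site) variable.
#' @param order Optional character vector giving a partial causal /
#'   temporal ordering used to refine the topological order.
#' @param lag_variable Name of the previous-year scaled cover column
#'   used in interaction terms (default `"prev_cover"`).
#' @param nodes Optional explicit node set (defaults to every name
#'   appearing in `edges`).
#' @return A validated object of class `causal_graph` with the computed
#'   topological order.
#' @examples
#' g <- causal_graph(rbind(c("A", "B"), c("B", "C")), group = "site")
#' basis_set(g)
#' @export
causal_graph <- function(edges, correlated_errors = list(),
                         lag_interactions = list(), group = "site_id",
                         order = NULL, lag_variable = "prev_cover",
                         nodes = NULL) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  }
  edges <- as.matrix(edges)
  if (length(edges) > 0 && ncol(edges) != 2) {
    stop("edges must have two columns (from, to)", call. = FALSE)
  }
  ed <- tibble(from = as.character(edges[, 1]), to = as.character(edges[, 2]))
  ce <- tibble(a = character(0), b = character(0))
  if (length(correlated_errors) > 0) {
    ce <- purrr::map_dfr(correlated_errors, function(p) {
      stopifnot(length(p) == 2)
      tibble(a = as.character(p[1]), b = as.character(p[2]))
    })
  }
  nodes <- sort(unique(c(nodes, ed$from, ed$to, ce$a, ce$b)))
  g <- structure(list(
    nodes = nodes, edges = ed, correlated_errors = ce,
    lag_interactions = lag_interactions, group = group, order = order,
    lag_variable = lag_variable
  ), class = "causal_graph")
  validate_graph(g)
}

graph_parents <- function(graph, node) {
  sort(graph$edges$from[graph$edges$to == node])
}

graph_adjacent <- function(graph, a, b) {
  any(graph$edges$from == a & graph$edges$to == b) ||
    any(graph$edges$from == b & graph$edges$to == a)
}

graph_roles <- function(graph) {
  setNames(ifelse(graph$nodes %in% graph$edges$to, "endogenous", "exogenous"),
           graph$nodes)
}

# Kahn topological sort; among simultaneously available nodes, prefer the
# declared partial order, then alphabetical -- fully deterministic.
topological_order <- function(graph) {
  nodes <- graph$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  for (to in graph$edges$to) indeg[to] <- indeg[to] + 1L
  rank <- setNames(rep(Inf, length(nodes)), nodes)
  if (!is.null(graph$order)) {
    rank[intersect(graph$order, nodes)] <-
      match(intersect(graph$order, nodes), graph$order)
  }
  out <- character(0)
  remaining <- nodes
  while (length(remaining) > 0) {
    avail <- remaining[indeg[remaining] == 0L]
    if (length(avail) == 0) {
      cyc <- find_cycle(graph, remaining)
      stop("causal graph contains a cycle: ",
           paste(cyc, collapse = " -> "), call. = FALSE)
    }
    nxt <- avail[order(rank[avail], avail)][1]
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- graph$edges$to[graph$edges$from == nxt]
    indeg[ch] <- indeg[ch] - 1L
  }
  out
}

find_cycle <- function(graph, nodes) {
  # walk forward from any remaining node until a node repeats
  cur <- nodes[1]
  path <- cur
  repeat {
    nxt <- graph$edges$to[graph$edges$from == cur & graph$edges$to %in% nodes]
    if (length(nxt) == 0) return(path)
    cur <- nxt[1]
    if (cur %in% path) {
      return(c(path[which(path == cur):length(path)], cur))
    }
    path <- c(path, cur)
  }
}

#' Validate a causal graph
#'
#' Asserts acyclicity (a topological sort exists), that correlated-error
#' pairs are not also directed edges, and that every declared lag
#' interaction refers to an existing edge into its target. The returned
#' graph carries the computed topological order (refined by any declared
#' partial order) and node roles.
#'
#' @param graph A `causal_graph`.
#' @return The graph, with `$topo_order` and `$roles` filled in.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  if (anyDuplicated(graph$edges)) stop("duplicate edges", call. = FALSE)
  if (any(graph$edges$from == graph$edges$to)) {
    stop("self-loop edge", call. = FALSE)
  }
  graph$topo_order <- topological_order(graph)
  graph$roles <- graph_roles(graph)
  if (nrow(graph$correlated_errors) > 0) {
    for (i in seq_len(nrow(graph$correlated_errors))) {
      a <- graph$correlated_errors$a[i]
      b <- graph$correlated_errors$b[i]
      if (graph_adjacent(graph, a, b)) {
        stop("correlated-error pair (", a, ", ", b,
             ") is also a directed edge", call. = FALSE)
      }
    }
  }
  for (target in names(graph$lag_interactions)) {
    for (drv in graph$lag_interactions[[target]]) {
      if (!any(graph$edges$from == drv & graph$edges$to == target)) {
        stop("lag interaction ", drv, " x previous-year cover declared for '",
             target, "' but ", drv, " -> ", target, " is not an edge",
             call. = FALSE)
      }
    }
  }
  graph
}

#' @export
print.causal_graph <- function(x, ...) {
  x <- validate_graph(x)
  cat("Causal graph:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$correlated_errors), "correlated-error pair(s)\n")
  cat("  order:", paste(x$topo_order, collapse = " < "), "\n")
  endo <- names(x$roles)[x$roles == "endogenous"]
  for (e in endo) {
    cat("  ", e, "~", paste(graph_parents(x, e), collapse = " + "), "\n")
  }
  invisible(x)
}

#' Read a causal graph from a JSON specification
#'
#' Schema: `{"nodes": [...], "edges": [[src, dst], ...],
#' "correlated_errors": [[a, b], ...], "lag_interactions":
#' {target: [drivers]}, "group": name, "order": [...],
#' "lag_variable": name}`. Only `edges` is mandatory.
#'
#' @param path Path to the JSON file.
#' @return A validated `causal_graph`.
#' @export
read_causal_graph <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyMatrix = TRUE)
  if (is.null(spec$edges)) stop("graph spec has no edges", call. = FALSE)
  edges <- spec$edges
  if (is.list(edges)) edges <- do.call(rbind, edges)
  ce <- spec$correlated_errors
  if (!is.null(ce) && is.matrix(ce)) ce <- asplit(ce, 1)
  li <- spec$lag_interactions
  if (!is.null(li)) li <- lapply(li, as.character)
  causal_graph(
    edges = edges, correlated_errors = ce %||% list(),
    lag_interactions = li %||% list(),
    group = spec$group %||% "site_id", order = spec$order,
    lag_variable = spec$lag_variable %||% "prev_cover",
    nodes = spec$nodes
  )
}

#' Write a causal graph to its JSON representation
#'
#' @param graph A `causal_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_causal_graph <- function(graph, path) {
  stopifnot(inherits(graph, "causal_graph"))
  spec <- list(
    nodes = graph$nodes,
    edges = unname(apply(as.matrix(graph$edges), 1, identity, simplify = FALSE)),
    correlated_errors = unname(apply(as.matrix(graph$correlated_errors), 1,
                                     identity, simplify = FALSE)),
    lag_interactions = graph$lag_interactions,
    group = graph$group, order = graph$order,
    lag_variable = graph$lag_variable
  )
  jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' d-separation basis set of a causal graph
#'
#' One independence claim per unordered pair of non-adjacent nodes that
#' is not a correlated-error pair, excluding pairs of two exogenous
#' nodes (their joint distribution is unmodeled). The claim's response
#' is the endogenous member, or the later node in the causal order when
#' both are endogenous; the conditioning set is the union of both
#' nodes' direct parents (excluding the pair themselves).
#'
#' @param graph A validated `causal_graph`.
#' @return Tibble with columns `indep`, `response`, `conditioning`
#'   (list-column of character vectors), sorted by (`response`,
#'   `indep`). Empty for a saturated model.
#' @export
basis_set <- function(graph) {
  graph <- validate_graph(graph)
  nodes <- graph$topo_order
  roles <- graph$roles
  ce_key <- character(0)
  if (nrow(graph$correlated_errors) > 0) {
    ce_key <- apply(graph$correlated_errors, 1,
                    function(p) paste(sort(p), collapse = "\r"))
  }
  claims <- list()
  if (length(nodes) >= 2) {
    for (i in seq_len(length(nodes) - 1L)) {
      for (j in seq((i + 1L), length(nodes))) {
        a <- nodes[i]; b <- nodes[j] # a earlier in causal order
        if (graph_adjacent(graph, a, b)) next
        if (paste(sort(c(a, b)), collapse = "\r") %in% ce_key) next
        if (roles[a] == "exogenous" && roles[b] == "exogenous") next
        # response: the endogenous member, else the later node
        if (roles[b] == "endogenous") { resp <- b; indep <- a }
        else { resp <- a; indep <- b }
        cond <- setdiff(sort(union(graph_parents(graph, a),
                                   graph_parents(graph, b))), c(a, b))
        claims[[length(claims) + 1L]] <-
          tibble(indep = indep, response = resp, conditioning = list(cond))
      }
    }
  }
  if (length(claims) == 0) {
    return(tibble(indep = character(0), response = character(0),
                  conditioning = list()))
  }
  bind_rows(claims) |> arrange(.data$response, .data$indep)
}
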