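#' Build the directed spacer-pair graph
#'
#' Each node is a spacer cluster; a directed edge u -> v with weight w
#' records that the ordered neighbouring-spacer pair (u, v) was observed w
#' times in reads. Self-loops are kept but flagged.
#'
#' @param pairs Data frame with columns `first` and `second` (cluster
#'   ids), one row per observed pair.
#' @param nodes Optional additional node ids (e.g. clusters observed only
#'   singly).
#' @return Object of class `pair_graph`: list with `nodes` (character)
#'   and `edges` (`from`, `to`, `weight`, `self_loop`).
#' @export
build_pair_graph <- function(pairs, nodes = NULL) {
  stopifnot(all(c("first", "second") %in% names(pairs)))
  if (nrow(pairs)) {
    key <- paste(pairs$first, pairs$second, sep = "\r")
    tab <- table(key)
    ft <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(ft, `[`, character(1), 1L),
      to = vapply(ft, `[`, character(1), 2L),
      weight = as.integer(tab)
    )
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = integer(0))
  }
  edges$self_loop <- edges$from == edges$to
  all_nodes <- sort(unique(c(edges$from, edges$to, nodes)))
  structure(list(nodes = all_nodes, edges = edges), class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  cat("Spacer pair graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (total weight",
      sum(x$edges$weight), ")\n")
  invisible(x)
}

#' Remove putative chimeric edges by the 5% weight rule
#'
#' For each edge (u, v) the sum of outgoing weights of u (`s_out`) and the
#' sum of incoming weights of v (`s_in`) are computed from the unfiltered
#' graph (single pass). Under `mode = "either"` (default) the edge is
#' removed when its weight is below `fraction` of either sum; under
#' `mode = "both"` it must be below the threshold against both sums.
#'
#' Rare PCR template-switch artifacts connect spacers from different
#' arrays with low weight relative to the true adjacency evidence at
#' either endpoint; the disjunctive default also catches chimeras whose
#' head carries no other incoming evidence (the first spacer of an array,
#' or a mini-array spacer), which the conjunctive variant can never
#' remove. A genuine sole edge of a rare array is ~100% of both of its
#' endpoint sums and is retained under either mode.
#'
#' @param graph A [build_pair_graph()] result.
#' @param fraction Weight fraction threshold (default 0.05).
#' @param mode `"either"` or `"both"` (see details).
#' @return List with `graph` (filtered `pair_graph`, same node set) and
#'   `report` (all edges with `s_out`, `s_in`, `removed`, `reason`).
#' @export
filter_chimeric_edges <- function(graph, fraction = 0.05,
                                  mode = c("either", "both")) {
  stopifnot(inherits(graph, "pair_graph"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  mode <- match.arg(mode)
  e <- graph$edges
  if (nrow(e) == 0) {
    return(list(graph = graph,
                report = cbind(e, s_out = numeric(0), s_in = numeric(0),
                               removed = logical(0),
                               reason = character(0))))
  }
  s_out <- tapply(e$weight, e$from, sum)
  s_in <- tapply(e$weight, e$to, sum)
  e$s_out <- as.numeric(s_out[e$from])
  e$s_in <- as.numeric(s_in[e$to])
  below_out <- e$weight < fraction * e$s_out
  below_in <- e$weight < fraction * e$s_in
  removed <- if (mode == "either") below_out | below_in else
    below_out & below_in
  reason <- rep("kept", nrow(e))
  reason[removed & below_out & below_in] <- "below_both_sums"
  reason[removed & below_out & !below_in] <- "below_outgoing_sum"
  reason[removed & !below_out & below_in] <- "below_incoming_sum"
  e$removed <- removed
  e$reason <- reason
  kept <- e[!removed, c("from", "to", "weight", "self_loop")]
  rownames(kept) <- NULL
  list(
    graph = structure(list(nodes = graph$nodes, edges = kept),
                      class = "pair_graph"),
    report = e
  )
}

# adjacency list representation keyed by node index
.adj_list <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  out <- vector("list", length(nodes))
  if (nrow(edges)) {
    by_from <- split(seq_len(nrow(edges)), edges$from)
    for (f in names(by_from)) out[[idx[[f]]]] <- by_from[[f]]
  }
  out
}

# find one directed cycle (as a vector of edge-row indices), or NULL
.find_cycle <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  out_edges <- .adj_list(nodes, edges)
  color <- integer(length(nodes))  # 0 white, 1 grey, 2 black
  path_nodes <- integer(0)         # current DFS path (node indices)
  path_edges <- integer(0)         # path_edges[s]: edge node s -> s+1
  result <- NULL
  dfs <- function(v) {
    color[v] <<- 1L
    path_nodes <<- c(path_nodes, v)
    for (ei in out_edges[[v]]) {
      if (!is.null(result)) break
      w <- idx[[edges$to[ei]]]
      if (color[w] == 1L) {
        pos <- match(w, path_nodes)
        cyc <- if (pos < length(path_nodes)) {
          path_edges[pos:(length(path_nodes) - 1L)]
        } else integer(0)
        result <<- c(cyc, ei)
      } else if (color[w] == 0L) {
        path_edges <<- c(path_edges, ei)
        dfs(w)
        path_edges <<- path_edges[-length(path_edges)]
      }
    }
    color[v] <<- 2L
    path_nodes <<- path_nodes[-length(path_nodes)]
  }
  for (v in seq_along(nodes)) {
    if (!is.null(result)) break
    if (color[v] == 0L) dfs(v)
  }
  result
}

# iteratively break cycles at the minimum-weight edge of a detected cycle
# (deterministic tie-break: lexicographic from, then to); returns edges
# with cycle edges dropped plus a log of removals
.break_cycles <- function(nodes, edges) {
  removed_log <- edges[0, , drop = FALSE]
  if (any(edges$self_loop)) {  # one-node cycles
    removed_log <- rbind(removed_log, edges[edges$self_loop, ])
    edges <- edges[!edges$self_loop, , drop = FALSE]
  }
  repeat {
    cyc <- .find_cycle(nodes, edges)
    if (is.null(cyc)) break
    ce <- edges[cyc, , drop = FALSE]
    pick <- cyc[order(ce$weight, ce$from, ce$to)][1L]
    removed_log <- rbind(removed_log, edges[pick, ])
    edges <- edges[-pick, , drop = FALSE]
  }
  rownames(edges) <- NULL
  rownames(removed_log) <- NULL
  list(edges = edges, removed = removed_log)
}

# Kahn topological order of a DAG given as an edge table
.topo_order <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  indeg <- integer(length(nodes))
  if (nrow(edges)) {
    t <- table(factor(edges$to, levels = nodes))
    indeg <- as.integer(t)
  }
  out_edges <- .adj_list(nodes, edges)
  queue <- which(indeg == 0L)
  order_out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ei in out_edges[[v]]) {
      w <- idx[[edges$to[ei]]]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order_out) != length(nodes)) stop("graph is not acyclic")
  order_out
}

#' Reconstruct CRISPR array paths from the filtered pair graph
#'
#' Breaks any cycles (expected only from noise) at the minimum-weight edge
#' of each cycle, then enumerates every maximal path from a source node
#' (in-degree 0) to a sink node (out-degree 0). At branch points all
#' branches are reported; isolated nodes yield single-spacer paths.
#'
#' @param graph A (typically chimera-filtered) `pair_graph`.
#' @param max_paths Safety cap on the number of reported paths.
#' @return Object of class `array_paths`: list with `paths` (list of
#'   cluster-id vectors), `summary` (`path_id`, `component_id`, `length`,
#'   `min_weight`), `components` (node -> component id) and
#'   `cycle_edges_removed`.
#' @export
reconstruct_paths <- function(graph, max_paths = 1e5) {
  stopifnot(inherits(graph, "pair_graph"))
  nodes <- graph$nodes
  br <- .break_cycles(nodes, graph$edges)
  edges <- br$edges

  ig <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  comp <- igraph::components(ig, mode = "weak")$membership
  components <- stats::setNames(as.integer(comp), nodes)

  idx <- stats::setNames(seq_along(nodes), nodes)
  out_edges <- .adj_list(nodes, edges)
  indeg <- as.integer(table(factor(edges$to, levels = nodes)))
  sources <- which(indeg == 0L)

  wmap <- stats::setNames(edges$weight,
                          paste(edges$from, edges$to, sep = "\r"))
  paths <- list()
  walk <- function(v, acc) {
    es <- out_edges[[v]]
    if (length(es) == 0L) {
      if (length(paths) >= max_paths) {
        stop("more than max_paths maximal paths; raise max_paths")
      }
      paths[[length(paths) + 1L]] <<- c(acc, nodes[v])
      return(invisible())
    }
    for (ei in es) walk(idx[[edges$to[ei]]], c(acc, nodes[v]))
  }
  for (s in sources) walk(s, character(0))

  min_w <- vapply(paths, function(p) {
    if (length(p) < 2) return(NA_integer_)
    min(wmap[paste(p[-length(p)], p[-1], sep = "\r")])
  }, integer(1))
  structure(list(
    paths = paths,
    summary = data.frame(
      path_id = seq_along(paths),
      component_id = vapply(paths, function(p) components[[p[1]]],
                            integer(1)),
      length = lengths(paths),
      min_weight = min_w
    ),
    components = components,
    cycle_edges_removed = br$removed,
    edges = edges
  ), class = "array_paths")
}

#' @export
print.array_paths <- function(x, ...) {
  cat("Reconstructed CRISPR array paths\n")
  cat(sprintf("  paths: %d  (longest: %d spacers)\n", length(x$paths),
              if (length(x$paths)) max(lengths(x$paths)) else 0L))
  cat(sprintf("  components: %d\n", length(unique(x$components))))
  if (nrow(x$cycle_edges_removed)) {
    cat(sprintf("  cycle edges removed: %d\n",
                nrow(x$cycle_edges_removed)))
  }
  invisible(x)
}

#' Node eccentricity: spacers on the longest path through each node
#'
#' For every node v, the number of spacers on the longest reconstructable
#' array passing through v: `longest_in(v) + longest_out(v) + 1`, computed
#' by dynamic programming over the DAG (cycles broken as in
#' [reconstruct_paths()]). Mini-CRISPR array candidates are screened by
#' eccentricity <= 2, since a spacer embedded in a long array lies on a
#' long path.
#'
#' @param graph A `pair_graph`.
#' @return Data frame (`cluster_id`, `eccentricity`); isolated nodes have
#'   eccentricity 1.
#' @export
node_eccentricity <- function(graph) {
  stopifnot(inherits(graph, "pair_graph"))
  nodes <- graph$nodes
  edges <- .break_cycles(nodes, graph$edges)$edges
  n <- length(nodes)
  ord <- .topo_order(nodes, edges)
  idx <- stats::setNames(seq_along(nodes), nodes)
  ef <- idx[edges$from]; et <- idx[edges$to]
  lin <- integer(n); lout <- integer(n)
  for (v in ord) {           # edges arrive from already-finalised nodes
    inc <- which(et == v)
    if (length(inc)) lin[v] <- 1L + max(lin[ef[inc]])
  }
  for (v in rev(ord)) {
    out <- which(ef == v)
    if (length(out)) lout[v] <- 1L + max(lout[et[out]])
  }
  data.frame(cluster_id = nodes, eccentricity = lin + lout + 1L)
}

#' Group graph components by correlated abundance profiles
#'
#' Genomes usually carry several CRISPR arrays with the same repeat, so
#' one strain contributes several graph components whose spacer
#' frequencies co-vary across samples. Components are grouped by
#' single-linkage at a Pearson correlation threshold on mean
#' log10(count + 1) abundance profiles.
#'
#' @param abundance Matrix of cluster counts (rows = cluster ids, columns
#'   = samples; at least 2 samples).
#' @param components Named vector mapping cluster id -> component id.
#' @param r_threshold Pearson correlation threshold (default 0.9).
#' @return List with `groups` (`component_id`, `group_id`), `profiles`
#'   (component x sample matrix) and `correlation` matrix.
#' @export
correlate_components <- function(abundance, components, r_threshold = 0.9) {
  if (ncol(abundance) < 2) stop("need at least 2 samples")
  comp <- components[rownames(abundance)]
  if (anyNA(comp)) stop("components must cover all abundance rows")
  lg <- log10(abundance + 1)
  comp_ids <- sort(unique(comp))
  profiles <- t(vapply(comp_ids, function(cid) {
    colMeans(lg[comp == cid, , drop = FALSE])
  }, numeric(ncol(abundance))))
  rownames(profiles) <- comp_ids
  if (length(comp_ids) == 1L) {
    return(list(groups = data.frame(component_id = comp_ids, group_id = 1L),
                profiles = profiles,
                correlation = matrix(1, 1, 1,
                                     dimnames = list(comp_ids, comp_ids))))
  }
  R <- suppressWarnings(stats::cor(t(profiles)))
  R[is.na(R)] <- 0
  adj <- R >= r_threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  grp <- igraph::components(g)$membership
  list(
    groups = data.frame(component_id = comp_ids,
                        group_id = as.integer(grp)),
    profiles = profiles,
    correlation = R
  )
}
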