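#' Shortest capillary loops through every vertex
#'
#' For every root vertex and every unordered pair of its neighbours, the
#' length-weighted shortest path between the pair that avoids the root is
#' computed (Dijkstra on the graph with the root's incident edges removed)
#' and closed through the root's two edges. Each loop is identified once per
#' member vertex; repetitions are removed by reduction to a canonical cyclic
#' form (lowest vertex first, lexicographically smaller direction).
#'
#' @param net a [vascular_network()].
#' @param weighted weight edges by their length (the practical choice);
#'   `FALSE` uses unit weights.
#' @return object of class `loop_set`: `loops` (list of cyclic vertex
#'   sequences, closure vertex not repeated), `lengths` (total loop length,
#'   um), `n_edges` (edges per loop), `edge_count` (per-network-edge count of
#'   loops containing it).
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0))
#' tri <- vascular_network(v, rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L)))
#' find_shortest_loops(tri)
#' @export
find_shortest_loops <- function(net, weighted = TRUE) {
  E <- net$edges
  n <- nrow(net$vertices)
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  w <- if (weighted) net$length else rep(1, nrow(E))
  igraph::E(g)$weight <- w
  igraph::E(g)$eid <- seq_len(nrow(E))

  seen <- new.env(hash = TRUE, parent = emptyenv())
  loops <- list(); nl <- 0L
  for (v in seq_len(n)) {
    inc <- igraph::incident(g, v)
    nbrs <- unique(setdiff(as.integer(igraph::ends(g, inc)), v))
    if (length(nbrs) < 2L) next
    gv <- igraph::delete_edges(g, inc)
    for (a in seq_along(nbrs)[-length(nbrs)]) {
      # distances+paths from one neighbour to the later ones, root removed
      sp <- suppressWarnings(igraph::shortest_paths(
        gv, from = nbrs[a], to = nbrs[(a + 1):length(nbrs)],
        weights = igraph::E(gv)$weight, output = "vpath"))
      for (k in seq_along(sp$vpath)) {
        path <- as.integer(sp$vpath[[k]])
        if (length(path) < 2L) next  # unreachable without the root
        cyc <- c(v, path)
        key <- .canonical_cycle_key(cyc)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        nl <- nl + 1L
        loops[[nl]] <- cyc
      }
    }
  }
  ekey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  edge_count <- rep(0L, nrow(E))
  lens <- numeric(nl); nedges <- integer(nl)
  elen <- net$length
  lookup <- stats::setNames(seq_len(nrow(E)), ekey)
  for (i in seq_len(nl)) {
    cyc <- loops[[i]]
    a <- cyc; b <- c(cyc[-1], cyc[1])
    ids <- lookup[paste(pmin(a, b), pmax(a, b))]
    nedges[i] <- length(cyc)
    lens[i] <- sum(elen[ids])
    edge_count[ids] <- edge_count[ids] + 1L
  }
  structure(list(loops = loops, lengths = lens, n_edges = nedges,
                 edge_count = edge_count),
            class = "loop_set")
}

.canonical_cycle_key <- function(cyc) {
  m <- length(cyc)
  i <- which.min(cyc)
  fwd <- cyc[((seq_len(m) + i - 2L) %% m) + 1L]
  rev_ <- c(fwd[1], rev(fwd[-1]))
  key <- if (paste(fwd, collapse = ",") <= paste(rev_, collapse = ","))
    fwd else rev_
  paste(key, collapse = ",")
}

#' @exportS3Method base::print
print.loop_set <- function(x, ...) {
  cat("Loop set:", length(x$loops), "unique shortest loops\n")
  if (length(x$loops))
    cat(sprintf("  mean edges/loop %.2f, mean loop length %.1f um\n",
                mean(x$n_edges), mean(x$lengths)))
  invisible(x)
}

#' Loop-topology statistics
#'
#' Mean edges per loop, mean loop length, mean loops per edge, and the
#' percentage of interior vertices with more than three connections. The
#' loops-per-edge mean is taken over the edges participating in at least one
#' loop: in a cropped region a substantial fraction of edges end in boundary
#' stubs and can never lie on a cycle of the cropped graph, so they carry no
#' topological information (the all-edge mean is reported alongside).
#'
#' @param loops a `loop_set` from [find_shortest_loops()].
#' @param net the corresponding [vascular_network()].
#' @return list with `mean_edges_per_loop`, `mean_loop_length`,
#'   `mean_loops_per_edge` (participating edges),
#'   `mean_loops_per_edge_all` (all edges), `multiply_connected_pct`,
#'   `n_loops`.
#' @export
loop_statistics <- function(loops, net) {
  lab <- classify_vertices(net)
  deg <- vertex_degrees(net)
  interior <- lab$class == "interior"
  mc <- if (any(interior)) 100 * mean(deg[interior] > 3L) else NA_real_
  if (!length(loops$loops)) {
    warning("empty loop set")
    return(list(mean_edges_per_loop = 0, mean_loop_length = 0,
                mean_loops_per_edge = 0, mean_loops_per_edge_all = 0,
                multiply_connected_pct = mc, n_loops = 0L))
  }
  part <- loops$edge_count > 0
  list(mean_edges_per_loop = mean(loops$n_edges),
       mean_loop_length = mean(loops$lengths),
       mean_loops_per_edge = mean(loops$edge_count[part]),
       mean_loops_per_edge_all = mean(loops$edge_count),
       multiply_connected_pct = mc,
       n_loops = length(loops$loops))
}
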