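# Fixture graphs built in code, and a session cache for generated ensembles
# so that several test files can share the same networks.

.capnet_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.capnet_cache[[key]])) .capnet_cache[[key]] <- force(expr)
  .capnet_cache[[key]]
}

s75_config <- function(seed = 1) {
  generation_config(lc = 75, domain = c(240, 240, 240), seed = seed)
}

s75_network <- function(seed = 1) {
  cached(paste0("s75_", seed), generate_network(s75_config(seed)))
}

s75_ensemble <- function(n = 10) {
  cached(paste0("s75_ens_", n), generate_ensemble(s75_config(1), n))
}

converged_ensemble <- function(n = 10, size = 9) {
  cached(paste0("conv_ens_", n, "_", size), {
    cfg <- generation_config(lc = 75, domain = rep(size * 75, 3), seed = 1)
    generate_ensemble(cfg, n)
  })
}

# the worked toy graph: three loops around root vertex 1
toy_loop_graph <- function() {
  v <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, -1, 0), c(2, -1, 0), c(2, 0, 0),
             c(3, 1, 0), c(3, 0, 0), c(2, 2, 0))
  e <- rbind(c(1, 2), c(1, 3), c(1, 5), c(3, 4), c(4, 5), c(5, 7), c(7, 6),
             c(6, 2), c(2, 8), c(8, 3))
  vascular_network(v, e, domain = rbind(c(-1, -2, -1), c(4, 3, 1)))
}

triangle_graph <- function() {
  v <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0))
  vascular_network(v, rbind(c(1, 2), c(2, 3), c(1, 3)),
                   domain = rbind(c(-1, -1, -1), c(11, 9, 1)))
}

cube_graph <- function() {
  v <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  e <- list()
  for (a in 1:7) for (b in (a + 1):8)
    if (sum(v[a, ] != v[b, ]) == 1) e[[length(e) + 1]] <- c(a, b)
  vascular_network(v, do.call(rbind, e),
                   domain = rbind(c(-1, -1, -1), c(11, 11, 11)))
}

# small random connected 3-regular graph with random spatial positions, so
# edge lengths are continuous (no shortest-path ties) and the exhaustive
# path enumeration in the oracle stays tractable
random_small_graph <- function(n = 14, seed = 7) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_k_regular(n, 3)
    if (igraph::is_connected(g) && !igraph::any_multiple(g) &&
        !any(igraph::which_loop(g))) break
  }
  v <- matrix(runif(3 * n, 0, 100), n, 3)
  e <- igraph::as_edgelist(g)
  vascular_network(v, e, domain = rbind(rep(-1, 3), rep(101, 3)))
}

# independent per-root shortest-loop oracle by exhaustive simple-path
# enumeration (only for tiny graphs)
exhaustive_loops <- function(net) {
  E <- net$edges
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  elen <- net$length
  ekey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  path_len <- function(p) {
    a <- p[-length(p)]; b <- p[-1]
    sum(elen[match(paste(pmin(a, b), pmax(a, b)), ekey)])
  }
  keys <- character(0); loops <- list()
  for (v in seq_len(nrow(net$vertices))) {
    nbrs <- as.integer(igraph::neighbors(g, v))
    nbrs <- unique(nbrs[nbrs != v])
    if (length(nbrs) < 2) next
    gv <- igraph::delete_vertices(g, v)  # removes the root entirely
    relab <- function(i) i - (i > v)     # vertex ids shift after deletion
    for (a in seq_along(nbrs)[-length(nbrs)]) for (b in (a + 1):length(nbrs)) {
      ps <- igraph::all_simple_paths(gv, relab(nbrs[a]), relab(nbrs[b]))
      if (!length(ps)) next
      ps <- lapply(ps, function(p) {
        p <- as.integer(p)
        p + (p >= v)  # back to original labels
      })
      lens <- vapply(ps, path_len, numeric(1))
      best <- ps[[which.min(lens)]]
      cyc <- c(v, best)
      key <- capnet:::.canonical_cycle_key(cyc)
      if (!(key %in% keys)) { keys <- c(keys, key); loops[[length(loops) + 1]] <- cyc }
    }
  }
  list(loops = loops, keys = sort(keys))
}

loop_keys <- function(ls) {
  sort(vapply(ls$loops, capnet:::.canonical_cycle_key, character(1)))
}

# brute-force EVD oracle in plain R
evd_brute <- function(net, voxel) {
  ext <- net$domain[2, ] - net$domain[1, ]
  dims <- pmax(as.integer(round(ext / voxel)), 1L)
  out <- array(Inf, dims)
  A <- net$vertices[net$edges[, 1], , drop = FALSE]
  B <- net$vertices[net$edges[, 2], , drop = FALSE]
  r <- net$diameter / 2
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    p <- net$domain[1, ] + (c(i, j, k) - 0.5) * voxel
    dmin <- Inf
    for (s in seq_len(nrow(A))) {
      d <- B[s, ] - A[s, ]
      L2 <- sum(d^2)
      t <- if (L2 > 0) max(0, min(1, sum((p - A[s, ]) * d) / L2)) else 0
      q <- A[s, ] + t * d
      dmin <- min(dmin, sqrt(sum((p - q)^2)) - r[s])
    }
    out[i, j, k] <- dmin
  }
  out
}
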