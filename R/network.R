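#' Vascular network spatial graph
#'
#' Container for a capillary network: vertex positions in micrometres, an edge
#' list with per-edge diameters, and the axis-aligned domain box. Edges are
#' straight segments between their endpoint vertices; edge lengths are always
#' the Euclidean endpoint distance (tortuosity is deliberately ignored, so a
#' multi-point centreline read from file is collapsed to its endpoints).
#'
#' @param vertices numeric matrix (n x 3), positions in micrometres.
#' @param edges integer matrix (m x 2), 1-based vertex indices.
#' @param diameter numeric vector of length m (or a scalar, recycled), vessel
#'   diameters in micrometres. Default 5, the uniform capillary diameter used
#'   throughout.
#' @param domain numeric 2 x 3 matrix, rows = (min, max) corners of the
#'   axis-aligned bounding box in micrometres. Defaults to the vertex bounding
#'   box.
#' @param validate logical; run consistency checks.
#' @return An object of class `vascular_network`: a list with elements
#'   `vertices`, `edges`, `diameter`, `domain` and the derived `length` per
#'   edge (micrometres).
#' @examples
#' v <- rbind(c(0, 0, 0), c(100, 0, 0))
#' net <- vascular_network(v, rbind(c(1L, 2L)), diameter = 5)
#' edge_lengths(net)
#' @export
vascular_network <- function(vertices, edges, diameter = 5,
                             domain = NULL, validate = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2)
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  m <- nrow(edges)
  diameter <- rep_len(as.numeric(diameter), m)
  if (is.null(domain)) {
    if (nrow(vertices) > 0L) {
      domain <- rbind(apply(vertices, 2, min), apply(vertices, 2, max))
    } else {
      domain <- rbind(c(0, 0, 0), c(0, 0, 0))
    }
  }
  domain <- matrix(as.numeric(domain), nrow = 2)
  if (m > 0L && (any(edges < 1L) || any(edges > nrow(vertices))))
    stop("edge connectivity references a vertex outside 1..", nrow(vertices))
  net <- structure(
    list(vertices = vertices, edges = edges, diameter = diameter,
         domain = domain, length = .edge_lengths(vertices, edges)),
    class = "vascular_network")
  if (validate) validate_network(net)
  net
}

.edge_lengths <- function(vertices, edges) {
  if (nrow(edges) == 0L) return(numeric(0))
  d <- vertices[edges[, 1], , drop = FALSE] - vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' @rdname vascular_network
#' @param net a `vascular_network`.
#' @export
edge_lengths <- function(net) net$length

#' Validate a vascular network
#'
#' Checks edge indices, positive diameters, absence of self-loops and that all
#' vertices lie inside the domain box (to a small tolerance). Parallel edges
#' between the same vertex pair are permitted but reported as an attribute.
#'
#' @param net a `vascular_network`.
#' @return `net`, invisibly; stops on violation.
#' @export
validate_network <- function(net) {
  n <- nrow(net$vertices)
  if (nrow(net$edges) > 0L) {
    if (any(net$edges < 1L) || any(net$edges > n))
      stop("edge connectivity references a vertex outside 1..", n)
    if (any(net$edges[, 1] == net$edges[, 2]))
      stop("self-loop edges are not permitted")
    if (any(net$diameter <= 0))
      stop("all diameters must be positive")
  }
  if (n > 0L) {
    tol <- 1e-6 * max(net$domain[2, ] - net$domain[1, ], 1)
    lo <- sweep(net$vertices, 2, net$domain[1, ] - tol)
    hi <- sweep(net$vertices, 2, net$domain[2, ] + tol)
    if (any(lo < 0) || any(hi > 0))
      stop("vertex positions lie outside the domain box")
  }
  invisible(net)
}

#' Flag parallel (duplicate) edges
#'
#' @param net a `vascular_network`.
#' @return logical vector, `TRUE` for every edge after the first between the
#'   same vertex pair.
#' @export
parallel_edges <- function(net) {
  if (nrow(net$edges) == 0L) return(logical(0))
  key <- paste(pmin(net$edges[, 1], net$edges[, 2]),
               pmax(net$edges[, 1], net$edges[, 2]))
  duplicated(key)
}

#' @exportS3Method base::print
print.vascular_network <- function(x, ...) {
  ext <- x$domain[2, ] - x$domain[1, ]
  cat("Vascular network:", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  cat(sprintf("  domain: %.4g x %.4g x %.4g um\n", ext[1], ext[2], ext[3]))
  if (nrow(x$edges) > 0L)
    cat(sprintf("  mean length %.3g um, mean diameter %.3g um\n",
                mean(x$length), mean(x$diameter)))
  invisible(x)
}

#' @exportS3Method base::summary
summary.vascular_network <- function(object, ...) {
  lab <- classify_vertices(object)
  deg <- vertex_degrees(object)
  vol <- prod(object$domain[2, ] - object$domain[1, ])
  out <- list(
    n_vertices = nrow(object$vertices),
    n_edges = nrow(object$edges),
    n_interior = sum(lab$class == "interior"),
    n_boundary = sum(lab$class == "boundary"),
    total_length = sum(object$length),
    mean_length = if (nrow(object$edges)) mean(object$length) else NA_real_,
    length_density_mm2 = sum(object$length) / vol * 1e6,
    degree_table = table(deg[lab$class == "interior"]))
  class(out) <- "summary.vascular_network"
  out
}

#' @exportS3Method base::print
print.summary.vascular_network <- function(x, ...) {
  cat("Vascular network summary\n")
  cat("  vertices:", x$n_vertices,
      sprintf("(%d interior, %d boundary)\n", x$n_interior, x$n_boundary))
  cat("  edges:", x$n_edges,
      sprintf("  mean length %.3g um\n", x$mean_length))
  cat(sprintf("  length density: %.4g mm^-2\n", x$length_density_mm2))
  cat("  interior degree distribution:\n")
  print(x$degree_table)
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.vascular_network <- function(x, axes = c(1, 2), ...) {
  a <- axes[1]; b <- axes[2]
  lab <- c("x", "y", "z")
  graphics::plot(NA, xlim = x$domain[, a], ylim = x$domain[, b], asp = 1,
                 xlab = paste0(lab[a], " (um)"), ylab = paste0(lab[b], " (um)"),
                 ...)
  if (nrow(x$edges)) {
    graphics::segments(x$vertices[x$edges[, 1], a], x$vertices[x$edges[, 1], b],
                       x$vertices[x$edges[, 2], a], x$vertices[x$edges[, 2], b],
                       col = "steelblue4")
  }
  invisible(x)
}

#' Vertex degrees
#'
#' @param net a `vascular_network`.
#' @return integer vector of vertex degrees (parallel edges each counted).
#' @export
vertex_degrees <- function(net) {
  tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = nrow(net$vertices))
}

#' Classify vertices as boundary or interior
#'
#' A vertex within tolerance `eps` of any face of the domain box is a boundary
#' vertex; all others are interior. Boundary vertices of generated and cropped
#' networks are the clipped intersections of edges with the domain faces.
#'
#' @param net a `vascular_network`.
#' @param eps absolute tolerance in micrometres; default `1e-6` times the
#'   largest domain edge.
#' @return list with `class` (character, "interior"/"boundary") and `degree`.
#' @export
classify_vertices <- function(net, eps = NULL) {
  if (is.null(eps)) eps <- 1e-6 * max(net$domain[2, ] - net$domain[1, ], 1)
  n <- nrow(net$vertices)
  if (n == 0L) return(list(class = character(0), degree = integer(0)))
  near_lo <- abs(sweep(net$vertices, 2, net$domain[1, ])) <= eps
  near_hi <- abs(sweep(net$vertices, 2, net$domain[2, ])) <= eps
  boundary <- rowSums(near_lo | near_hi) > 0
  list(class = ifelse(boundary, "boundary", "interior"),
       degree = vertex_degrees(net))
}

#' Crop a network to a box
#'
#' Edges crossing a face of `box` are clipped, introducing a new boundary
#' vertex exactly on the face; edges fully outside are removed; diameters are
#' preserved. The operation is idempotent and never increases total length.
#'
#' @param net a `vascular_network`.
#' @param box numeric 2 x 3 matrix (min and max corners) in micrometres.
#' @return a `vascular_network` with `domain = box`.
#' @export
crop_network <- function(net, box) {
  box <- matrix(as.numeric(box), nrow = 2)
  if (any(box[2, ] <= box[1, ])) stop("degenerate crop box (zero extent)")
  V <- net$vertices
  E <- net$edges
  if (nrow(E) == 0L) {
    keep <- .inside_box(V, box)
    return(vascular_network(V[keep, , drop = FALSE],
                            matrix(integer(0), ncol = 2),
                            numeric(0), domain = box, validate = FALSE))
  }
  newV <- list(); newE <- list(); newD <- list()
  nV <- 0L
  add_vertex <- function(p) {
    nV <<- nV + 1L
    newV[[nV]] <<- p
    nV
  }
  vmap <- rep(NA_integer_, nrow(V))
  get_vertex <- function(i) {
    if (is.na(vmap[i])) vmap[i] <<- add_vertex(V[i, ])
    vmap[i]
  }
  k <- 0L
  for (e in seq_len(nrow(E))) {
    a <- V[E[e, 1], ]; b <- V[E[e, 2], ]
    seg <- .clip_segment(a, b, box)
    if (is.null(seg)) next
    k <- k + 1L
    ia <- if (seg$ta == 0) get_vertex(E[e, 1]) else add_vertex(seg$a)
    ib <- if (seg$tb == 1) get_vertex(E[e, 2]) else add_vertex(seg$b)
    if (ia == ib) next
    newE[[k]] <- c(ia, ib)
    newD[[k]] <- net$diameter[e]
  }
  V2 <- if (nV > 0L) do.call(rbind, newV) else matrix(numeric(0), ncol = 3)
  E2 <- if (length(newE)) do.call(rbind, newE) else matrix(integer(0), ncol = 2)
  # snap clipped coordinates exactly onto faces to avoid tolerance drift
  if (nrow(V2) > 0L) {
    for (ax in 1:3) {
      V2[abs(V2[, ax] - box[1, ax]) < 1e-9, ax] <- box[1, ax]
      V2[abs(V2[, ax] - box[2, ax]) < 1e-9, ax] <- box[2, ax]
      V2[, ax] <- pmin(pmax(V2[, ax], box[1, ax]), box[2, ax])
    }
  }
  vascular_network(V2, E2, unlist(newD), domain = box, validate = FALSE)
}

.inside_box <- function(P, box, tol = 1e-9) {
  if (nrow(P) == 0L) return(logical(0))
  ok <- rep(TRUE, nrow(P))
  for (ax in 1:3)
    ok <- ok & P[, ax] >= box[1, ax] - tol & P[, ax] <= box[2, ax] + tol
  ok
}

# Liang-Barsky clip of segment a->b against an axis-aligned box.
# Returns NULL if outside, else endpoints and their parameters along [0,1].
.clip_segment <- function(a, b, box) {
  d <- b - a
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (a[ax] < box[1, ax] || a[ax] > box[2, ax]) return(NULL)
    } else {
      ta <- (box[1, ax] - a[ax]) / d[ax]
      tb <- (box[2, ax] - a[ax]) / d[ax]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  if (t1 - t0 < 1e-12) return(NULL)
  list(a = a + t0 * d, b = a + t1 * d, ta = t0, tb = t1)
}
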