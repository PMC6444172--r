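#' Face-pressure boundary conditions for network flow
#'
#' A pressure gradient is applied across the domain along one axis: every
#' boundary vertex on the two faces perpendicular to `axis` receives the
#' inlet/outlet pressure, all other boundary vertices are sealed (no-flow).
#'
#' @param axis "x", "y" or "z".
#' @param dp pressure drop across the domain (Pa; arbitrary positive scale —
#'   the permeability is independent of it).
#' @param mu dynamic blood viscosity (Pa s); with uniform diameters the
#'   effective viscosity is the same in every vessel. Irrelevant to the
#'   permeability.
#' @return list of class `flow_bc`.
#' @export
flow_bc <- function(axis = c("x", "y", "z"), dp = 100, mu = 1e-3) {
  axis <- match.arg(axis)
  stopifnot(dp > 0, mu > 0)
  structure(list(axis = match(axis, c("x", "y", "z")), dp = dp, mu = mu),
            class = "flow_bc")
}

#' Solve Poiseuille network flow
#'
#' Linear network flow: each vessel has Poiseuille conductance
#' `g = pi d^4 / (128 mu l)`, flow is conserved at every vertex, and the
#' face pressures of `bc` are imposed. The sparse symmetric system is solved
#' for the unknown vertex pressures.
#'
#' @param net a [vascular_network()].
#' @param bc a [flow_bc()].
#' @param conductance optional per-edge conductance overriding the Poiseuille
#'   value (used internally for occlusions).
#' @return object of class `flow_solution`: vertex `pressure`, per-edge
#'   signed `flow` (um^3/s, positive from the lower- to the higher-indexed
#'   endpoint), per-edge mean `velocity` (um/s), global `Q` (um^3/s), face
#'   area `A` (um^2), domain length `L` (um), and the `bc`.
#' @export
solve_flow <- function(net, bc = flow_bc(), conductance = NULL) {
  if (nrow(net$edges) == 0L) stop("network has no edges")
  ax <- bc$axis
  lab <- classify_vertices(net)
  eps <- 1e-6 * max(net$domain[2, ] - net$domain[1, ])
  inlet <- abs(net$vertices[, ax] - net$domain[1, ax]) <= eps
  outlet <- abs(net$vertices[, ax] - net$domain[2, ax]) <= eps
  if (!any(inlet) || !any(outlet))
    stop("no vertices on the inlet/outlet faces: network does not span the ",
         c("x", "y", "z")[ax], " axis")
  g <- if (is.null(conductance))
    pi * net$diameter^4 / (128 * bc$mu * net$length) else conductance
  n <- nrow(net$vertices)
  E <- net$edges

  # restrict to components connected to both faces through the graph
  comp <- igraph::components(igraph::graph_from_edgelist(E, directed = FALSE))
  comp_id <- comp$membership
  ok_comp <- intersect(unique(comp_id[inlet]), unique(comp_id[outlet]))
  if (!length(ok_comp))
    stop("singular system: no path connects the inlet and outlet faces")
  active_v <- comp_id %in% ok_comp
  active_e <- active_v[E[, 1]] & active_v[E[, 2]]

  P <- rep(NA_real_, n)
  P[inlet] <- bc$dp
  P[outlet] <- 0
  fixed <- (inlet | outlet) & active_v
  free <- active_v & !fixed
  idx <- rep(NA_integer_, n)
  idx[free] <- seq_len(sum(free))
  Ea <- E[active_e, , drop = FALSE]
  ga <- g[active_e]
  i1 <- Ea[, 1]; i2 <- Ea[, 2]
  both_free <- free[i1] & free[i2]
  trip_i <- c(idx[i1[free[i1]]], idx[i2[free[i2]]],
              idx[i1[both_free]], idx[i2[both_free]])
  trip_j <- c(idx[i1[free[i1]]], idx[i2[free[i2]]],
              idx[i2[both_free]], idx[i1[both_free]])
  trip_x <- c(ga[free[i1]], ga[free[i2]], -ga[both_free], -ga[both_free])
  nf <- sum(free)
  if (nf > 0L) {
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(nf, nf))
    b <- rep(0, nf)
    f1 <- free[i1] & fixed[i2]
    f2 <- free[i2] & fixed[i1]
    acc <- c(ga[f1] * P[i2[f1]], ga[f2] * P[i1[f2]])
    rows <- c(idx[i1[f1]], idx[i2[f2]])
    if (length(acc)) {
      tab <- tapply(acc, rows, sum)
      b[as.integer(names(tab))] <- as.numeric(tab)
    }
    P[free] <- as.numeric(Matrix::solve(A, b))
  }
  flow <- rep(0, nrow(E))
  flow[active_e] <- ga * (P[i1] - P[i2])
  area <- pi * net$diameter^2 / 4
  velocity <- flow / area
  # global flowrate: net flow from the inlet-face vertex set into the domain
  cross <- xor(inlet[i1], inlet[i2])
  Qx <- sum(ifelse(inlet[i1], 1, -1)[cross] * (ga * (P[i1] - P[i2]))[cross])
  dims <- net$domain[2, ] - net$domain[1, ]
  Aface <- prod(dims[-ax])
  structure(list(pressure = P, flow = flow, velocity = velocity, Q = Qx,
                 A = Aface, L = dims[ax], bc = bc,
                 conductance = g, active_edge = active_e),
            class = "flow_solution")
}

#' @exportS3Method base::print
print.flow_solution <- function(x, ...) {
  cat("Network flow solution:", length(x$pressure), "vertices\n")
  cat(sprintf("  Q = %.4g um^3/s through face area %.4g um^2\n", x$Q, x$A))
  cat(sprintf("  mean |velocity| = %.4g um/s\n",
              mean(abs(x$velocity[x$active_edge]))))
  invisible(x)
}

#' Residual mass imbalance of a flow solution
#'
#' Maximum net inflow at any interior vertex, as a fraction of the total
#' inflow; a solver sanity value (should be < 1e-8).
#'
#' @param net the network the solution was computed on.
#' @param sol a `flow_solution`.
#' @return numeric scalar.
#' @export
mass_imbalance <- function(net, sol) {
  n <- nrow(net$vertices)
  E <- net$edges
  div <- rep(0, n)
  tab <- tapply(c(-sol$flow, sol$flow), c(E[, 1], E[, 2]), sum)
  div[as.integer(names(tab))] <- as.numeric(tab)
  ax <- sol$bc$axis
  eps <- 1e-6 * max(net$domain[2, ] - net$domain[1, ])
  face <- abs(net$vertices[, ax] - net$domain[1, ax]) <= eps |
          abs(net$vertices[, ax] - net$domain[2, ax]) <= eps
  max(abs(div[!face])) / max(sol$Q, .Machine$double.eps)
}

#' Darcy permeability of a network
#'
#' `K = mu (Q/A) / (dP/L)` with `Q` the global flowrate entering through the
#' face perpendicular to the axis, `A` that face's area and `L` the domain
#' length along the axis. Units um^2; independent of `dp` and `mu`.
#'
#' @param net a [vascular_network()].
#' @param axis "x", "y" or "z".
#' @param bc optional [flow_bc()] (its axis is overridden).
#' @param sol optional precomputed `flow_solution`.
#' @return permeability in um^2 (0, with a warning, if no flow passes).
#' @export
permeability <- function(net, axis = "x", bc = NULL, sol = NULL) {
  if (is.null(sol)) {
    if (is.null(bc)) bc <- flow_bc(axis = axis)
    bc$axis <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
    sol <- solve_flow(net, bc)
  }
  if (sol$Q <= 0) {
    warning("zero global flow; permeability is 0")
    return(0)
  }
  sol$bc$mu * (sol$Q / sol$A) / (sol$bc$dp / sol$L)
}

#' Capillary transit times
#'
#' Per-vessel transit time `t = l / |v|` for all vessels with nonzero
#' velocity, and the median.
#'
#' @param net a [vascular_network()].
#' @param sol a `flow_solution` for `net`.
#' @return list with `times` (seconds, assuming um/s velocities) and
#'   `median`.
#' @export
transit_times <- function(net, sol) {
  v <- abs(sol$velocity)
  keep <- v > 0
  if (!any(keep)) stop("all-zero flow: transit times undefined")
  t <- net$length[keep] / v[keep]
  list(times = t, median = stats::median(t))
}

#' Single-occlusion robustness campaign
#'
#' Each edge upstream of a flowing three-connected vertex is occluded in
#' turn by a hundredfold diameter reduction, the flow re-solved, and the
#' post- to pre-occlusion flow ratio recorded in the outflow edge(s).
#' Converging vertices (two inflows, one outflow) and diverging vertices
#' (one inflow, two outflows) are treated separately; for diverging vertices
#' branch A keeps its baseline flow direction and branch B reverses. A
#' vertex only qualifies if all its baseline edge flows exceed
#' `q_tol` (a fraction of the total inflow).
#'
#' @param net a [vascular_network()].
#' @param bc a [flow_bc()].
#' @param q_tol flow tolerance as a fraction of total inflow (default 1e-5,
#'   i.e. 0.001 percent).
#' @return object of class `occlusion_summary`: per-test records and class
#'   means. Diverging zero-outflow outcomes (both branches below `q_tol`
#'   post-occlusion) enter the branch-A mean as 0 and are also counted
#'   separately.
#' @export
occlusion_campaign <- function(net, bc = flow_bc(), q_tol = 1e-5) {
  base <- solve_flow(net, bc)
  qmin <- q_tol * base$Q
  lab <- classify_vertices(net)
  deg <- vertex_degrees(net)
  E <- net$edges
  g0 <- base$conductance
  v3 <- which(deg == 3L & lab$class == "interior")
  rec <- list(); nr <- 0L
  for (v in v3) {
    inc <- which(E[, 1] == v | E[, 2] == v)
    # signed flow into v along each incident edge
    qin <- ifelse(E[inc, 2] == v, base$flow[inc], -base$flow[inc])
    if (any(abs(qin) <= qmin)) next
    inflow <- inc[qin > 0]
    outflow <- inc[qin < 0]
    type <- if (length(inflow) == 2L && length(outflow) == 1L) "converging"
            else if (length(inflow) == 1L && length(outflow) == 2L) "diverging"
            else next
    for (occl in inflow) {
      g <- g0
      g[occl] <- g0[occl] / 100^4  # diameter reduction factor 100
      sol <- solve_flow(net, bc, conductance = g)
      qpost <- ifelse(E[inc, 2] == v, sol$flow[inc], -sol$flow[inc])
      if (type == "converging") {
        k <- match(outflow, inc)
        nr <- nr + 1L
        rec[[nr]] <- data.frame(vertex = v, type = type,
                                ratio_a = qpost[k] / qin[k],
                                ratio_b = NA_real_, zero_flow = FALSE)
      } else {
        k <- match(outflow, inc)
        r <- qpost[k] / qin[k]
        zero <- all(abs(qpost[k]) <= qmin)
        if (zero) {
          ra <- 0; rb <- 0
        } else {
          # branch A keeps its direction (ratio >= 0), branch B reverses
          ia <- which.max(r)
          ra <- r[ia]; rb <- r[-ia][1]
        }
        nr <- nr + 1L
        rec[[nr]] <- data.frame(vertex = v, type = type, ratio_a = ra,
                                ratio_b = rb, zero_flow = zero)
      }
    }
  }
  if (!nr) {
    out <- list(records = data.frame(), mean_converging = NA_real_,
                mean_diverging_a = NA_real_, zero_flow_fraction = NA_real_,
                q_tol = q_tol)
    class(out) <- "occlusion_summary"
    return(out)
  }
  records <- do.call(rbind, rec)
  conv <- records$type == "converging"
  divg <- records$type == "diverging"
  out <- list(records = records,
              mean_converging = if (any(conv)) mean(records$ratio_a[conv]) else NA_real_,
              mean_diverging_a = if (any(divg)) mean(records$ratio_a[divg]) else NA_real_,
              mean_diverging_b = if (any(divg)) mean(records$ratio_b[divg], na.rm = TRUE) else NA_real_,
              zero_flow_fraction = if (any(divg)) mean(records$zero_flow[divg]) else NA_real_,
              q_tol = q_tol)
  class(out) <- "occlusion_summary"
  out
}

#' @exportS3Method base::print
print.occlusion_summary <- function(x, ...) {
  cat("Occlusion campaign:", nrow(x$records), "occlusions\n")
  cat(sprintf("  mean converging ratio:  %.3f\n", x$mean_converging))
  cat(sprintf("  mean diverging A ratio: %.3f (zero-flow fraction %.2f)\n",
              x$mean_diverging_a, x$zero_flow_fraction))
  invisible(x)
}
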