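#' Ensemble metric table
#'
#' Computes the full metric panel (morphometry, loop topology, flow,
#' optionally EVD statistics, transit times, exchange and occlusion
#' robustness) for each network and summarizes as mean and SD across
#' networks (ROIs), the convention used for reported tables.
#'
#' @param networks a list of [vascular_network()] objects (or a single one).
#' @param evd_voxel voxel size for the EVD field, or `NULL` to skip EVD
#'   metrics.
#' @param flow compute flow/permeability/transit metrics.
#' @param occlusion run the single-occlusion campaign.
#' @param exchange compute the mass exchange coefficient (slowest metric;
#'   off by default).
#' @param bc a [flow_bc()].
#' @return object of class `metrics_table`: `per_network` data.frame and
#'   `summary` data.frame (metric, mean, sd).
#' @export
metric_table <- function(networks, evd_voxel = NULL, flow = TRUE,
                         occlusion = FALSE, exchange = FALSE,
                         bc = flow_bc()) {
  if (inherits(networks, "vascular_network")) networks <- list(networks)
  rows <- lapply(networks, function(net) {
    r <- tryCatch({
      evd <- if (!is.null(evd_voxel)) compute_evd(net, evd_voxel) else NULL
      mo <- morphometry(net, evd)
      lp <- loop_statistics(find_shortest_loops(net), net)
      out <- c(mean_length = mo$length_mean, sd_length = mo$length_sd,
               edge_density = mo$edge_density,
               length_density = mo$length_density,
               vertex_density = mo$interior_vertex_density,
               boundary_vertex_density = mo$boundary_vertex_density,
               multiply_connected_pct = mo$multiply_connected_pct,
               mean_edges_per_loop = lp$mean_edges_per_loop,
               mean_loop_length = lp$mean_loop_length,
               mean_loops_per_edge = lp$mean_loops_per_edge)
      if (!is.null(evd)) {
        out <- c(out, mean_evd = mo$mean_evd,
                 mean_local_max_evd = mo$mean_local_max_evd,
                 max_evd = mo$max_evd, convexity_index = mo$convexity_index)
      }
      if (flow) {
        sol <- solve_flow(net, bc)
        tt <- transit_times(net, sol)
        out <- c(out,
                 mean_velocity = mean(abs(sol$velocity[sol$active_edge])),
                 sd_velocity = stats::sd(abs(sol$velocity[sol$active_edge])),
                 permeability = permeability(net, sol = sol),
                 median_transit_time = tt$median)
      }
      if (occlusion) {
        oc <- occlusion_campaign(net, bc)
        out <- c(out, occl_converging = oc$mean_converging,
                 occl_diverging_a = oc$mean_diverging_a)
      }
      if (exchange) {
        ex <- exchange_coefficient(net)
        out <- c(out, exchange_h = ex$h)
      }
      out
    }, error = function(e) {
      warning("metric computation failed for a network: ",
              conditionMessage(e))
      NULL
    })
    r
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  per <- as.data.frame(do.call(rbind, rows))
  summ <- data.frame(metric = names(per),
                     mean = vapply(per, mean, numeric(1)),
                     sd = if (nrow(per) > 1)
                       vapply(per, stats::sd, numeric(1))
                     else rep(NA_real_, ncol(per)),
                     row.names = NULL)
  structure(list(per_network = per, summary = summ,
                 n = nrow(per)), class = "metrics_table")
}

#' @exportS3Method base::print
print.metrics_table <- function(x, ...) {
  cat("Metrics over", x$n, "network(s): mean ± SD\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-26s %10.4g ± %.3g\n", s$metric[i], s$mean[i],
                s$sd[i]))
  invisible(x)
}

#' Convergence of metrics with domain size
#'
#' Regenerates ensembles at increasing cubic domain sizes (multiples of the
#' characteristic length), computes the requested metrics, and evaluates the
#' convergence value |M_k - M_(k-1)| / M_k between successive sizes. A
#' metric is converged from the first size after which all convergence
#' values stay below `tol` (default 0.05); the largest such size over the
#' metrics considered estimates the representative elementary volume.
#'
#' @param config a [generation_config()]; its domain is overridden.
#' @param sizes ascending numeric vector of domain sizes in units of `lc`
#'   (at least 3 values).
#' @param n networks per size.
#' @param metrics character subset of the table metrics to track.
#' @return object of class `convergence_series`: per-size metric means,
#'   convergence values and `x_conv` per metric.
#' @export
convergence_study <- function(config, sizes = c(2, 3, 4, 5.5, 7, 9), n = 10,
                              metrics = c("mean_length",
                                          "mean_edges_per_loop",
                                          "mean_loops_per_edge",
                                          "permeability"),
                              tol = 0.05) {
  if (length(sizes) < 3) stop("need at least 3 sizes")
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  vals <- matrix(NA_real_, length(sizes), length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_along(sizes)) {
    cfg <- config
    cfg$domain <- rbind(c(0, 0, 0), rep(sizes[i] * config$lc, 3))
    nets <- generate_ensemble(cfg, n)
    tab <- metric_table(nets, flow = "permeability" %in% metrics)
    vals[i, ] <- tab$summary$mean[match(metrics, tab$summary$metric)]
  }
  conv <- abs(vals[-1, , drop = FALSE] - vals[-nrow(vals), , drop = FALSE]) /
    abs(vals[-1, , drop = FALSE])
  x_conv <- vapply(seq_along(metrics), function(j) {
    below <- conv[, j] < tol
    for (k in seq_along(below))
      if (all(below[k:length(below)])) return(sizes[k + 1])
    NA_real_
  }, numeric(1))
  names(x_conv) <- metrics
  structure(list(sizes = sizes, values = vals, convergence = conv,
                 x_conv = x_conv, rev = max(x_conv, na.rm = TRUE), tol = tol),
            class = "convergence_series")
}

#' Convergence values from a metric series
#'
#' The arithmetic of the convergence criterion alone:
#' |M_k - M_(k-1)| / M_k.
#'
#' @param M numeric vector of metric values at ascending sizes.
#' @return numeric vector, `NA` for the first entry.
#' @export
convergence_values <- function(M) {
  c(NA_real_, abs(M[-1] - M[-length(M)]) / abs(M[-1]))
}

#' @exportS3Method base::print
print.convergence_series <- function(x, ...) {
  cat("Convergence study over sizes (in lc units):",
      paste(x$sizes, collapse = ", "), "\n")
  for (m in colnames(x$values))
    cat(sprintf("  %-22s x_conv = %s lc\n", m,
                format(x$x_conv[m])))
  invisible(x)
}

#' Scaling of metrics with the characteristic length
#'
#' Generates ensembles at several `lc` values in a fixed domain and fits
#' log-log regressions of each metric against `lc`, returning exponents and
#' prefactors. Mean length, mean EVD and mean loop length scale linearly
#' with `lc`; length density and permeability scale with `1/lc^2`. The
#' length-density prefactor feeds [calibrate_lc()].
#'
#' @param config a [generation_config()]; `lc` is overridden.
#' @param lc_values at least 3 characteristic lengths (um).
#' @param n networks per value.
#' @param metrics metrics to fit.
#' @return object of class `scaling_fits`: per-metric exponent, prefactor
#'   and R^2.
#' @export
scaling_study <- function(config, lc_values = c(60, 75, 90), n = 5,
                          metrics = c("length_density", "mean_length",
                                      "mean_loop_length", "permeability")) {
  if (length(lc_values) < 3) stop("need at least 3 lc values")
  vals <- matrix(NA_real_, length(lc_values), length(metrics),
                 dimnames = list(NULL, metrics))
  for (i in seq_along(lc_values)) {
    cfg <- config
    cfg$lc <- lc_values[i]
    nets <- generate_ensemble(cfg, n)
    tab <- metric_table(nets, flow = "permeability" %in% metrics)
    vals[i, ] <- tab$summary$mean[match(metrics, tab$summary$metric)]
  }
  fits <- lapply(metrics, function(m) {
    y <- vals[, m]
    fit <- stats::lm(log(y) ~ log(lc_values))
    list(exponent = unname(stats::coef(fit)[2]),
         prefactor = exp(unname(stats::coef(fit)[1])),
         r_squared = summary(fit)$r.squared)
  })
  names(fits) <- metrics
  structure(list(lc_values = lc_values, values = vals, fits = fits),
            class = "scaling_fits")
}

#' @exportS3Method base::print
print.scaling_fits <- function(x, ...) {
  cat("Scaling with lc over", paste(x$lc_values, collapse = ", "), "um\n")
  for (m in names(x$fits))
    cat(sprintf("  %-18s exponent %+.3f (R^2 %.3f)\n", m,
                x$fits[[m]]$exponent, x$fits[[m]]$r_squared))
  invisible(x)
}
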