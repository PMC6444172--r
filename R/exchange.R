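#' Vessel-tissue mass exchange coefficient
#'
#' Volume-averaged exchange coefficient `h` for a non-reactive, highly
#' diffusible tracer, from a two-medium closure on a voxel grid: the vessel
#' phase is treated as well mixed at uniform concentration, the tissue phase
#' carries steady diffusion with a uniform volumetric sink, and `h` is the
#' interfacial flux per unit total volume per unit vessel-tissue averaged
#' concentration difference. Writing `s` for the unit-sink solution
#' (`D_t lap s = -1` in tissue, `s = 0` on the vessel surface, no-flux on the
#' domain boundary), `h = eps_t / <s>` with `eps_t` the tissue volume
#' fraction. `h` is exactly linear in `D_ratio` (the tissue-to-vessel
#' diffusivity ratio), zero when the tissue cannot diffuse, and increases
#' with the interfacial area and hence the vessel length density. Absolute
#' values are convention dependent.
#'
#' @param net a [vascular_network()].
#' @param d_ratio tissue-to-vessel diffusivity ratio (the conventional
#'   reporting value is 0.25).
#' @param voxel grid resolution in micrometres; must not exceed half the
#'   smallest vessel diameter.
#' @param d_vessel vessel (blood) diffusivity in um^2/s, scale reference.
#' @param tol relative tolerance of the conjugate-gradient solve.
#' @return object of class `exchange_result`: `h` (per second), `d_ratio`,
#'   `voxel`, `eps_t` (tissue volume fraction), `mean_s`.
#' @export
exchange_coefficient <- function(net, d_ratio = 0.25, voxel = 2,
                                 d_vessel = 1, tol = 1e-8) {
  if (voxel > min(net$diameter) / 2)
    stop("grid too coarse to resolve vessels (voxel > d/2)")
  if (d_ratio < 0) stop("d_ratio must be non-negative")
  field <- compute_evd(net, voxel)
  mask <- field$mask  # TRUE inside vessels
  if (!any(mask)) stop("no vessel voxels at this resolution")
  if (all(mask)) stop("no tissue voxels at this resolution")
  eps_t <- mean(!mask)
  if (d_ratio == 0) {
    return(structure(list(h = 0, d_ratio = 0, voxel = voxel, eps_t = eps_t,
                          mean_s = Inf), class = "exchange_result"))
  }
  Dt <- d_ratio * d_vessel
  dims <- dim(mask)
  n <- prod(dims)
  tidx <- which(!mask)
  row_of <- rep(NA_integer_, n)
  row_of[tidx] <- seq_along(tidx)
  nt <- length(tidx)
  ijk <- arrayInd(tidx, dims)
  # 7-point Laplacian over tissue voxels; vessel neighbours are Dirichlet 0,
  # domain-boundary neighbours are mirrored (no-flux)
  ii <- list(); jj <- list(); xx <- list(); q <- 0L
  diag_coef <- rep(0, nt)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- ijk
    nb[, ax] <- nb[, ax] + s
    inside <- nb[, ax] >= 1L & nb[, ax] <= dims[ax]
    nb_lin <- rep(NA_integer_, nt)
    nb_lin[inside] <- (nb[inside, 1] +
                       (nb[inside, 2] - 1L) * dims[1] +
                       (nb[inside, 3] - 1L) * dims[1] * dims[2])
    is_tissue <- inside
    is_tissue[inside] <- !mask[nb_lin[inside]]
    # faces inside the domain count on the diagonal (tissue neighbour:
    # standard stencil; vessel neighbour: Dirichlet 0); no-flux domain
    # boundary faces contribute nothing
    diag_coef <- diag_coef + as.numeric(inside)
    has_t <- which(is_tissue)
    q <- q + 1L
    ii[[q]] <- has_t
    jj[[q]] <- row_of[nb_lin[has_t]]
    xx[[q]] <- rep(-1, length(has_t))
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nt), unlist(ii)),
                            j = c(seq_len(nt), unlist(jj)),
                            x = c(diag_coef, unlist(xx)),
                            dims = c(nt, nt))
  # D_t lap s = -1  =>  (Dt/voxel^2) A s = 1
  b <- rep(voxel^2 / Dt, nt)
  s <- .cg_solve(A, b, tol = tol)
  mean_s <- mean(s)
  h <- eps_t / mean_s
  structure(list(h = h, d_ratio = d_ratio, voxel = voxel, eps_t = eps_t,
                 mean_s = mean_s), class = "exchange_result")
}

#' @exportS3Method base::print
print.exchange_result <- function(x, ...) {
  cat(sprintf("Exchange coefficient h = %.4g s^-1 (D_ratio = %g, voxel %g um)\n",
              x$h, x$d_ratio, x$voxel))
  invisible(x)
}

# Jacobi-preconditioned conjugate gradient for the SPD grid Laplacian
.cg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  x <- rep(0, length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) < tol * b2) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}
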