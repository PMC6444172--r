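#' Cubic lattice network (CLN)
#'
#' Regular 3D cubic grid with strut length `L` and 6-connectivity, built by
#' offset-and-clip placement: nodes at half-integer multiples of `L` on each
#' axis, axis-aligned struts, and boundary-crossing struts clipped at the
#' domain faces. With this placement the finite-domain length density equals
#' the analytic `3 / L^2` exactly whenever the domain is a multiple of `L`.
#' For the CLN the characteristic length equals the strut length, `lc = L`.
#'
#' @param L strut length in micrometres (> 0).
#' @param domain extents (length-3 vector) or 2 x 3 matrix, micrometres.
#' @param diameter uniform vessel diameter, micrometres.
#' @return a [vascular_network()].
#' @export
build_cln <- function(L, domain = c(240, 240, 240), diameter = 5) {
  if (L <= 0) stop("L must be positive")
  if (!is.matrix(domain)) domain <- rbind(c(0, 0, 0), as.numeric(domain))
  ext <- domain[2, ] - domain[1, ]
  if (any(ext < L)) stop("domain smaller than the strut length")
  nk <- floor(ext / L + 1e-9)
  ax_pos <- lapply(1:3, function(k) domain[1, k] + (seq_len(nk[k]) - 0.5) * L)
  grid <- as.matrix(expand.grid(ax_pos[[1]], ax_pos[[2]], ax_pos[[3]]))
  idx <- as.matrix(expand.grid(seq_len(nk[1]), seq_len(nk[2]), seq_len(nk[3])))
  key <- function(i, j, k) (k - 1) * nk[1] * nk[2] + (j - 1) * nk[1] + i
  V <- grid[order(key(idx[, 1], idx[, 2], idx[, 3])), , drop = FALSE]
  E <- list(); nE <- 0L
  add <- function(a, b) { nE <<- nE + 1L; E[[nE]] <<- c(a, b) }
  # interior struts
  for (ax in 1:3) {
    shift <- c(0L, 0L, 0L); shift[ax] <- 1L
    ok <- idx[, ax] < nk[ax]
    a <- key(idx[ok, 1], idx[ok, 2], idx[ok, 3])
    b <- key(idx[ok, 1] + shift[1], idx[ok, 2] + shift[2], idx[ok, 3] + shift[3])
    for (q in seq_along(a)) add(a[q], b[q])
  }
  E <- do.call(rbind, E)
  net <- vascular_network(V, E, diameter, domain = domain, validate = FALSE)
  # boundary stubs: extend every line to the faces, then clip
  stubs_V <- list(); stubs_E <- list(); nb <- 0L
  nV <- nrow(V)
  for (ax in 1:3) {
    lo <- which(idx[, ax] == 1L)
    hi <- which(idx[, ax] == nk[ax])
    for (v in key(idx[lo, 1], idx[lo, 2], idx[lo, 3])) {
      p <- V[v, ]; p[ax] <- domain[1, ax]
      nb <- nb + 1L; stubs_V[[nb]] <- p; stubs_E[[nb]] <- c(v, nV + nb)
    }
    for (v in key(idx[hi, 1], idx[hi, 2], idx[hi, 3])) {
      p <- V[v, ]; p[ax] <- domain[2, ax]
      nb <- nb + 1L; stubs_V[[nb]] <- p; stubs_E[[nb]] <- c(v, nV + nb)
    }
  }
  V <- rbind(V, do.call(rbind, stubs_V))
  E <- rbind(E, do.call(rbind, stubs_E))
  vascular_network(V, E, diameter, domain = domain, validate = FALSE)
}

#' Periodic three-connected lattice network (PLN)
#'
#' Open-cell-foam-inspired lattice: cubes of side `2L` placed with period
#' `3L`, each of the twelve cube edges linked through its midpoint by a
#' capillary strut across the inter-cube gap to the facing edge midpoint of
#' the neighbouring cube (link axes assigned cyclically, so the lattice is
#' symmetric under cyclic axis permutation). Every interior vertex (cube
#' corner or edge midpoint) has degree exactly 3, the motif is
#' translation-periodic with period `3L`, and the length density is
#' `10 / lc^2` with `lc = 3L`.
#'
#' @inheritParams build_cln
#' @return a [vascular_network()].
#' @export
build_pln <- function(L, domain = c(240, 240, 240), diameter = 5) {
  if (L <= 0) stop("L must be positive")
  if (!is.matrix(domain)) domain <- rbind(c(0, 0, 0), as.numeric(domain))
  ext <- domain[2, ] - domain[1, ]
  if (any(ext < 3 * L)) stop("domain smaller than the lattice period 3L")
  p <- 3 * L
  # build motif edges as segment list on an extended region, then crop
  ncell <- ceiling(ext / p) + 1L
  segs <- list(); ns <- 0L
  seg <- function(a, b) { ns <<- ns + 1L; segs[[ns]] <<- c(a, b) }
  corners <- as.matrix(expand.grid(c(0, 2 * L), c(0, 2 * L), c(0, 2 * L)))
  for (cx in seq_len(ncell[1] + 3L) - 2L) {
    for (cy in seq_len(ncell[2] + 3L) - 2L) {
      for (cz in seq_len(ncell[3] + 3L) - 2L) {
        o <- domain[1, ] - p / 2 + c(cx, cy, cz) * p
        crn <- sweep(corners, 2, o, "+")
        # cube edges, split at midpoints
        for (a in 1:7) for (b in (a + 1):8) {
          if (sum(corners[a, ] != corners[b, ]) == 1L) {
            mid <- (crn[a, ] + crn[b, ]) / 2
            seg(crn[a, ], mid); seg(mid, crn[b, ])
          }
        }
        # straight links across the inter-cube gap: the midpoint of an edge
        # along axis w links along axis a(w) = w mod 3 + 1 (cyclic, so the
        # lattice is symmetric under cyclic axis permutation) to the facing
        # midpoint of the next cube; emitted only from the far (+a) side
        for (w in 1:3) {
          a <- w %% 3L + 1L
          b <- setdiff(1:3, c(w, a))
          for (su in c(0, 2 * L)) for (sv in c(0, 2 * L)) {
            m <- o
            m[w] <- o[w] + L
            m[a] <- o[a] + su
            m[b] <- o[b] + sv
            if (su == 2 * L) {
              m2 <- m
              m2[a] <- m[a] + (p - 2 * L)
              seg(m, m2)
            }
          }
        }
      }
    }
  }
  A <- do.call(rbind, lapply(segs, function(s) s[1:3]))
  B <- do.call(rbind, lapply(segs, function(s) s[4:6]))
  # deduplicate segments shared between neighbouring motif copies
  keym <- paste(round((A + B) / 2, 6)[, 1], round((A + B) / 2, 6)[, 2],
                round((A + B) / 2, 6)[, 3])
  keep <- !duplicated(keym)
  A <- A[keep, , drop = FALSE]; B <- B[keep, , drop = FALSE]
  P <- rbind(A, B)
  gid <- .merge_points(P, tol = 1e-6 * L)
  E <- cbind(gid$map[seq_len(nrow(A))], gid$map[nrow(A) + seq_len(nrow(B))])
  big <- rbind(apply(gid$points, 2, min), apply(gid$points, 2, max))
  net <- vascular_network(gid$points, E, diameter, domain = big,
                          validate = FALSE)
  crop_network(net, domain)
}

#' Analytic lattice scaling laws
#'
#' Predicted length density, mean loop length and Darcy permeability of the
#' lattice networks as functions of the characteristic length and diameter.
#' For the CLN these are closed forms: length density `3 / lc^2`, loop
#' length `4 lc`, and permeability `pi d^4 / (128 lc^2)` under Poiseuille
#' conductance (one through-going channel per `lc^2` of face area). For the
#' PLN the prefactors follow from its motif (per period `(3L)^3`: 12 cube
#' edges of length `2L` and 12 diagonal links of length `sqrt(2) L`).
#'
#' @param kind "cln" or "pln".
#' @param lc characteristic length, micrometres.
#' @param diameter vessel diameter, micrometres.
#' @return list with `length_density` (um^-2), `mean_loop_length` (um),
#'   `permeability` (um^2).
#' @export
lattice_scaling <- function(kind = c("cln", "pln"), lc, diameter = 5) {
  kind <- match.arg(kind)
  if (kind == "cln") {
    c_den <- 3
    c_loop <- 4
    c_perm <- pi / 128
  } else {
    # per period (3L)^3 = lc^3: 24 cube-edge halves plus 6 owned gap links,
    # all of length L => density 30 / (27 L^2) = 10 / lc^2
    c_den <- 10
    c_loop <- NA_real_
    c_perm <- NA_real_  # no closed form retained; see vignette
  }
  list(length_density = c_den / lc^2,
       mean_loop_length = c_loop * lc,
       permeability = c_perm * diameter^4 / lc^2)
}

#' Calibrate the characteristic length from a target length density
#'
#' Given the fitted scaling `density = c2 / lc^2`, returns the `lc` that
#' matches a target length density. For the CLN the closed form `c2 = 3`
#' recovers the strut length exactly.
#'
#' @param target_length_density target density in mm^-2.
#' @param c2 scaling prefactor such that density (um^-2) = `c2 / lc^2`;
#'   default 3 (the CLN closed form).
#' @param snap snap the result to a whole micrometre (the convention used for
#'   the lattice baselines reported by the package).
#' @return characteristic length in micrometres.
#' @export
calibrate_lc <- function(target_length_density, c2 = 3, snap = FALSE) {
  if (target_length_density <= 0) stop("target density must be positive")
  lc <- sqrt(c2 / (target_length_density * 1e-6))
  if (snap) lc <- round(lc)
  lc
}
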