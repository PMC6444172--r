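#' Read an AmiraMesh ASCII spatial graph
#'
#' Parses the Avizo/Amira ASCII spatial-graph dialect (sections
#' `VertexCoordinates`, `EdgeConnectivity`, `NumEdgePoints`,
#' `EdgePointCoordinates`, `thickness`). Tortuous multi-point edges are
#' collapsed to their endpoint pair, so every edge length is the straight
#' endpoint distance; the per-point thickness is averaged along each edge.
#'
#' @param path file path.
#' @param thickness_is radius ("radius", the Avizo convention, default) or
#'   "diameter"; controls conversion of the thickness field to diameters.
#' @return a [vascular_network()].
#' @export
read_spatialgraph <- function(path, thickness_is = c("radius", "diameter")) {
  thickness_is <- match.arg(thickness_is)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*#\\s*AmiraMesh 3D ASCII", lines[1]))
    stop("malformed header: expected '# AmiraMesh 3D ASCII'")
  counts <- c(VERTEX = NA_integer_, EDGE = NA_integer_, POINT = NA_integer_)
  for (nm in names(counts)) {
    m <- grep(paste0("^\\s*define\\s+", nm, "\\s+\\d+"), lines, value = TRUE)
    if (length(m))
      counts[nm] <- as.integer(sub(paste0(".*define\\s+", nm, "\\s+(\\d+).*"),
                                   "\\1", m[1]))
  }
  if (any(is.na(counts)))
    stop("malformed header: missing define for ",
         paste(names(counts)[is.na(counts)], collapse = ", "))
  # map data markers (@1..) to section names from the declaration block
  decl <- grep("@\\d+\\s*$", lines)
  decl <- decl[grepl("\\{", lines[decl]) | grepl("\\}", lines[decl]) |
               grepl("(VERTEX|EDGE|POINT)", lines[decl])]
  sec_of <- list()
  for (i in decl) {
    id <- sub(".*@(\\d+)\\s*$", "\\1", lines[i])
    nm <- if (grepl("VertexCoordinates", lines[i])) "VertexCoordinates"
      else if (grepl("EdgeConnectivity", lines[i])) "EdgeConnectivity"
      else if (grepl("NumEdgePoints", lines[i])) "NumEdgePoints"
      else if (grepl("EdgePointCoordinates", lines[i])) "EdgePointCoordinates"
      else if (grepl("thickness|Thickness|Radius", lines[i])) "thickness"
      else NA_character_
    if (!is.na(nm)) sec_of[[id]] <- nm
  }
  # data blocks start at lines equal to "@k"
  starts <- grep("^@\\d+\\s*$", lines)
  blocks <- list()
  for (j in seq_along(starts)) {
    id <- sub("^@(\\d+)\\s*$", "\\1", lines[starts[j]])
    end <- if (j < length(starts)) starts[j + 1] - 1L else length(lines)
    body <- if (starts[j] + 1L > end) character(0)
            else lines[(starts[j] + 1L):end]
    body <- body[nzchar(trimws(body))]
    nm <- sec_of[[id]]
    if (!is.null(nm))
      blocks[[nm]] <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  }
  need <- c("VertexCoordinates", "EdgeConnectivity", "NumEdgePoints",
            "EdgePointCoordinates")
  for (nm in need)
    if (is.null(blocks[[nm]])) stop("missing data section: ", nm)

  nv <- counts["VERTEX"]; ne <- counts["EDGE"]; np <- counts["POINT"]
  if (length(blocks$VertexCoordinates) != 3 * nv)
    stop("inconsistent section counts: VertexCoordinates")
  if (length(blocks$EdgeConnectivity) != 2 * ne)
    stop("inconsistent section counts: EdgeConnectivity")
  if (length(blocks$NumEdgePoints) != ne)
    stop("inconsistent section counts: NumEdgePoints")
  if (length(blocks$EdgePointCoordinates) != 3 * np)
    stop("inconsistent section counts: EdgePointCoordinates")

  V <- matrix(blocks$VertexCoordinates, ncol = 3, byrow = TRUE)
  E <- matrix(as.integer(blocks$EdgeConnectivity), ncol = 2, byrow = TRUE) + 1L
  if (ne > 0L && (any(E < 1L) || any(E > nv)))
    stop("EdgeConnectivity references a vertex outside 0..", nv - 1L)
  nep <- as.integer(blocks$NumEdgePoints)
  if (sum(nep) != np) stop("inconsistent section counts: NumEdgePoints vs POINT")

  thick <- blocks$thickness
  diam <- rep(5, max(ne, 0L))
  if (!is.null(thick)) {
    if (length(thick) != np) stop("inconsistent section counts: thickness")
    idx <- rep(seq_len(ne), nep)
    per_edge <- tapply(thick, idx, mean)
    diam <- as.numeric(per_edge)[seq_len(ne)]
    if (thickness_is == "radius") diam <- 2 * diam
  }
  vascular_network(V, E, diam, validate = TRUE)
}

#' Write an AmiraMesh ASCII spatial graph
#'
#' Writes the network in the standard Avizo ASCII spatial-graph format; each
#' straight edge is written with two edge points and per-point thickness equal
#' to the vessel radius. `read_spatialgraph()` round-trips the result.
#'
#' @param net a [vascular_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spatialgraph <- function(net, path) {
  nv <- nrow(net$vertices); ne <- nrow(net$edges)
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# AmiraMesh 3D ASCII 2.0", "",
    sprintf("define VERTEX %d", nv),
    sprintf("define EDGE %d", ne),
    sprintf("define POINT %d", 2L * ne), "",
    "Parameters {",
    "    ContentType \"HxSpatialGraph\"",
    "}", "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5", "")
  fmt3 <- function(M) sprintf("%.9g %.9g %.9g", M[, 1], M[, 2], M[, 3])
  w("@1")
  if (nv > 0L) w(fmt3(net$vertices))
  w("", "@2")
  if (ne > 0L) w(sprintf("%d %d", net$edges[, 1] - 1L, net$edges[, 2] - 1L))
  w("", "@3")
  if (ne > 0L) w(rep("2", ne))
  w("", "@4")
  if (ne > 0L) {
    P <- matrix(NA_real_, 2L * ne, 3)
    P[seq(1, 2 * ne, by = 2), ] <- net$vertices[net$edges[, 1], , drop = FALSE]
    P[seq(2, 2 * ne, by = 2), ] <- net$vertices[net$edges[, 2], , drop = FALSE]
    w(fmt3(P))
  }
  w("", "@5")
  if (ne > 0L) w(sprintf("%.9g", rep(net$diameter / 2, each = 2)))
  invisible(path)
}
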