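test_that("network construction derives straight lengths and validates input", {
  v <- rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12))
  net <- vascular_network(v, rbind(c(1L, 2L), c(2L, 3L)), diameter = 5)
  expect_equal(edge_lengths(net), c(5, 12))
  expect_equal(net$diameter, c(5, 5))
  expect_error(vascular_network(v, rbind(c(1L, 4L))), "outside")
  expect_error(vascular_network(v, rbind(c(1L, 1L))), "self-loop")
  expect_error(vascular_network(v, rbind(c(1L, 2L)), diameter = -1), "positive")
  # parallel edges permitted but flagged
  net2 <- vascular_network(v, rbind(c(1L, 2L), c(2L, 1L)))
  expect_equal(parallel_edges(net2), c(FALSE, TRUE))
})

test_that("spatialgraph files round-trip and a thickness radius becomes a diameter", {
  path <- withr::local_tempfile(fileext = ".am")
  v <- rbind(c(0, 0, 0), c(100, 0, 0))
  net <- vascular_network(v, rbind(c(1L, 2L)), diameter = 5,
                          domain = rbind(c(0, -10, -10), c(100, 10, 10)))
  write_spatialgraph(net, path)
  txt <- readLines(path)
  expect_match(txt[1], "AmiraMesh 3D ASCII")
  expect_true(any(grepl("define VERTEX 2", txt)))
  expect_true(any(grepl("define EDGE 1", txt)))
  expect_true(any(grepl("define POINT 2", txt)))
  back <- read_spatialgraph(path)
  expect_equal(back$vertices, net$vertices, tolerance = 1e-6)
  expect_equal(back$edges, net$edges)
  expect_equal(back$diameter, net$diameter, tolerance = 1e-6)

  net3 <- s75_network(1)
  p3 <- withr::local_tempfile(fileext = ".am")
  write_spatialgraph(net3, p3)
  back3 <- read_spatialgraph(p3)
  expect_equal(back3$vertices, net3$vertices, tolerance = 1e-6)
  expect_equal(back3$edges, net3$edges)
  expect_equal(back3$diameter, net3$diameter, tolerance = 1e-6)

  # empty network still writes a readable file
  p4 <- withr::local_tempfile(fileext = ".am")
  empty <- vascular_network(matrix(numeric(0), ncol = 3),
                            matrix(integer(0), ncol = 2),
                            domain = rbind(c(0, 0, 0), c(1, 1, 1)))
  write_spatialgraph(empty, p4)
  expect_equal(nrow(read_spatialgraph(p4)$vertices), 0L)
})

test_that("malformed spatialgraph files raise named parse errors", {
  path <- withr::local_tempfile(fileext = ".am")
  writeLines(c("# AmiraMesh 3D ASCII 2.0",
               "define VERTEX 10", "define EDGE 1", "define POINT 2",
               "VERTEX { float[3] VertexCoordinates } @1",
               "EDGE { int[2] EdgeConnectivity } @2",
               "EDGE { int NumEdgePoints } @3",
               "POINT { float[3] EdgePointCoordinates } @4",
               "@1", paste(rep("0 0 0", 10), collapse = "\n"),
               "@2", "0 99",
               "@3", "2",
               "@4", "0 0 0", "1 1 1"), path)
  expect_error(read_spatialgraph(path), "references a vertex")
  writeLines("not amira", path)
  expect_error(read_spatialgraph(path), "header")
})

test_that("vertices are classified by proximity to the domain faces", {
  v <- rbind(c(0, 120, 120), c(120, 120, 120), c(240, 0, 13))
  net <- vascular_network(v, rbind(c(1L, 2L), c(2L, 3L)),
                          domain = rbind(c(0, 0, 0), c(240, 240, 240)))
  lab <- classify_vertices(net, eps = 1e-6)
  expect_equal(lab$class, c("boundary", "interior", "boundary"))
  expect_equal(lab$degree, c(1L, 2L, 1L))
  # CLN built by offset-and-clip: every clipped stub endpoint is boundary
  cln <- build_cln(60, c(240, 240, 240))
  lab2 <- classify_vertices(cln)
  deg <- vertex_degrees(cln)
  expect_true(all(lab2$class[deg == 1L] == "boundary"))
  expect_equal(sum(lab2$class == "boundary"), 6L * 16L)  # 4x4 stubs per face
})

test_that("cropping clips edges at faces, preserves length additivity and is idempotent", {
  box <- rbind(c(0, 0, 0), c(240, 240, 240))
  v <- rbind(c(-10, 0, 0) + c(0, 60, 60), c(110, 120, 120))
  net <- vascular_network(v, rbind(c(1L, 2L)),
                          domain = rbind(c(-20, 0, 0), c(240, 240, 240)))
  cr <- crop_network(net, box)
  expect_equal(nrow(cr$edges), 1L)
  expect_equal(min(cr$vertices[, 1]), 0)  # clipped exactly on the face
  # additivity: inside part + outside part = original length
  inside_len <- sum(cr$length)
  expect_lt(inside_len, sum(net$length))
  frac <- 110 / 120  # parameter of the x = 0 crossing along the segment
  expect_equal(inside_len, sum(net$length) * frac, tolerance = 1e-12)

  full <- s75_network(1)
  again <- crop_network(full, full$domain)
  expect_equal(sort(round(as.numeric(again$vertices), 9)),
               sort(round(as.numeric(full$vertices), 9)))
  expect_equal(nrow(again$edges), nrow(full$edges))
  expect_lte(sum(again$length), sum(full$length) + 1e-9)
  expect_error(crop_network(full, rbind(c(0, 0, 0), c(0, 240, 240))),
               "degenerate")
})
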