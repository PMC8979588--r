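test_that("tsoax dialect parses headers, rows and junction sections", {
  f <- withr::local_tempfile()
  writeLines(c("# comment header",
               "$ another header",
               "1 1 0.0 0.0 0.0 5.0",
               "1 2 0.5 0.0 0.0 6.0",
               "1 3 1.0 0.1 0.0 7.0",
               "2 1 3.0 3.0 1.0 1.0",
               "2 2 3.5 3.0 1.0 1.5",
               "[ junction section",
               "0.5 0.0 0.0"), f)
  s <- suppressMessages(read_snakes(f, "tsoax"))
  expect_equal(n_snakes(s), 2)
  expect_equal(nrow(s), 5)
  expect_equal(s$x[1:3], c(0, 0.5, 1))          # file order preserved
  expect_equal(s$intensity[4:5], c(1, 1.5))
  expect_length(attr(s, "junctions"), 2)
})

test_that("snake round trips are exact in both dialects", {
  s <- snake_set(rbind(
    data.frame(snake_id = 1, x = c(0, 1.25, 2.5), y = c(0, 0.2, 0),
               z = c(0, 0, 0.125), intensity = c(5, 8.5, 2)),
    data.frame(snake_id = 7, x = c(3, 4), y = 1, z = 0.5, intensity = 1)))
  for (dialect in c("tsoax", "polyline_table")) {
    f <- withr::local_tempfile()
    write_snakes(s, f, dialect)
    s2 <- read_snakes(f, dialect)
    expect_equal(as.data.frame(s2), as.data.frame(s), tolerance = 1e-6)
  }
})

test_that("malformed snake input is rejected with a line number", {
  f <- withr::local_tempfile()
  writeLines(c("1 1 0 0 0 5", "1 2 1 0 0 5",
               "2 1 9 9 9 1", "2 2 9 8 9 1",
               "1 3 2 0 0 5"), f)               # snake 1 reappears
  expect_error(read_snakes(f, "tsoax"), "contiguous")

  writeLines(c("1 1 0 0 0 5", "1 2 oops 0 0 5"), f)
  expect_error(read_snakes(f, "tsoax"), "line 2")

  writeLines(c("1 1 0 0 0 5"), f)               # single-vertex snake
  expect_error(read_snakes(f, "tsoax"), "fewer than 2")

  writeLines(c("snake_id,x,y,intensity", "1,0,0,5"), f)
  expect_error(read_snakes(f, "polyline_table"), "z")
})

test_that("coordinate scale converts voxel-unit files to micrometres", {
  f <- withr::local_tempfile()
  writeLines(c("1 1 0 0 0 5", "1 2 10 0 0 5"), f)
  s <- read_snakes(f, "tsoax", scale = 0.065)
  expect_equal(s$x[2], 0.65)
})

test_that("writing non-finite coordinates is refused; empty set allowed", {
  bad <- data.frame(snake_id = 1, x = c(0, NaN), y = 0, z = 0, intensity = 1)
  expect_error(snake_set(bad), "finite")
  empty <- snake_set(data.frame(snake_id = numeric(0), x = numeric(0),
                                y = numeric(0), z = numeric(0),
                                intensity = numeric(0)))
  f <- withr::local_tempfile()
  write_snakes(empty, f, "tsoax")
  expect_match(readLines(f)[1], "^#")
  expect_equal(nrow(read_snakes(f, "tsoax")), 0)
})

test_that("TIFF stack round trip preserves voxels and spacing", {
  st <- image_stack(array(runif(4 * 4 * 4) * 300, c(4, 4, 4)),
                    c(0.18, 0.065, 0.065))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, f)
  st2 <- read_stack(f)
  expect_equal(st2$voxels, st$voxels, tolerance = 1e-6)
  expect_equal(unname(st2$spacing), c(0.18, 0.065, 0.065))
})

test_that("2D TIFF reads as a one-plane stack; missing spacing errors", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), f)
  st <- read_stack(f, spacing = c(0.2, 0.05, 0.05))
  expect_equal(dim(st$voxels), c(1, 4, 4))
  expect_error(read_stack(f), "spacing")
})

test_that("RGB TIFF input is rejected", {
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(48), c(4, 4, 3)), f)
  expect_error(read_stack(f, spacing = c(1, 1, 1)), "RGB")
})

test_that("network serialization conserves vertices in every format", {
  m <- build_network(y_branch_snakes(), graph_params())
  f <- withr::local_tempfile(fileext = ".json")
  write_network(m, f, "json")
  m2 <- read_network(f)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))
  expect_equal(m2$vertices$x, m$vertices$x)
  expect_equal(m2$vertices$intensity, m$vertices$intensity)
  expect_equal(m2$segments$arc_length, m$segments$arc_length)

  fg <- withr::local_tempfile(fileext = ".graphml")
  write_network(m, fg, "graphml")
  g <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(m$nodes))
  expect_equal(igraph::ecount(g), nrow(m$segments))

  stem <- withr::local_tempfile()
  paths <- write_network(m, stem, "csv_tables")
  expect_true(all(file.exists(paths)))
  vt <- read.csv(paths[3])
  expect_equal(nrow(vt), nrow(m$vertices))
})

test_that("OBJ export encodes geometry, thickness sidecar and colors", {
  m <- build_network(y_branch_snakes(), graph_params())
  f <- withr::local_tempfile(fileext = ".obj")
  out <- export_obj(m, f, radius_scale = 0.01, seed = 4)
  lines <- readLines(f)
  expect_equal(sum(grepl("^v ", lines)), nrow(m$vertices))
  expect_equal(sum(grepl("^l ", lines)), nrow(m$segments))
  radii <- read.csv(out$radii)
  # radius ratio equals brightness ratio
  expect_equal(max(radii$radius) / min(radii$radius),
               max(m$segments$mean_intensity) / min(m$segments$mean_intensity))
  expect_equal(radii$radius, 0.01 * m$segments$mean_intensity)
  # seeded colors are reproducible
  f2 <- withr::local_tempfile(fileext = ".obj")
  export_obj(m, f2, radius_scale = 0.01, seed = 4)
  expect_identical(readLines(out$mtl),
                   readLines(sub("\\.obj$", ".mtl", f2)))
  # tube meshes: 8 ring vertices per polyline vertex
  f3 <- withr::local_tempfile(fileext = ".obj")
  export_obj(m, f3, radius_scale = 0.01, tubes = TRUE)
  expect_equal(sum(grepl("^v ", readLines(f3))), 8 * nrow(m$vertices))
})

test_that("a 3-row single snake file gives one snake in file order", {
  f <- withr::local_tempfile()
  writeLines(c("5 1 1 2 3 4", "5 2 2 2 3 4", "5 3 3 2 3 4"), f)
  s <- read_snakes(f, "tsoax")
  expect_equal(n_snakes(s), 1)
  expect_equal(s$x, c(1, 2, 3))
})
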