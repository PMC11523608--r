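# Mesh I/O, FO candidate extraction, quadrant labels, interior sampling.

test_that("STL reading handles the canonical cube and unit conversion", {
  path <- write_cube_stl()
  m <- read_mesh(path)
  expect_s3_class(m, "tri_mesh")
  expect_equal(nrow(m$faces), 12L)
  expect_equal(nrow(m$vertices), 8L)
  expect_true(is_watertight(m))
  m_m <- read_mesh(path, units = "m")
  expect_equal(range(m_m$vertices), c(0, 1000))
})

test_that("STL write/read round-trips preserve facets and coordinates", {
  geo <- default_scene()$geo
  for (fmt in c("ascii", "binary")) {
    path <- tempfile(fileext = ".stl")
    write_mesh(geo$la, path, format = fmt)
    back <- read_mesh(path)
    expect_equal(nrow(back$faces), nrow(geo$la$faces))
    orig_tri <- geo$la$vertices[t(geo$la$faces), ]
    back_tri <- back$vertices[t(back$faces), ]
    expect_lt(max(abs(orig_tri - back_tri)), 1e-4)
  }
})

test_that("unreadable or empty mesh files raise classed errors", {
  bad <- tempfile(fileext = ".stl")
  writeLines(c("solid junk", "facet normal", "vertex oops"), bad)
  expect_error(read_mesh(bad), class = "fossagii_format_error")
  empty <- tempfile(fileext = ".stl")
  file.create(empty)
  expect_error(read_mesh(empty), class = "fossagii_format_error")
  expect_error(read_mesh(tempfile()), class = "fossagii_resolution_error")
})

test_that("FO centroid is the thinnest vertex with lowest-index tie-break", {
  geo <- default_scene()$geo
  fo <- geo$fo
  # parabolic profile: minimum at the disc centre (vertex 1)
  patch <- extract_fo_candidates(fo, geo$thickness)
  expect_equal(patch$centroid_index, 1L)
  expect_equal(patch$centroid, fo$vertices[1L, ])
  # uniform thickness: tie resolves to vertex 1
  flat <- extract_fo_candidates(fo, rep(1, nrow(fo$vertices)))
  expect_equal(flat$centroid_index, 1L)
  expect_equal(range(geo$thickness), c(0.65, 1.75))
  expect_error(extract_fo_candidates(fo, rep(0, nrow(fo$vertices))),
               class = "fossagii_validation_error")
})

test_that("FO normals are unit, point to the LA side, and flip with it", {
  geo <- default_scene()$geo
  patch <- extract_fo_candidates(geo$fo, geo$thickness,
                                 la_reference = geo$la_centroid)
  lens <- sqrt(rowSums(patch$normals^2))
  expect_lt(max(abs(lens - 1)), 1e-9)
  inward <- geo$la_centroid - patch$centroid
  expect_true(all(patch$normals %*% inward > 0))
  mirrored <- extract_fo_candidates(geo$fo, geo$thickness,
                                    la_reference = 2 * patch$centroid - geo$la_centroid)
  expect_equal(mirrored$normals, -patch$normals)
})

test_that("quadrant labels follow offset signs with ties toward S and P", {
  frame <- list(superior = c(0, 0, 1), posterior = c(0, 1, 0))
  ctr <- c(5, 5, 5)
  expect_equal(assign_quadrant(ctr + c(0, 1, 1), frame, ctr), "SP")
  expect_equal(assign_quadrant(ctr + c(0, -1, -1), frame, ctr), "IA")
  expect_equal(assign_quadrant(ctr + c(0, -1, 1), frame, ctr), "SA")
  expect_equal(assign_quadrant(ctr + c(0, 1, -1), frame, ctr), "IP")
  expect_equal(assign_quadrant(ctr, frame, ctr), "SP")
  expect_error(assign_quadrant(ctr + 1, list(superior = c(0, 0, 2),
                                             posterior = c(0, 1, 0)), ctr),
               class = "fossagii_validation_error")
})

test_that("quadrant assignment is invariant under rigid transforms", {
  frame <- list(superior = c(0, 0, 1), posterior = c(0, 1, 0))
  ctr <- c(1, 2, 3)
  set.seed(11)
  for (k in 1:20) {
    p <- ctr + rnorm(3)
    R <- random_rotation(100 + k)
    shift <- rnorm(3, sd = 10)
    lab <- assign_quadrant(p, frame, ctr)
    frame_r <- list(superior = as.numeric(R %*% frame$superior),
                    posterior = as.numeric(R %*% frame$posterior))
    lab_r <- assign_quadrant(as.numeric(R %*% p) + shift, frame_r,
                             as.numeric(R %*% ctr) + shift)
    expect_equal(lab_r, lab)
  }
})

test_that("interior grid sampling matches the volume-ratio oracle", {
  ico <- fossagii:::icosphere(3L)
  sphere <- tri_mesh(ico$vertices * 20, ico$faces, name = "sphere20")
  samp <- sample_la_interior(sphere, 2.5)
  expected <- (4 / 3) * pi * 20^3 / 2.5^3
  expect_lt(abs(nrow(samp$points) - expected) / expected, 0.05)
})

test_that("halving the grid spacing multiplies the count by ~8", {
  ico <- fossagii:::icosphere(2L)
  sphere <- tri_mesh(ico$vertices * 20, ico$faces, name = "sphere20c")
  n1 <- nrow(sample_la_interior(sphere, 4)$points)
  n2 <- nrow(sample_la_interior(sphere, 2)$points)
  expect_lt(abs(n2 / n1 - 8) / 8, 0.10)
})

test_that("degenerate sampling inputs raise resolution/validation errors", {
  ico <- fossagii:::icosphere(1L)
  sphere <- tri_mesh(ico$vertices * 5, ico$faces)
  expect_error(sample_la_interior(sphere, 50),
               class = "fossagii_resolution_error")
  open_mesh <- tri_mesh(sphere$vertices, sphere$faces[-1, ])
  expect_error(sample_la_interior(open_mesh, 2),
               class = "fossagii_validation_error")
  expect_error(sample_la_interior(sphere, -1),
               class = "fossagii_validation_error")
})

test_that("all sampled points are inside by the winding-number oracle", {
  ico <- fossagii:::icosphere(2L)
  sphere <- tri_mesh(ico$vertices * 15, ico$faces)
  samp <- sample_la_interior(sphere, 4)
  expect_true(all(winding_inside(samp$points, sphere)))
  # and points placed clearly outside are not flagged inside by the sampler's
  # own parity test
  outside <- matrix(c(20, 0, 0, 0, 25, 0, 16, 16, 16), ncol = 3, byrow = TRUE)
  expect_false(any(fossagii:::points_in_mesh(outside, sphere)))
})

test_that("PLY heatmap export writes a parseable per-vertex scalar", {
  geo <- default_scene()$geo
  path <- tempfile(fileext = ".ply")
  write_ply_scalar(geo$fo, seq_len(nrow(geo$fo$vertices)) / 197, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  nv <- nrow(geo$fo$vertices)
  expect_true(sprintf("element vertex %d", nv) %in% lines)
  body <- strsplit(lines[which(lines == "end_header") + 1], " ")[[1]]
  expect_length(body, 7L)
})
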