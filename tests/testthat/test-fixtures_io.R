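test_that("tube phantoms have exact centreline distance, arc length and orientation", {
  ph <- make_tube_phantom(2.5e-3, 90, 0.03, c(0.1, 0.1))
  expect_equal(ph$total_arc, 0.2 + 0.03 * pi / 2, tolerance = 1e-12)

  # near-degenerate bend: centreline length equals the sum of parts
  flat <- make_tube_phantom(2e-3, 1, 0.03, c(0.05, 0.05), capped = FALSE)
  expect_equal(max(flat$centreline$arc),
               0.1 + 0.03 * pi / 180, tolerance = 1e-3 * 0.1)

  # every vertex exactly one lumen radius from the analytic centreline
  d <- tube_centreline_distance(ph$mesh$vertices, ph)$distance
  expect_lt(max(abs(d - 2.5e-3)), 1e-9)

  # full-mesh orientation audit: normals point towards the centreline
  V <- ph$mesh$vertices; F_ <- ph$mesh$faces
  centroid <- (V[F_[, 1], ] + V[F_[, 2], ] + V[F_[, 3], ]) / 3
  near <- tube_path_points(ph, tube_centreline_distance(centroid, ph)$arc)
  inward <- rowSums(ph$mesh$normals * (near - centroid))
  expect_true(all(inward > 0))

  expect_error(make_tube_phantom(2.5e-3, 90, 1e-3, c(0.1, 0.1)),
               "self-intersecting")
  expect_error(make_tube_phantom(2.5e-3, 270, 0.03, c(0.1, 0.1)),
               "bend_angle")
})

test_that("stenosed/healthy pairs share topology and nest radially", {
  pair <- make_stenosed_vessel(2e-3, stenosis_center = 0.03, severity = 0.5,
                               extent = 0.012)
  expect_identical(pair$stenosed$mesh$faces, pair$healthy$mesh$faces)

  # throat radius is severity-scaled
  d_sten <- tube_centreline_distance(pair$stenosed$mesh$vertices,
                                     pair$healthy)$distance
  expect_equal(min(d_sten), 0.5 * 2e-3, tolerance = 1e-9)

  # stenosed lumen nested inside the healthy lumen, vertex by vertex
  d_heal <- tube_centreline_distance(pair$healthy$mesh$vertices,
                                     pair$healthy)$distance
  expect_true(all(d_sten <= d_heal + 1e-12))
})

test_that("mesh round-trips preserve geometry across OBJ and both STL flavours", {
  ph <- small_tube(segments = 10L, axial_step = 6e-3)
  dir <- withr::local_tempdir()

  obj <- file.path(dir, "tube.obj")
  write_mesh(ph$mesh, obj)
  back <- read_mesh(obj)
  expect_lt(max(abs(back$vertices - ph$mesh$vertices)), 1e-6 * 1e-3)
  expect_identical(back$faces, ph$mesh$faces)

  stla <- file.path(dir, "tube_a.stl")
  stlb <- file.path(dir, "tube_b.stl")
  write_mesh(ph$mesh, stla, format = "ascii")
  write_mesh(ph$mesh, stlb, format = "binary")
  ma <- read_mesh(stla); mb <- read_mesh(stlb)
  tri_set <- function(m) {
    soup <- round(cbind(m$vertices[m$faces[, 1], ], m$vertices[m$faces[, 2], ],
                        m$vertices[m$faces[, 3], ]) * 1e7)
    sort(apply(soup, 1, paste, collapse = ","))
  }
  expect_identical(tri_set(ma), tri_set(mb))
  expect_equal(nrow(ma$faces), nrow(ph$mesh$faces))
})

test_that("centreline and drive files round-trip; malformed rows are reported", {
  dir <- withr::local_tempdir()
  cl <- reference_centreline(cbind(c(0, 0.01, 0.02), c(0, 1e-3, 0), 0))
  csv <- file.path(dir, "line.csv")
  write_centreline(cl, csv)
  expect_equal(read_centreline(csv)$points, cl$points, tolerance = 1e-12)
  js <- file.path(dir, "line.json")
  write_centreline(cl, js)
  expect_equal(read_centreline(js)$points, cl$points, tolerance = 1e-12)

  bad <- file.path(dir, "bad.csv")
  writeLines(c("x_mm,y_mm,z_mm", "1,2,3", "4,oops,6"), bad)
  expect_error(read_centreline(bad), "row 2")

  drv <- insertion_drive(c(0, 1, 2.5), c(0.02, 0, -0.02), c(0, pi, 0))
  dcsv <- file.path(dir, "drive.csv")
  write_drive(drv, dcsv)
  expect_equal(unclass(read_drive(dcsv)), unclass(drv), tolerance = 1e-12)
})

test_that("scenario YAML files load into params and solver config", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scenario.yaml")
  writeLines(c(
    "dt: 0.001",
    "duration: 2",
    "seed: 7",
    "instrument:",
    "  name: test_wire",
    "  total_length_mm: 255",
    "  n_points: 256",
    "  E_b_Pa: 5.0e6",
    "  radius_mm: 0.4",
    "  density_kg_m3: 8.0e6",
    "  K_p: 0.2",
    "  alpha: 0.5",
    "  tip_points: 5",
    "  mu: 0.3",
    "solver:",
    "  distance_mode: local_gauss_seidel",
    "  outer_iterations: 10"), path)
  sc <- read_scenario(path)
  expect_equal(sc$params$young_modulus_shaft, 5e6)
  expect_equal(sc$params$radius, 0.4e-3)
  expect_equal(sc$config$distance_mode, "local_gauss_seidel")
  expect_equal(sc$config$outer_iterations, 10L)
  expect_equal(sc$n_points, 256)
  expect_equal(sc$total_length, 0.255)
  expect_equal(sc$seed, 7)
})

test_that("a small compression benchmark is bit-reproducible", {
  p <- material_params()
  sc <- canonical_compression_scenario(n_points = 64L, total_length = 0.063,
                                       params = p)
  sc$duration <- 1.5
  variants <- data.frame(mode = c("global_tridiagonal", "local_gauss_seidel"),
                         iterations = c(1, 5))
  r1 <- run_compression_experiment(sc, variants, seed = 3L)
  r2 <- run_compression_experiment(sc, variants, seed = 3L)
  expect_identical(r1$results$compression_percent,
                   r2$results$compression_percent)
  expect_identical(r1$results$compression_mm, r2$results$compression_mm)

  dir <- withr::local_tempdir()
  write_experiment_report(r1, dir)
  expect_true(file.exists(file.path(dir, "compression.csv")))
  back <- read.csv(file.path(dir, "compression.csv"))
  expect_equal(back$compression_percent, r1$results$compression_percent,
               tolerance = 1e-12)
})

test_that("recorded trajectories export to CSV", {
  p <- material_params()
  rod <- perturbed_rod(10, seed = 30)
  sim <- simulate_insertion(rod, p, config = sim_config(), duration = 0.05,
                            record_stride = 10L)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "traj.csv")
  write_trajectory(sim, f)
  tr <- read.csv(f)
  expect_true(all(c("time_s", "point", "x_mm") %in% names(tr)))
  expect_equal(nrow(tr), length(sim$trace$time) * 10)
})
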