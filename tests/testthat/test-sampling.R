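test_that("volume normalisation follows the per-modality modes", {
  v50 <- constant_volume(50, modality = "t1w")
  out <- normalise_volume(v50, target_mean = 100)
  expect_equal(out$data, array(100, dim(v50$data)))

  q <- constant_volume(0.02, modality = "qsm")
  outq <- normalise_volume(q, target_mean = 0)
  expect_equal(outq$data, array(0, dim(q$data)), tolerance = 1e-12)

  fa <- constant_volume(0.4, modality = "fa")
  expect_identical(normalise_volume(fa, target_mean = 100)$data, fa$data)

  # idempotence: normalising twice equals normalising once
  set.seed(2)
  g <- voxel_grid(c(8, 8, 8))
  noisy <- image_volume(array(runif(512, 40, 80), c(8, 8, 8)), g$affine,
                        modality = "t2w")
  once <- normalise_volume(noisy, target_mean = 100)
  twice <- normalise_volume(once, target_mean = 100)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("CSF exclusion and error contracts of normalisation hold", {
  g <- voxel_grid(c(6, 6, 6))
  dat <- array(10, c(6, 6, 6)); dat[1:3, , ] <- 1000  # bright CSF half
  vol <- image_volume(dat, g$affine, modality = "t1w")
  csf <- array(0, c(6, 6, 6)); csf[1:3, , ] <- 1
  csf_mask <- image_volume(csf, g$affine, modality = "mask")
  out <- normalise_volume(vol, csf_mask = csf_mask, target_mean = 100)
  expect_equal(out$data[6, 1, 1], 100)  # mean over non-CSF voxels was 10

  neg <- constant_volume(-5, modality = "t1w")
  expect_error(normalise_volume(neg, target_mean = 100), "non-positive")
  allcsf <- image_volume(array(1, c(6, 6, 6)), g$affine, modality = "mask")
  expect_error(normalise_volume(vol, csf_mask = allcsf), "empty")
})

test_that("trilinear profile sampling is exact on linear fields", {
  vol <- linear_x_volume()
  pr <- sample_profile(vol, origin = c(10, 0, 0), direction = c(1, 0, 0),
                       spacing = 0.5, n = 5)
  expect_equal(pr$values, c(9, 9.5, 10, 10.5, 11), tolerance = 1e-12)
  expect_true(all(pr$valid))
  # centre offset moves the whole window
  pr2 <- sample_profile(vol, c(10, 0, 0), c(1, 0, 0), 0.5, 5,
                        centre_offset = 2)
  expect_equal(pr2$values, pr$values - 1, tolerance = 1e-12)
})

test_that("out-of-FOV samples are flagged, not fatal", {
  vol <- constant_volume(7)
  pr <- sample_profile(vol, origin = c(100, 0, 0), direction = c(1, 0, 0),
                       spacing = 1, n = 5)
  expect_true(all(!pr$valid))
  expect_true(all(is.na(pr$values)))
  expect_error(sample_profile(vol, c(0, 0, 0), c(1, 1, 0), 1, 5),
               "unit vector")
})

test_that("profile extraction obeys the geometry and validity contracts", {
  cfg <- mist_config(k_prime = 20)
  expect_equal(cfg$k, 40)           # default rule: k = k' + Delta, Delta = k'
  mesh <- icosphere_mesh(0, c(3, 3, 3))
  normals <- compute_vertex_normals(mesh)
  vols <- list(list(t1w = constant_volume(5, dim = c(24, 24, 24))),
               list(t1w = constant_volume(5, dim = c(24, 24, 24))))
  cfg2 <- mist_config(k_prime = 6, spacing_mm = 0.5)
  ps <- extract_profiles(vols, mesh, normals, cfg2)
  expect_equal(dim(ps$profiles), c(2, 1, 12, 6))
  # zero-noise constant phantom: all profiles identical
  expect_lt(max(abs(ps$profiles - 5)), 1e-9)
  expect_true(all(ps$valid))
  expect_equal(ps$k, 12)

  # missing modality is an error naming the subject
  vols_bad <- list(list(t1w = constant_volume(5)), list(other = constant_volume(5)))
  expect_error(extract_profiles(vols_bad, mesh, normals, cfg2),
               "subject 2 is missing")

  # vertices whose profiles leave the FOV are flagged invalid
  small <- list(list(t1w = constant_volume(5, dim = c(4, 4, 4))))
  mesh_big <- icosphere_mesh(0, c(2, 2, 2))
  ps2 <- extract_profiles(small, mesh_big, compute_vertex_normals(mesh_big),
                          mist_config(k_prime = 8, spacing_mm = 1))
  expect_true(any(!ps2$valid))
})

test_that("phantom profiles split into inside and outside halves", {
  spec <- phantom_spec(subdivisions = 1, def_h_mm = 1e-9,
                       modalities = list(t1w = list(inside = 100, outside = 60,
                                                    neighbour = 135,
                                                    noise_sd = 0)))
  s <- generate_subject(spec, 5, with_mask = FALSE)
  mesh <- s$reference_mesh
  normals <- compute_vertex_normals(mesh)
  cfg <- spec$config
  # vertex away from the neighbour band (x < 0 side)
  i <- which.min(mesh$vertices[, 1])
  pr <- sample_profile(s$volumes$t1w, mesh$vertices[i, ], normals[i, ],
                       cfg$spacing_mm, cfg$k_prime)
  kp <- cfg$k_prime
  # allow one transition sample at each end of the boundary (partial volume)
  expect_true(all(abs(pr$values[1:(kp / 2 - 1)] - 100) < 20))
  expect_true(all(abs(pr$values[(kp / 2 + 2):kp] - 60) < 20))
})

test_that("image volume construction validates input", {
  g <- voxel_grid(c(4, 4, 4))
  expect_error(image_volume(array(c(1, NA), c(4, 4, 4)), g$affine),
               "non-finite")
  expect_error(image_volume(array(2, c(4, 4, 4)), g$affine, modality = "fa"),
               "sanity range")
  bad <- g$affine; bad[1, 1] <- 0
  expect_error(image_volume(array(1, c(4, 4, 4)), bad), "singular")
})

test_that("NIfTI volumes round-trip with affine", {
  v <- image_volume(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                    rbind(c(1.25, 0, 0, -3), c(0, 1.25, 0, -4),
                          c(0, 0, 1.25, -5), c(0, 0, 0, 1)),
                    modality = "t1w")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f, "t1w")
  expect_equal(v2$data, v$data, tolerance = 1e-5)
  expect_equal(v2$affine, v$affine, tolerance = 1e-5, ignore_attr = TRUE)
})
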