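# Shared fixtures: a small (8 x 96 x 96) phantom for unit tests, built once
# per test run and memoised. All fixtures are generated in code.

.fixtures <- new.env(parent = emptyenv())

small_phantom_spec <- function(seed = 101, kind = "metastasis",
                               necrosis_offset = c(0, 1, 1),
                               necrosis_margin = 3,
                               noise = list(sigma = 12, impulse_fraction = 0.005),
                               deformation = NULL) {
  tc <- c(3.5, 36, 38)
  if (is.null(deformation))
    deformation <- list(rotation_deg = 1, scale = c(1, 1.004, 1.004),
                        translation_voxels = c(0, 1.5, 2),
                        amplitude = c(0.2, 1.2, 1.2),
                        wavelength = c(20, 70, 80), phase = c(0.15, 0.55))
  phantom_spec(
    grid_shape = c(8, 96, 96), spacing_mm = c(5, 1, 1),
    liver = list(center = c(3.5, 47.5, 47.5), radii = c(6.5, 38, 43),
                 intensity = 2200,
                 texture = list(amplitude = 50, wavelength = c(6.3, 17.3, 21.6),
                                phase = c(0.3, 0.8))),
    tumor = list(kind = kind, center = tc, radii = c(2.2, 10, 13),
                 ring_fractions = c(0.35, 0.78, 1), intensities = NULL,
                 edge_voxels = 1.5),
    necrosis = list(center = tc + necrosis_offset,
                    radii = c(2.2, 10, 13) + c(0.8, necrosis_margin, necrosis_margin),
                    intensity = 900, patch = NULL),
    deformation = deformation, noise = noise, seed = seed
  )
}

small_phantom <- function() {
  if (is.null(.fixtures$pair)) .fixtures$pair <- make_phantom_pair(small_phantom_spec())
  .fixtures$pair
}

small_phantom_clean <- function() {
  if (is.null(.fixtures$pair_clean)) {
    sp <- small_phantom_spec(noise = list(sigma = 0, impulse_fraction = 0))
    .fixtures$pair_clean <- make_phantom_pair(sp)
  }
  .fixtures$pair_clean
}

# hand-built cluster_result for segmentation-rule tests that need exact labels
fake_clusters <- function(labels, c = 7, spacing_mm = c(5, 1, 1)) {
  structure(list(
    labels = labels, centroids = seq_len(c) * 500, c = as.integer(c), m = 2,
    iterations = 1L, objective = 0, objective_trace = 0,
    values = seq_len(c) * 500, memberships = diag(c),
    spacing_mm = spacing_mm
  ), class = "cluster_result")
}

# rasterize an ellipse (half-axes a >= b, rotation theta degrees) on an
# n x n slice mask; independent oracle geometry for orientation tests
raster_ellipse <- function(n, a, b, theta_deg, center = NULL) {
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  th <- theta_deg * pi / 180
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  dr <- g$r - center[1]
  dc <- g$c - center[2]
  u <- dr * cos(th) + dc * sin(th)
  v <- -dr * sin(th) + dc * cos(th)
  matrix((u / a)^2 + (v / b)^2 <= 1, n, n)
}
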