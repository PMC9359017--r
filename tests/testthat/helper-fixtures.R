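# Shared fixtures and independent oracles for the test suite.

# Random mask on a small grid; density kept moderate so surfaces exist.
random_mask <- function(geom, density = 0.2, seed = 1) {
  withr::with_seed(seed, {
    binary_mask(geom, array(runif(prod(geom$size)) < density, geom$size))
  })
}

sphere_mask <- function(geom, center, radius) {
  co <- adaptqa:::coord_arrays(geom)
  binary_mask(geom, (co$x - center[1])^2 + (co$y - center[2])^2 +
                    (co$z - center[3])^2 <= radius^2)
}

# World coordinates of all inside voxels, n x 3.
inside_points <- function(mask) {
  co <- adaptqa:::coord_arrays(mask$geometry)
  cbind(co$x[mask$inside], co$y[mask$inside], co$z[mask$inside])
}

# Brute-force margin expansion: all-pairs voxel-center distances.
oracle_expand <- function(mask, margin) {
  pts <- inside_points(mask)
  co <- adaptqa:::coord_arrays(mask$geometry)
  d <- vapply(seq_len(prod(mask$geometry$size)), function(i) {
    sqrt(min((co$x[i] - pts[, 1])^2 + (co$y[i] - pts[, 2])^2 +
             (co$z[i] - pts[, 3])^2))
  }, 0)
  binary_mask(mask$geometry, array(d <= margin + 1e-9, mask$geometry$size))
}

# Brute-force pooled mean symmetric surface distance via all point pairs.
oracle_mssd <- function(a, b) {
  sa <- adaptqa:::surface_voxels(a$inside)
  sb <- adaptqa:::surface_voxels(b$inside)
  pa <- inside_points(binary_mask(a$geometry, sa))
  pb <- inside_points(binary_mask(b$geometry, sb))
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)), function(i, j) {
    sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2 +
         (pa[i, 3] - pb[j, 3])^2)
  })
  mean(c(apply(dmat, 1, min), apply(dmat, 2, min)))
}

# 6-connected component count via BFS flood fill.
n_components_6 <- function(inside) {
  d <- dim(inside)
  labels <- array(0L, d)
  nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  comp <- 0L
  todo <- which(inside & labels == 0L)
  while (length(todo) > 0) {
    comp <- comp + 1L
    frontier <- todo[1]
    labels[frontier] <- comp
    while (length(frontier) > 0) {
      idx <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (k in 1:6) {
        cand <- sweep(idx, 2, nb[k, ], "+")
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
              cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        lin <- cand[, 1] + (cand[, 2] - 1) * d[1] + (cand[, 3] - 1) * d[1] * d[2]
        lin <- lin[inside[lin] & labels[lin] == 0L]
        labels[lin] <- comp
        nxt <- c(nxt, lin)
      }
      frontier <- unique(nxt)
    }
    todo <- which(inside & labels == 0L)
  }
  comp
}

# Coarse phantom sharing the default world extent: fast enough for unit
# tests while exercising the same code paths.
small_phantom_config <- function(seed = 20220707) {
  phantom_config(geom = geometry(origin = c(-139, -7, 609),
                                 spacing = c(4, 4, 4), size = c(64, 64, 48)),
                 seed = seed)
}

small_study_config <- function(n_deformations = 2, n_fractions = 8,
                               n_ai_per_plan = 2) {
  study_config(phantom = small_phantom_config(),
               n_deformations = n_deformations, n_fractions = n_fractions,
               n_ai_per_plan = n_ai_per_plan)
}
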