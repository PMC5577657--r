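# Brute-force reference implementations, deliberately independent of the
# package's C++ kernels: everything works on explicit voxel coordinate lists.

bf_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  s <- rowSums(abs(g))
  lim <- c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)]
  g[s > 0 & s <= lim, , drop = FALSE]
}

in_bounds <- function(coords, d) {
  coords[, 1] >= 1 & coords[, 1] <= d[1] &
    coords[, 2] >= 1 & coords[, 2] <= d[2] &
    coords[, 3] >= 1 & coords[, 3] <= d[3]
}

bf_dilate <- function(mask, steps, connectivity) {
  d <- dim(mask)
  off <- bf_offsets(connectivity)
  cur <- mask
  for (s in seq_len(steps)) {
    out <- cur
    idx <- which(cur, arr.ind = TRUE)
    for (i in seq_len(nrow(off))) {
      nb <- sweep(idx, 2, off[i, ], "+")
      nb <- nb[in_bounds(nb, d), , drop = FALSE]
      out[nb] <- TRUE
    }
    cur <- out
  }
  cur
}

# boundary faces as a matrix (z, y, x, dz, dy, dx), one row per face
bf_faces <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  rows <- list()
  for (i in 1:6) {
    nb <- sweep(idx, 2, dirs[i, ], "+")
    outside <- !in_bounds(nb, d)
    exposed <- outside
    exposed[!outside] <- !mask[nb[!outside, , drop = FALSE]]
    f <- idx[exposed, , drop = FALSE]
    if (nrow(f))
      rows[[length(rows) + 1L]] <-
        cbind(f, matrix(dirs[i, ], nrow(f), 3, byrow = TRUE))
  }
  m <- do.call(rbind, rows)
  m[order(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6]), , drop = FALSE]
}

# contact faces: seed boundary faces whose owning voxel has a soil voxel
# within the structuring-element neighbourhood
bf_contact_counts <- function(seed, soil, connectivity) {
  d <- dim(seed)
  faces <- bf_faces(seed)
  off <- bf_offsets(connectivity)
  hit <- 0L
  for (k in seq_len(nrow(faces))) {
    own <- faces[k, 1:3]
    nb <- sweep(off, 2, own, "+")
    nb <- nb[in_bounds(nb, d), , drop = FALSE]
    if (any(soil[nb])) hit <- hit + 1L
  }
  c(total = nrow(faces), hit = hit)
}

# shell by direct distance computation between voxel coordinate lists
bf_shell <- function(seed, width, metric) {
  d <- dim(seed)
  sidx <- which(seed, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  all_idx <- which(!seed, arr.ind = TRUE)
  for (k in seq_len(nrow(all_idx))) {
    v <- all_idx[k, ]
    dz <- abs(sidx[, 1] - v[1]); dy <- abs(sidx[, 2] - v[2])
    dx <- abs(sidx[, 3] - v[3])
    dist <- if (metric == "chebyshev") min(pmax(dz, pmax(dy, dx)))
            else sqrt(min(dz^2 + dy^2 + dx^2))
    if (dist <= width) out[v[1], v[2], v[3]] <- TRUE
  }
  out
}

# TRUE when the mask encloses a background cavity (6-connected background
# flood fill from the grid boundary cannot reach every background voxel)
bf_has_enclosed_bg <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, dim = d)
  bnd <- bg
  bnd[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
  reach[bnd] <- TRUE
  off <- bf_offsets(6)
  repeat {
    idx <- which(reach, arr.ind = TRUE)
    grew <- FALSE
    for (i in seq_len(nrow(off))) {
      nb <- sweep(idx, 2, off[i, ], "+")
      nb <- nb[in_bounds(nb, d), , drop = FALSE]
      new <- nb[bg[nb] & !reach[nb], , drop = FALSE]
      if (nrow(new)) { reach[new] <- TRUE; grew <- TRUE }
    }
    if (!grew) break
  }
  any(bg & !reach)
}

rand_mask <- function(d, p) {
  array(runif(prod(d)) < p, dim = d)
}

make_sphere <- function(n, r, center = rep((n + 1) / 2, 3)) {
  z2 <- (seq_len(n) - center[1])^2
  y2 <- (seq_len(n) - center[2])^2
  x2 <- (seq_len(n) - center[3])^2
  array(outer(outer(z2, y2, "+"), x2, "+") <= r^2, dim = rep(n, 3))
}

# assemble a phase label map from seed and soil masks (the rest is air)
make_labels <- function(seed, soil, voxel_size_um) {
  lab <- array(0L, dim = dim(seed))
  lab[soil] <- 1L
  lab[seed] <- 2L
  phase_label_map(lab, voxel_size_um)
}
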