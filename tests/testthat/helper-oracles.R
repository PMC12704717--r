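# Independent brute-force oracles. These deliberately use the simplest
# possible algorithms (plain distance marking, queue-based flood fill,
# rotation-grid search) and share no code with the package implementation.

# Enclosed probe-accessible cavities by flood fill: voxels farther than
# (vdw + probe) from every atom are free; free voxels 6-connected to the
# grid boundary are bulk solvent; the rest are enclosed cavity voxels,
# labelled into connected components. Returns component volumes (A^3),
# largest first.
oracle_enclosed_volumes <- function(xyz, radii, probe, spacing,
                                    padding = 2) {
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  ax <- lapply(1:3, function(d) seq(lo[d], hi[d], by = spacing))
  nd <- vapply(ax, length, integer(1))
  free <- array(TRUE, nd)
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + probe
    rng <- lapply(1:3, function(d) which(abs(ax[[d]] - xyz[a, d]) <= r))
    if (any(lengths(rng) == 0)) next
    sub <- outer(outer((ax[[1]][rng[[1]]] - xyz[a, 1])^2,
                       (ax[[2]][rng[[2]]] - xyz[a, 2])^2, `+`),
                 (ax[[3]][rng[[3]]] - xyz[a, 3])^2, `+`) <= r^2
    blk <- free[rng[[1]], rng[[2]], rng[[3]]]
    blk[sub] <- FALSE
    free[rng[[1]], rng[[2]], rng[[3]]] <- blk
  }
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  nxy <- nx * ny
  # queue-based BFS over linear indices with 6-neighbour steps
  bfs <- function(seeds, open) {
    seen <- logical(length(open))
    frontier <- seeds[open[seeds] & !seen[seeds]]
    seen[frontier] <- TRUE
    while (length(frontier) > 0) {
      iz <- (frontier - 1L) %/% nxy
      rem <- (frontier - 1L) %% nxy
      iy <- rem %/% nx
      ix <- rem %% nx
      nbrs <- c(frontier[ix > 0L] - 1L, frontier[ix < nx - 1L] + 1L,
                frontier[iy > 0L] - nx, frontier[iy < ny - 1L] + nx,
                frontier[iz > 0L] - nxy, frontier[iz < nz - 1L] + nxy)
      nbrs <- unique(nbrs[open[nbrs] & !seen[nbrs]])
      seen[nbrs] <- TRUE
      frontier <- nbrs
    }
    seen
  }
  idx <- array(seq_len(prod(nd)), nd)
  boundary <- c(idx[c(1, nx), , ], idx[, c(1, ny), ], idx[, , c(1, nz)])
  outside <- bfs(boundary, as.vector(free))
  enclosed <- as.vector(free) & !outside
  vols <- numeric(0)
  remaining <- which(enclosed)
  while (length(remaining) > 0) {
    comp <- bfs(remaining[1], enclosed)
    vols <- c(vols, sum(comp) * spacing^3)
    enclosed[comp] <- FALSE
    remaining <- which(enclosed)
  }
  sort(vols, decreasing = TRUE)
}

# Best rigid-superposition RMSD by rotation-grid search plus Nelder-Mead
# refinement over Euler angles, centroids removed analytically.
oracle_min_rmsd <- function(P, Q, grid_step = pi / 12) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  }
  f <- function(a) sqrt(mean(rowSums((P0 %*% t(rotmat(a)) - Q0)^2)))
  angs <- as.matrix(expand.grid(seq(0, 2 * pi, by = grid_step),
                                seq(0, pi, by = grid_step),
                                seq(0, 2 * pi, by = grid_step)))
  vals <- apply(angs, 1, f)
  best <- angs[which.min(vals), ]
  stats::optim(best, f, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}
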