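#' Grid specification for dual-probe cavity detection
#'
#' Parameters of the grid method: lattice spacing, the small probe (water,
#' 1.4 A) that defines accessible space, the large probe (4.0 A) whose
#' exclusion zone separates internal voids from bulk solvent, the minimum
#' volume a component must reach to be reported, and the padding added
#' around the atomic bounding box, which gives the large probe room to roam
#' the bulk solvent around the structure.
#'
#' @param spacing Lattice spacing in A, 0 < spacing <= probe_in.
#' @param probe_in Small probe radius in A.
#' @param probe_out Large probe radius in A, > probe_in.
#' @param min_cavity_volume Minimum reported cavity volume, A^3.
#' @param padding Grid padding beyond the atom bounding box, A (default
#'   `probe_out`).
#' @param max_points Grid-point budget; larger grids raise an error advising
#'   a coarser spacing.
#' @return A list of class `"grid_spec"`.
#' @export
#' @examples
#' grid_spec()
#' grid_spec(spacing = 0.4)
grid_spec <- function(spacing = 0.6, probe_in = 1.4, probe_out = 4.0,
                      min_cavity_volume = 5.0, padding = probe_out,
                      max_points = 2.5e7) {
  if (!(spacing > 0 && spacing <= probe_in)) {
    stop("need 0 < spacing <= probe_in", call. = FALSE)
  }
  if (probe_out <= probe_in) stop("need probe_out > probe_in", call. = FALSE)
  stopifnot(min_cavity_volume >= 0, padding > 0, max_points > 0)
  structure(list(spacing = spacing, probe_in = probe_in,
                 probe_out = probe_out,
                 min_cavity_volume = min_cavity_volume,
                 padding = padding, max_points = max_points),
            class = "grid_spec")
}

# Regular lattice covering the atoms' bounding box plus padding.
make_lattice <- function(xyz, spacing, padding, max_points) {
  lo <- apply(xyz, 2L, min) - padding
  hi <- apply(xyz, 2L, max) + padding
  axes <- lapply(1:3, function(d) seq(lo[d], hi[d], by = spacing))
  dims <- vapply(axes, length, integer(1L))
  if (prod(as.numeric(dims)) > max_points) {
    stop(sprintf(paste0("grid of %.3g points exceeds the budget of %.3g; ",
                        "use a coarser spacing"),
                 prod(as.numeric(dims)), max_points), call. = FALSE)
  }
  list(axes = axes, dims = dims)
}

# Logical vector over the lattice (column-major x,y,z order): TRUE where the
# point lies within (vdw + extra) of any atom. Per-atom subgrid marking keeps
# this O(atoms x local voxels).
mark_within <- function(lattice, xyz, radii, extra) {
  ax <- lattice$axes
  nd <- lattice$dims
  h <- ax[[1L]][2L] - ax[[1L]][1L]
  excl <- logical(prod(nd))
  nxy <- nd[1L] * nd[2L]
  for (a in seq_len(nrow(xyz))) {
    r <- radii[a] + extra
    rng <- lapply(1:3, function(d) {
      i1 <- max(1L, ceiling((xyz[a, d] - r - ax[[d]][1L]) / h) + 1L)
      i2 <- min(nd[d], floor((xyz[a, d] + r - ax[[d]][1L]) / h) + 1L)
      if (i1 > i2) integer(0) else i1:i2
    })
    if (any(lengths(rng) == 0L)) next
    d2 <- lapply(1:3, function(d) (ax[[d]][rng[[d]]] - xyz[a, d])^2)
    na <- length(rng[[1L]]); nb <- length(rng[[2L]]); nc <- length(rng[[3L]])
    tot <- rep(d2[[1L]], times = nb * nc) +
      rep(rep(d2[[2L]], each = na), times = nc) +
      rep(d2[[3L]], each = na * nb)
    lin <- rep(rng[[1L]], times = nb * nc) +
      (rep(rep(rng[[2L]], each = na), times = nc) - 1L) * nd[1L] +
      (rep(rng[[3L]], each = na * nb) - 1L) * nxy
    excl[lin[tot <= r * r]] <- TRUE
  }
  excl
}

# Free-region voxels (6-connected) reachable from the grid boundary, by
# raster-scan propagation: directional sweeps along each axis are iterated
# to a fixpoint. Each sweep propagates reachability all the way along its
# axis, so only a handful of iterations are needed.
flood_from_boundary <- function(free, dims) {
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  reach <- array(FALSE, dims)
  reach[c(1L, nx), , ] <- free[c(1L, nx), , ]
  reach[, c(1L, ny), ] <- reach[, c(1L, ny), ] | free[, c(1L, ny), ]
  reach[, , c(1L, nz)] <- reach[, , c(1L, nz)] | free[, , c(1L, nz)]
  repeat {
    before <- sum(reach)
    for (x in 2:nx) reach[x, , ] <- reach[x, , ] | (reach[x - 1L, , ] & free[x, , ])
    for (x in (nx - 1L):1L) reach[x, , ] <- reach[x, , ] | (reach[x + 1L, , ] & free[x, , ])
    for (y in 2:ny) reach[, y, ] <- reach[, y, ] | (reach[, y - 1L, ] & free[, y, ])
    for (y in (ny - 1L):1L) reach[, y, ] <- reach[, y, ] | (reach[, y + 1L, ] & free[, y, ])
    for (z in 2:nz) reach[, , z] <- reach[, , z] | (reach[, , z - 1L] & free[, , z])
    for (z in (nz - 1L):1L) reach[, , z] <- reach[, , z] | (reach[, , z + 1L] & free[, , z])
    if (sum(reach) == before) break
  }
  reach
}

# Binary dilation of a voxel mask by a Euclidean ball of radius r_vox
# (in voxel units), via shifted ORs over the ball stencil. Large radii are
# composed from several passes of smaller balls (Minkowski sums), trading
# at most a voxel of rounding per pass for a much smaller stencil.
dilate_ball <- function(mask, dims, r_vox, max_pass_radius = 4.5) {
  passes <- max(1L, ceiling(r_vox / max_pass_radius))
  rp <- r_vox / passes
  k <- floor(rp)
  offs <- as.matrix(expand.grid(dx = -k:k, dy = -k:k, dz = -k:k))
  offs <- offs[rowSums(offs^2) <= rp^2 & rowSums(abs(offs)) > 0L, ,
               drop = FALSE]
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  for (p in seq_len(passes)) {
    out <- mask
    for (o in seq_len(nrow(offs))) {
      dx <- offs[o, 1L]; dy <- offs[o, 2L]; dz <- offs[o, 3L]
      tx <- (1L + max(dx, 0L)):(nx + min(dx, 0L))
      ty <- (1L + max(dy, 0L)):(ny + min(dy, 0L))
      tz <- (1L + max(dz, 0L)):(nz + min(dz, 0L))
      out[tx, ty, tz] <- out[tx, ty, tz] |
        mask[tx - dx, ty - dy, tz - dz]
    }
    mask <- out
  }
  mask
}

# 26-connected components of a set of lattice points given as linear indices.
# Returns an integer component label per point and a per-component flag for
# touching the grid boundary.
label_components <- function(lin, dims) {
  n <- length(lin)
  nx <- dims[1L]; ny <- dims[2L]; nz <- dims[3L]
  nxy <- nx * ny
  iz <- (lin - 1L) %/% nxy + 1L
  rem <- (lin - 1L) %% nxy
  iy <- rem %/% nx + 1L
  ix <- rem %% nx + 1L
  rank <- integer(nx * ny * nz)
  rank[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  comp <- integer(n)
  touches <- logical(0)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    frontier <- s
    while (length(frontier) > 0L) {
      nbr <- integer(0)
      for (o in seq_len(nrow(offs))) {
        jx <- ix[frontier] + offs[o, 1L]
        jy <- iy[frontier] + offs[o, 2L]
        jz <- iz[frontier] + offs[o, 3L]
        ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny & jz >= 1L & jz <= nz
        if (!any(ok)) next
        r <- rank[jx[ok] + (jy[ok] - 1L) * nx + (jz[ok] - 1L) * nxy]
        r <- r[r > 0L]
        r <- r[comp[r] == 0L]
        if (length(r)) {
          comp[r] <- ncomp
          nbr <- c(nbr, r)
        }
      }
      frontier <- unique(nbr)
    }
    m <- comp == ncomp
    touches[ncomp] <- any(ix[m] == 1L | ix[m] == nx |
                            iy[m] == 1L | iy[m] == ny |
                            iz[m] == 1L | iz[m] == nz)
  }
  list(comp = comp, touches = touches, ix = ix, iy = iy, iz = iz)
}

#' Detect internal cavities by the dual-probe grid method
#'
#' Lays a regular lattice over the structure (bounding box plus padding) and
#' classifies each point. A point is accessible to the small probe (water)
#' if it lies farther than (vdW + probe_in) from every atom. The large probe
#' is rolled in from bulk solvent: its allowed centre positions (farther
#' than vdW + probe_out from every atom) are flood-filled from the grid
#' boundary and the probe volume is swept around them. Candidate cavity
#' points are small-probe accessible but outside the swept large-probe
#' region — this interior-filling classification is the one the dual-probe
#' cavity method family uses, and keeps the cores of cavities wider than the
#' large probe. Candidates' 26-connected components are computed; components
#' touching the grid boundary and components below `min_cavity_volume` are
#' discarded. Volume is point count times spacing cubed.
#'
#' @param struct An [opsin_structure()].
#' @param grid A [grid_spec()].
#' @return An object of class `"cavity_set"`: a list with `cavities` (each
#'   with `volume`, `n_points`, `points` coordinate matrix, `centroid`),
#'   sorted by decreasing volume, plus `cavity_count` and the `grid` echo.
#' @export
#' @examples
#' shell <- generate_toy_structure(10, 1.7, 1000)
#' cs <- detect_cavities(shell, grid_spec())
#' cs$cavity_count
detect_cavities <- function(struct, grid = grid_spec()) {
  stopifnot(inherits(struct, "opsin_structure"), inherits(grid, "grid_spec"))
  xyz <- struct_xyz(struct)
  lat <- make_lattice(xyz, grid$spacing, grid$padding, grid$max_points)
  small_excl <- mark_within(lat, xyz, struct$vdw, grid$probe_in)
  large_excl <- mark_within(lat, xyz, struct$vdw, grid$probe_out)
  big_free <- array(!large_excl, dim = lat$dims)
  outside_big <- flood_from_boundary(big_free, lat$dims)
  swept <- dilate_ball(outside_big, lat$dims, grid$probe_out / grid$spacing)
  cand <- which(!small_excl & !as.vector(swept))
  vol_per_pt <- grid$spacing^3
  cavities <- list()
  if (length(cand) > 0L) {
    lab <- label_components(cand, lat$dims)
    for (cc in seq_along(lab$touches)) {
      if (lab$touches[cc]) next
      m <- lab$comp == cc
      vol <- sum(m) * vol_per_pt
      if (vol < grid$min_cavity_volume) next
      pts <- cbind(x = lat$axes[[1L]][lab$ix[m]],
                   y = lat$axes[[2L]][lab$iy[m]],
                   z = lat$axes[[3L]][lab$iz[m]])
      cavities[[length(cavities) + 1L]] <-
        list(volume = vol, n_points = sum(m), points = pts,
             centroid = colMeans(pts))
    }
  }
  if (length(cavities) > 1L) {
    cavities <- cavities[order(vapply(cavities, `[[`, numeric(1L), "volume"),
                               decreasing = TRUE)]
  }
  structure(list(cavities = cavities, cavity_count = length(cavities),
                 grid = grid),
            class = "cavity_set")
}

#' @export
print.cavity_set <- function(x, ...) {
  cat(sprintf("Dual-probe cavity detection: %d cavity(ies) at %.2f A spacing\n",
              x$cavity_count, x$grid$spacing))
  for (i in seq_along(x$cavities)) {
    cat(sprintf("  [%d] volume %.1f A^3 (%d grid points)\n",
                i, x$cavities[[i]]$volume, x$cavities[[i]]$n_points))
  }
  invisible(x)
}

#' Van der Waals volume of a ligand by grid occupancy
#'
#' Volume of the union (not the sum) of the atoms' vdW spheres, counted on a
#' fine grid: occupied voxels times spacing cubed.
#'
#' @param ligand An [opsin_structure()] (or subset) with >= 1 atom.
#' @param spacing Grid spacing in A (default 0.25).
#' @param max_points Grid-point budget.
#' @return Volume in A^3.
#' @export
#' @examples
#' carbon <- opsin_structure(0, 0, 0, element = "C")
#' ligand_volume(carbon)  # ~ (4/3) pi 1.7^3 = 20.58
ligand_volume <- function(ligand, spacing = 0.25, max_points = 2.5e7) {
  stopifnot(inherits(ligand, "opsin_structure"))
  if (nrow(ligand) == 0L) stop("empty ligand selection", call. = FALSE)
  xyz <- struct_xyz(ligand)
  lat <- make_lattice(xyz, spacing, padding = max(ligand$vdw) + spacing,
                      max_points = max_points)
  occ <- mark_within(lat, xyz, ligand$vdw, extra = 0)
  sum(occ) * spacing^3
}

#' Water-molecule capacity of a volume
#'
#' floor(volume x 3.35e-2): the number of water molecules a cavity of the
#' given volume can hold at the bulk number density of liquid water
#' (1 g/mL, i.e. 3.35e-2 H2O per cubic Angstrom). The floor convention is
#' used, never rounding.
#'
#' @param volume Volume(s) in A^3, >= 0.
#' @param density Water number density in H2O/A^3; defaults to the standard
#'   3.35e-2 (see [h2o_per_cubic_angstrom()]).
#' @return Integer water count(s).
#' @export
#' @examples
#' water_capacity(1454.3)  # 48
#' water_capacity(842.4)   # 28
water_capacity <- function(volume, density = 3.35e-2) {
  if (any(volume < 0)) stop("'volume' must be >= 0", call. = FALSE)
  stopifnot(density > 0)
  as.integer(floor(volume * density))
}

#' Ligand-cavity volume and hydration-capacity report
#'
#' Computes the volume of the cavity that houses a ligand: the ligand's atoms
#' are removed from the occluder set, cavities are detected, and the cavity
#' containing the ligand centroid is selected (not simply the largest). The
#' gross volume counts the ligand's space as cavity; the ligand's own vdW
#' volume is subtracted to give the net (ligand-free) volume, from which the
#' water capacity follows by [water_capacity()].
#'
#' @param struct An [opsin_structure()] containing both protein and ligand
#'   atoms.
#' @param ligand Either an [opsin_structure()] of the ligand atoms or a
#'   residue name present in `struct$resid` (default `"LIG"`).
#' @param grid A [grid_spec()].
#' @param ligand_spacing Grid spacing for the ligand vdW volume, A.
#' @return An object of class `"cavity_report"`: `v_gross`, `v_ligand`,
#'   `v_net` (= v_gross - v_ligand), `n_water` (= floor(v_net x 3.35e-2)),
#'   `cavity_count`, `grid`.
#' @export
cavity_report <- function(struct, ligand = "LIG", grid = grid_spec(),
                          ligand_spacing = 0.25) {
  stopifnot(inherits(struct, "opsin_structure"))
  if (is.character(ligand)) {
    sel <- struct$resid %in% ligand
    if (!any(sel)) stop("no atoms with resid '", ligand, "'", call. = FALSE)
    lig <- struct[sel, , drop = FALSE]
    occluders <- struct[!sel, , drop = FALSE]
    class(lig) <- class(occluders) <- c("opsin_structure", "data.frame")
  } else {
    stopifnot(inherits(ligand, "opsin_structure"))
    lig <- ligand
    key <- function(s) paste(round(s$x, 6), round(s$y, 6), round(s$z, 6))
    occluders <- struct[!key(struct) %in% key(lig), , drop = FALSE]
    class(occluders) <- c("opsin_structure", "data.frame")
  }
  if (nrow(occluders) == 0L) stop("no occluder atoms left", call. = FALSE)

  cs <- detect_cavities(occluders, grid)
  cen <- colMeans(struct_xyz(lig))
  thr2 <- grid$spacing^2
  inside <- vapply(cs$cavities, function(cv) {
    min(colSums((t(cv$points) - cen)^2)) <= thr2
  }, logical(1L))
  if (sum(inside) == 0L) {
    stop(sprintf(paste0("ligand centroid lies in none of the %d detected ",
                        "cavity(ies) (volumes: %s A^3)"),
                 cs$cavity_count,
                 paste(signif(vapply(cs$cavities, `[[`, numeric(1L),
                                     "volume"), 4), collapse = ", ")),
         call. = FALSE)
  }
  if (sum(inside) > 1L) {
    stop("ligand centroid is ambiguous between multiple cavities",
         call. = FALSE)
  }
  v_gross <- cs$cavities[[which(inside)]]$volume
  v_lig <- ligand_volume(lig, spacing = ligand_spacing)
  v_net <- v_gross - v_lig
  structure(
    list(v_gross = v_gross, v_ligand = v_lig, v_net = v_net,
         n_water = water_capacity(max(v_net, 0)),
         cavity_count = cs$cavity_count, grid = grid),
    class = "cavity_report"
  )
}

#' @export
print.cavity_report <- function(x, ...) {
  cat(sprintf("Cavity report: gross %.1f A^3 - ligand %.1f A^3 = net %.1f A^3\n",
              x$v_gross, x$v_ligand, x$v_net))
  cat(sprintf("  water capacity: %d H2O (of %d cavity(ies) detected)\n",
              x$n_water, x$cavity_count))
  invisible(x)
}
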