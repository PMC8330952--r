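#' Mesh specification for the hemispherical shell
#'
#' The simulated cell is a stationary hemisphere sitting on the `z = 0` plane
#' (dome in `z > 0`). Only a thin shell under the boundary -- the plasma
#' membrane plus the cytoskeletal cortex -- is discretized; the deep cytosol
#' is not meshed. All lengths are micrometres.
#'
#' @param radius cell radius (default 5).
#' @param shell_thickness thickness of the meshed membrane/cortex shell
#'   (default 0.2, i.e. 200 nm).
#' @param h_min,h_max allowable distances between mesh nodes (defaults 0.1
#'   and 0.3). The mesher aims its lateral spacing near `h_max`.
#' @param membrane_depth nodes within this distance of the outer boundary are
#'   classified as membrane nodes (default 0.02, i.e. 20 nm).
#' @param mesher_seed integer seed controlling the azimuthal phase jitter of
#'   the node rings.
#' @return an object of class `mesh_spec`.
#' @export
mesh_spec <- function(radius = 5, shell_thickness = 0.2,
                      h_min = 0.1, h_max = 0.3,
                      membrane_depth = 0.02, mesher_seed = 1L) {
  if (!(shell_thickness > 0 && shell_thickness < radius))
    stop("geometry error: need 0 < shell_thickness < radius")
  if (!(h_min > 0 && h_min <= h_max))
    stop("geometry error: need 0 < h_min <= h_max")
  if (!(membrane_depth > 0 && membrane_depth <= shell_thickness))
    stop("geometry error: need 0 < membrane_depth <= shell_thickness")
  structure(list(radius = radius, shell_thickness = shell_thickness,
                 h_min = h_min, h_max = h_max,
                 membrane_depth = membrane_depth,
                 mesher_seed = as.integer(mesher_seed)),
            class = "mesh_spec")
}

## ---- surface triangulation by latitude/radius rings -------------------------

## Bridge two concentric closed rings of points into a triangle strip.
## ia/ib: global node indices ordered by angle; aa/ab: their angles.
## Returns (na+nb) x 3 integer matrix.
bridge_rings <- function(ia, aa, ib, ab) {
  oa <- order(aa); ia <- ia[oa]; aa <- aa[oa]
  ob <- order(ab); ib <- ib[ob]; ab <- ab[ob]
  na <- length(ia); nb <- length(ib)
  ## rotate B so it starts near aa[1]
  j0 <- which.min((ab - aa[1]) %% (2 * pi))
  ord <- c(j0:nb, if (j0 > 1) 1:(j0 - 1))
  ib <- ib[ord]
  ab <- ab[ord]
  ab <- aa[1] + (ab - aa[1]) %% (2 * pi)    # unwrapped from aa[1]
  av <- c(aa, aa[1] + 2 * pi)
  bv <- c(ab, ab[1] + 2 * pi)
  A <- c(ia, ia[1]); B <- c(ib, ib[1])
  tri <- matrix(0L, na + nb, 3)
  i <- 1L; j <- 1L; k <- 0L
  while (i <= na || j <= nb) {
    advA <- i <= na && (j > nb || av[i + 1L] <= bv[j + 1L])
    k <- k + 1L
    if (advA) {
      tri[k, ] <- c(A[i], A[i + 1L], B[j]); i <- i + 1L
    } else {
      tri[k, ] <- c(B[j], B[j + 1L], A[i]); j <- j + 1L
    }
  }
  tri
}

## Fan from an apex point to a closed ring.
fan_ring <- function(apex, ib) {
  nb <- length(ib)
  cbind(apex, ib, ib[c(2:nb, 1L)], deparse.level = 0)
}

## Triangulate the outer boundary surface (dome + basal disk) of the
## hemisphere with target edge length h. Returns points (n x 3), triangles,
## and a per-point location code (1 dome, 2 rim, 3 disk).
surface_hemisphere <- function(R, h, seed = 1L) {
  rng <- local({ set.seed(seed); function(n) stats::runif(n) })
  pts <- matrix(numeric(0), 0, 3)
  loc <- integer(0)
  add_ring <- function(r, z, m, phase) {
    phi <- phase + 2 * pi * (seq_len(m) - 1L) / m
    idx <- nrow(pts) + seq_len(m)
    pts <<- rbind(pts, cbind(r * cos(phi), r * sin(phi), z))
    list(idx = idx, ang = phi %% (2 * pi))
  }
  tris <- list()

  ## dome: polar-angle rings from pole (theta = 0) to rim (theta = pi/2)
  ntheta <- max(2L, ceiling((pi / 2 * R) / h))
  pole <- 1L
  pts <- rbind(pts, c(0, 0, R)); loc <- c(loc, 1L)
  prev <- NULL
  rings <- vector("list", ntheta)
  for (k in seq_len(ntheta)) {
    th <- k * (pi / 2) / ntheta
    m <- max(6L, round(2 * pi * R * sin(th) / h))
    phase <- (k %% 2) * pi / m + 0.25 * (2 * pi / m) * (rng(1) - 0.5)
    rg <- add_ring(R * sin(th), R * cos(th), m, phase)
    loc <- c(loc, rep(if (k == ntheta) 2L else 1L, m))
    tris[[length(tris) + 1L]] <-
      if (is.null(prev)) fan_ring(pole, rg$idx)
      else bridge_rings(prev$idx, prev$ang, rg$idx, rg$ang)
    prev <- rg
    rings[[k]] <- rg
  }
  rim <- prev

  ## basal disk: radial rings from rim inward to the centre
  nr <- max(2L, ceiling(R / h))
  prev <- rim
  for (j in seq_len(nr - 1L)) {
    r <- R * (nr - j) / nr
    m <- max(6L, round(2 * pi * r / h))
    phase <- (j %% 2) * pi / m + 0.25 * (2 * pi / m) * (rng(1) - 0.5)
    rg <- add_ring(r, 0, m, phase)
    loc <- c(loc, rep(3L, m))
    tris[[length(tris) + 1L]] <- bridge_rings(prev$idx, prev$ang, rg$idx, rg$ang)
    prev <- rg
  }
  centre <- nrow(pts) + 1L
  pts <- rbind(pts, c(0, 0, 0)); loc <- c(loc, 3L)
  tris[[length(tris) + 1L]] <- fan_ring(centre, rev(prev$idx))

  list(points = pts, triangles = do.call(rbind, tris), loc = loc)
}

## ---- shell mesh -------------------------------------------------------------

tet_volumes <- function(vertices, tets) {
  p0 <- vertices[tets[, 1], , drop = FALSE]
  a <- vertices[tets[, 2], , drop = FALSE] - p0
  b <- vertices[tets[, 3], , drop = FALSE] - p0
  d <- vertices[tets[, 4], , drop = FALSE] - p0
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
         a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
         a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  det / 6
}

#' Build the hemispherical shell mesh
#'
#' Triangulates the outer boundary of the hemisphere (curved dome plus flat
#' basal disk) with edge length near `h_max`, extrudes the surface inward by
#' `shell_thickness` to form one layer of prisms, and splits each prism into
#' three tetrahedra with conforming diagonals. Nodal volumes are the
#' barycentric dual (a quarter of each incident tetrahedron); nodes are
#' classified membrane/cortex by depth under the outer boundary and
#' basal/apical by which boundary patch is nearest.
#'
#' @param spec a [mesh_spec()].
#' @return an object of class `shell_mesh` with fields `vertices`, `tets`,
#'   `nodal_volumes`, `node_class` (data.frame with factors `region` and
#'   `side`), `fem` (geometric jump-rate weights in CSR form) and `spec`.
#' @export
build_shell_mesh <- function(spec = mesh_spec()) {
  stopifnot(inherits(spec, "mesh_spec"))
  R <- spec$radius; t <- spec$shell_thickness
  surf <- surface_hemisphere(R, spec$h_max, spec$mesher_seed)
  n <- nrow(surf$points)

  ## inner copy of every surface node, offset along the inward boundary normal
  inner <- surf$points
  dome <- surf$loc == 1L; rimv <- surf$loc == 2L; disk <- surf$loc == 3L
  inner[dome, ] <- surf$points[dome, ] * (R - t) / R
  inner[disk, 3] <- inner[disk, 3] + t
  if (any(rimv)) {
    s <- t / sqrt(2)
    inner[rimv, 1:2] <- surf$points[rimv, 1:2] * (R - s) / R
    inner[rimv, 3] <- s
  }
  vertices <- rbind(surf$points, inner)

  ## split each prism (outer triangle + inner triangle) into 3 tets, with the
  ## classic sorted-vertex rule so that quad-face diagonals conform
  tr <- surf$triangles
  o <- t(apply(tr, 1, sort))
  v0 <- o[, 1]; v1 <- o[, 2]; v2 <- o[, 3]
  tets <- rbind(cbind(v0, v1, v2, v2 + n),
                cbind(v0, v1, v2 + n, v1 + n),
                cbind(v0, v1 + n, v2 + n, v0 + n))
  vol <- abs(tet_volumes(vertices, tets))
  if (any(vol <= 1e-12))
    stop("geometry error: degenerate tetrahedron in generated mesh")

  nodal <- dual_volumes_impl(tets, vol, nrow(vertices))
  cls <- classify_nodes_impl(vertices, spec)
  fem <- fem_jump_weights(vertices, tets, vol, nodal)

  structure(list(vertices = vertices, tets = tets,
                 tet_volumes = vol, nodal_volumes = nodal,
                 node_class = cls, fem = fem, spec = spec),
            class = "shell_mesh")
}

dual_volumes_impl <- function(tets, vol, nv) {
  v <- numeric(nv)
  for (k in 1:4) {
    s <- rowsum(vol / 4, tets[, k])
    i <- as.integer(rownames(s))
    v[i] <- v[i] + s[, 1]
  }
  v
}

#' Barycentric dual volumes of a tetrahedral mesh
#'
#' Each tetrahedron's volume is apportioned equally to its four vertices.
#' The volumes partition the mesh: they are strictly positive and sum to the
#' total element volume.
#'
#' @param mesh a `shell_mesh`.
#' @return numeric vector of per-node volumes (micrometres cubed).
#' @export
dual_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "shell_mesh"))
  vol <- abs(tet_volumes(mesh$vertices, mesh$tets))
  if (any(vol <= 1e-12)) stop("geometry error: degenerate tetrahedron")
  dual_volumes_impl(mesh$tets, vol, nrow(mesh$vertices))
}

classify_nodes_impl <- function(vertices, spec) {
  R <- spec$radius
  r3 <- sqrt(rowSums(vertices^2))
  d_dome <- pmax(R - r3, 0)
  d_disk <- pmax(vertices[, 3], 0)
  depth <- pmin(d_dome, d_disk)
  region <- factor(ifelse(depth <= spec$membrane_depth + 1e-9,
                          "membrane", "cortex"),
                   levels = c("membrane", "cortex"))
  side <- factor(ifelse(vertices[, 3] <= spec$membrane_depth + 1e-9,
                        "basal", "apical"),
                 levels = c("basal", "apical"))
  data.frame(region = region, side = side)
}

#' Classify mesh nodes as membrane/cortex and basal/apical
#'
#' Membrane nodes lie within `membrane_depth` of the outer boundary (dome or
#' basal disk); all others are cortex nodes. A node is basal when its height
#' above the substrate plane is within `membrane_depth`, apical otherwise.
#'
#' @param mesh a `shell_mesh`.
#' @param spec a [mesh_spec()]; defaults to the one the mesh was built with.
#' @return data.frame with factor columns `region` and `side`.
#' @export
classify_nodes <- function(mesh, spec = mesh$spec) {
  stopifnot(inherits(mesh, "shell_mesh"))
  classify_nodes_impl(mesh$vertices, spec)
}

## ---- diffusion jump rates ---------------------------------------------------

## Linear finite-element stiffness assembly; returns the geometric jump-rate
## weights w_ij = max(0, -K_ij) / V_i in CSR form, with the number of clamped
## (positive off-diagonal) entries recorded. A species with diffusion
## constant D hops i -> j at rate D * w_ij.
fem_jump_weights <- function(vertices, tets, vol, nodal) {
  p0 <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - p0
  e2 <- vertices[tets[, 3], , drop = FALSE] - p0
  e3 <- vertices[tets[, 4], , drop = FALSE] - p0
  ## rows of inv(M)' where M = [e1; e2; e3]: gradients of barycentric coords
  cx <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  det <- rowSums(e1 * cx(e2, e3))
  g1 <- cx(e2, e3) / det
  g2 <- cx(e3, e1) / det
  g3 <- cx(e1, e2) / det
  g0 <- -(g1 + g2 + g3)
  G <- list(g0, g1, g2, g3)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (a in 1:3) for (b in (a + 1):4) {
    k <- vol * rowSums(G[[a]] * G[[b]])
    ii <- c(ii, tets[, a], tets[, b])
    jj <- c(jj, tets[, b], tets[, a])
    xx <- c(xx, k, k)
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(vertices), nrow(vertices)))
  Ks <- methods::as(K, "TsparseMatrix")
  keep <- Ks@i != Ks@j
  i <- Ks@i[keep] + 1L; j <- Ks@j[keep] + 1L; x <- Ks@x[keep]
  clamped <- sum(x > 0)
  w <- pmax(0, -x) / nodal[i]
  nz <- w > 0
  csr_from_triplets(i[nz], j[nz], w[nz], length(nodal), clamped)
}

csr_from_triplets <- function(i, j, w, n, clamped = 0L) {
  ord <- order(i, j)
  i <- i[ord]; j <- j[ord]; w <- w[ord]
  ptr <- c(0L, cumsum(tabulate(i, n)))
  wsum <- numeric(n)
  s <- rowsum(w, i)
  wsum[as.integer(rownames(s))] <- s[, 1]
  structure(list(ptr = ptr, idx = j, w = w, wsum = wsum, n = n,
                 clamped = clamped),
            class = "jump_graph")
}

#' Per-species diffusion jump-rate operator
#'
#' Rates follow the finite-element convention for master-equation diffusion on
#' an unstructured mesh: assemble the linear P1 stiffness matrix `K` and set
#' the rate of a single molecule hopping from voxel `i` to voxel `j` to
#' `D * max(0, -K_ij) / V_i`. Positive off-diagonal stiffness entries (obtuse
#' tetrahedra) are clamped to zero; the count is recorded in the result. The
#' construction satisfies detailed balance with respect to the nodal volumes,
#' so the stationary distribution of a diffusing tracer is proportional to
#' them.
#'
#' @param mesh a `shell_mesh` or a `voxel_graph` fixture.
#' @param D diffusion constant (micrometres squared per second), `D >= 0`.
#' @param nodes optional integer vector restricting the species to a subset of
#'   nodes (jumps leaving the subset are removed).
#' @return a `jump_operator`: CSR fields `ptr`, `idx`, `rate` (s^-1),
#'   `rate_sum`, plus `nodes` and `D`.
#' @export
diffusion_jump_rates <- function(mesh, D, nodes = NULL) {
  if (D < 0) stop("D must be non-negative")
  g <- jump_graph(mesh, nodes)
  structure(list(ptr = g$ptr, idx = g$idx, rate = D * g$w,
                 rate_sum = D * g$wsum, nodes = g$nodes, n = g$n, D = D),
            class = "jump_operator")
}

## Geometric jump weights (rate / D) of a mesh, optionally restricted to a
## node subset. Returns a `jump_graph` whose idx values are indices into the
## full node set.
jump_graph <- function(mesh, nodes = NULL) {
  g <- if (inherits(mesh, "shell_mesh")) mesh$fem
       else if (inherits(mesh, "voxel_graph")) mesh$fem
       else stop("unsupported mesh object")
  if (is.null(nodes)) {
    g$nodes <- seq_len(g$n)
    return(g)
  }
  nodes <- sort(unique(as.integer(nodes)))
  keep <- logical(g$n); keep[nodes] <- TRUE
  ii <- rep.int(seq_len(g$n), diff(g$ptr))
  sel <- keep[ii] & keep[g$idx]
  gg <- csr_from_triplets(ii[sel], g$idx[sel], g$w[sel], g$n, g$clamped)
  gg$nodes <- nodes
  gg
}

#' Jump operator as a sparse generator matrix
#'
#' Returns the infinitesimal generator `Q` (rates off-diagonal, negative row
#' sums on the diagonal) of the single-molecule jump chain, useful for
#' stationary-distribution and relaxation analyses.
#'
#' @param op a `jump_operator`.
#' @return a `dgCMatrix`.
#' @export
jump_generator <- function(op) {
  ii <- rep.int(seq_len(op$n), diff(op$ptr))
  Matrix::sparseMatrix(i = c(ii, seq_len(op$n)),
                       j = c(op$idx, seq_len(op$n)),
                       x = c(op$rate, -op$rate_sum),
                       dims = c(op$n, op$n))
}

## ---- toy voxel graphs (test fixtures) --------------------------------------

#' Toy voxel-chain fixture
#'
#' A linear chain of `n` well-stirred voxels with explicit finite-volume hop
#' weights `w_ij = A / (h * V_i)`, the closed-form rate for a structured pair
#' of voxels sharing a face of area `A` at centroid distance `h`. Used as a
#' small, analytically tractable stand-in for a mesh in engine tests.
#'
#' @param n number of voxels.
#' @param volumes per-voxel volumes (recycled), micrometres cubed.
#' @param area shared face area, `h` centroid distance.
#' @param h centroid distance between neighbouring voxels.
#' @return an object of class `voxel_graph` with `nodal_volumes`, `fem`
#'   (geometric weights) and a trivial `node_class`.
#' @export
voxel_chain <- function(n, volumes = 1, area = 1, h = 1) {
  volumes <- rep_len(volumes, n)
  if (n > 1) {
    i <- c(seq_len(n - 1L), 2:n)
    j <- c(2:n, seq_len(n - 1L))
    w <- area / (h * volumes[i])
    fem <- csr_from_triplets(i, j, w, n)
  } else {
    fem <- csr_from_triplets(integer(0), integer(0), numeric(0), 1L)
  }
  structure(list(nodal_volumes = volumes, fem = fem,
                 node_class = data.frame(
                   region = factor(rep("membrane", n),
                                   levels = c("membrane", "cortex")),
                   side = factor(rep("basal", n),
                                 levels = c("basal", "apical")))),
            class = "voxel_graph")
}

## ---- summaries --------------------------------------------------------------

#' @export
print.shell_mesh <- function(x, ...) {
  cls <- table(x$node_class$region)
  cat(sprintf(paste0(
    "Hemispherical shell mesh: %d nodes, %d tetrahedra\n",
    "  radius %.2f um, shell %.0f nm, total volume %.2f um^3\n",
    "  nodal volume %.3g +/- %.2g um^3 (mean +/- sd)\n",
    "  %d membrane / %d cortex nodes; %d clamped stiffness entries\n"),
    nrow(x$vertices), nrow(x$tets),
    x$spec$radius, 1000 * x$spec$shell_thickness, sum(x$tet_volumes),
    mean(x$nodal_volumes), stats::sd(x$nodal_volumes),
    cls[["membrane"]], cls[["cortex"]], x$fem$clamped))
  invisible(x)
}

#' Total mesh volume
#' @param mesh a `shell_mesh`.
#' @return sum of element volumes (micrometres cubed).
#' @export
mesh_volume <- function(mesh) sum(abs(tet_volumes(mesh$vertices, mesh$tets)))

#' Closed-form shell volume approximation
#'
#' Analytic volume of the meshed region: the spherical-dome shell plus the
#' basal slab, with the rim bevel correction for the chamfered corner where
#' the two meet. Used as an independent oracle for mesh volume checks.
#'
#' @param spec a [mesh_spec()].
#' @export
shell_volume_analytic <- function(spec) {
  R <- spec$radius; t <- spec$shell_thickness
  dome <- 2 * pi / 3 * (R^3 - (R - t)^3)
  s <- t / sqrt(2)
  slab <- pi * (R - s)^2 * t
  ## rim bevel: the extruded corner ring tapers between dome and slab
  bevel <- 2 * pi * (R - s) * (t * s / 2)
  dome + slab + bevel
}

#' Node indices by class
#' @param mesh a `shell_mesh` or `voxel_graph`.
#' @param region `"membrane"`, `"cortex"` or `"all"`.
#' @param side optional `"basal"` or `"apical"`.
#' @export
nodes_of <- function(mesh, region = "all", side = NULL) {
  nc <- mesh$node_class
  sel <- if (region == "all") rep(TRUE, nrow(nc)) else nc$region == region
  if (!is.null(side)) sel <- sel & nc$side == side
  which(sel)
}
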