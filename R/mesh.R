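# Triangulated-mesh oracles: independent discrete-differential-geometry
# estimators (triangle-area sums, divergence-theorem volumes, angle-defect
# Gaussian curvature, cotangent-Laplacian mean curvature) used to verify the
# analytic/quadrature machinery. Fixture generation is fully deterministic
# from the resolution parameters. These live beside the model, never inside
# the minimizer's hot path.

new_mesh <- function(vertices, faces, provenance = "mesh") {
  structure(list(vertices = vertices, faces = faces, provenance = provenance),
            class = "cp_mesh")
}

#' @export
print.cp_mesh <- function(x, ...) {
  cat(sprintf("<cp_mesh> %s: %d vertices, %d faces\n", x$provenance,
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Flip face orientation if the signed volume is negative (closed meshes are
# kept outward-oriented).
orient_outward <- function(m) {
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

mesh_signed_volume <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
        v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
        v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Triangulated mesh fixtures
#'
#' Deterministic latitude-longitude style triangulations: a closed oblate
#' spheroid, an open tube (one-sheet elliptic hyperboloid segment with two
#' boundary rings), a closed torus, and a closed genus-2 double torus (two
#' tori joined by a handle). Closed meshes are watertight and outward
#' oriented.
#'
#' @param a,c spheroid radii, nm.
#' @param n resolution (rings/segments; `n >= 8`).
#' @param tube a `cp_tube` from [solve_tube_junction()].
#' @param R,r torus major and minor radii, nm.
#' @return A `cp_mesh`: list with `vertices` (N x 3) and `faces` (M x 3,
#'   1-based indices).
#' @export
#' @examples
#' m <- mesh_spheroid(1, 1, 32)
#' mesh_area(m) / (4 * pi)   # ~1
mesh_spheroid <- function(a, c, n = 64) {
  check_spheroid(a, c)
  if (n < 8) abort("Mesh resolution n must be >= 8.", class = "cellplate_validation_error")
  nth <- n; nph <- n
  th <- seq_len(nth - 1) * pi / nth
  ph <- (seq_len(nph) - 1) * 2 * pi / nph
  ring <- function(t) cbind(a * sin(t) * cos(ph), a * sin(t) * sin(ph),
                            c * cos(t))
  verts <- rbind(c(0, 0, c), do.call(rbind, lapply(th, ring)), c(0, 0, -c))
  idx <- function(i, j) 1 + (i - 1) * nph + ((j - 1) %% nph) + 1  # ring i, col j
  faces <- list()
  faces[[1]] <- cbind(1, idx(1, seq_len(nph)), idx(1, seq_len(nph) + 1))
  for (i in seq_len(nth - 2)) {
    j <- seq_len(nph)
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  south <- nrow(verts)
  faces[[length(faces) + 1]] <- cbind(south, idx(nth - 1, seq_len(nph) + 1),
                                      idx(nth - 1, seq_len(nph)))
  orient_outward(new_mesh(verts, do.call(rbind, faces),
                          sprintf("spheroid(a=%g, c=%g, n=%d)", a, c, n)))
}

#' @rdname mesh_spheroid
#' @export
mesh_tube <- function(tube, n = 64) {
  check_tube(tube)
  if (n < 8) abort("Mesh resolution n must be >= 8.", class = "cellplate_validation_error")
  nx <- n; nph <- n
  xs <- seq(-tube$l / 2, tube$l / 2, length.out = nx + 1)
  ph <- (seq_len(nph) - 1) * 2 * pi / nph
  u <- tube$asym^2
  verts <- do.call(rbind, lapply(xs, function(x) {
    A <- tube$ah * sqrt(1 + x^2 / u)
    cbind(x, A * cos(ph), tube$bh / tube$ah * A * sin(ph))
  }))
  idx <- function(i, j) (i - 1) * nph + ((j - 1) %% nph) + 1
  faces <- list()
  for (i in seq_len(nx)) {
    j <- seq_len(nph)
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j))
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1))
  }
  new_mesh(verts, do.call(rbind, faces),
           sprintf("tube(ah=%g, bh=%g, l=%g, n=%d)", tube$ah, tube$bh,
                   tube$l, n))
}

#' @rdname mesh_spheroid
#' @export
mesh_torus <- function(R, r, n = 64) {
  if (R <= r || r <= 0) {
    abort("Torus needs R > r > 0.", class = "cellplate_validation_error")
  }
  if (n < 8) abort("Mesh resolution n must be >= 8.", class = "cellplate_validation_error")
  uu <- (seq_len(n) - 1) * 2 * pi / n   # major angle
  vv <- (seq_len(n) - 1) * 2 * pi / n   # minor angle
  verts <- do.call(rbind, lapply(uu, function(u) {
    cbind((R + r * cos(vv)) * cos(u), (R + r * cos(vv)) * sin(u),
          r * sin(vv))
  }))
  idx <- function(i, j) ((i - 1) %% n) * n + ((j - 1) %% n) + 1
  faces <- list()
  for (i in seq_len(n)) {
    j <- seq_len(n)
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  orient_outward(new_mesh(verts, do.call(rbind, faces),
                          sprintf("torus(R=%g, r=%g, n=%d)", R, r, n)))
}

# Remove the star of vertex v; return mesh plus the ordered directed boundary
# loop (in the orientation of the removed faces).
remove_vertex_star <- function(m, v) {
  inc <- which(rowSums(m$faces == v) > 0)
  star <- m$faces[inc, , drop = FALSE]
  # directed edge opposite v in each face, preserving face orientation
  opp <- t(apply(star, 1, function(f) {
    i <- which(f == v)
    f[c(i %% 3 + 1, (i + 1) %% 3 + 1)]
  }))
  loop <- opp[1, ]
  opp <- opp[-1, , drop = FALSE]
  while (nrow(opp) > 0) {
    nxt <- which(opp[, 1] == loop[length(loop)])
    if (length(nxt) != 1) abort("Vertex star is not a disk.", class = "cellplate_mesh_error")
    loop <- c(loop, opp[nxt, 2])
    opp <- opp[-nxt, , drop = FALSE]
  }
  if (loop[1] != loop[length(loop)]) {
    abort("Vertex star boundary is not a closed loop.", class = "cellplate_mesh_error")
  }
  m$faces <- m$faces[-inc, , drop = FALSE]
  list(mesh = m, loop = loop[-length(loop)])
}

#' @rdname mesh_spheroid
#' @param gap clearance between the two tori of the genus-2 fixture, nm.
#' @export
mesh_genus2 <- function(R = 3, r = 1, n = 32, gap = NULL) {
  gap <- gap %||% r
  m1 <- mesh_torus(R, r, n)
  m2 <- mesh_torus(R, r, n)
  shift <- 2 * (R + r) + gap
  m2$vertices[, 1] <- m2$vertices[, 1] + shift
  # vertices facing each other: outermost point on +x of torus 1, -x of torus 2
  v1 <- which.max(m1$vertices[, 1])
  v2 <- which.min(m2$vertices[, 1])
  s1 <- remove_vertex_star(m1, v1)
  s2 <- remove_vertex_star(m2, v2)
  off <- nrow(m1$vertices)
  verts <- rbind(s1$mesh$vertices, s2$mesh$vertices)
  faces <- rbind(s1$mesh$faces, s2$mesh$faces + off)
  loop1 <- s1$loop
  loop2 <- rev(s2$loop) + off
  # rotate loop2 so its start is nearest loop1's start (minimal twist)
  d <- colSums((t(verts[loop2, , drop = FALSE]) - verts[loop1[1], ])^2)
  loop2 <- c(loop2[which.min(d):length(loop2)],
             loop2[seq_len(which.min(d) - 1)])
  k <- length(loop1)
  if (length(loop2) != k) abort("Handle loops differ in length.", class = "cellplate_mesh_error")
  nxt <- function(i) i %% k + 1
  bridge <- do.call(rbind, lapply(seq_len(k), function(i) {
    rbind(c(loop1[i], loop1[nxt(i)], loop2[nxt(i)]),
          c(loop1[i], loop2[nxt(i)], loop2[i]))
  }))
  faces <- rbind(faces, bridge)
  # drop the two orphaned star centers and reindex
  keep <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[faces], ncol = 3)
  new_mesh(verts[keep, , drop = FALSE], faces,
           sprintf("genus2(R=%g, r=%g, n=%d)", R, r, n))
}

mesh_edge_table <- function(m) {
  f <- m$faces
  und <- rbind(cbind(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
               cbind(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
               cbind(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])))
  key <- paste(und[, 1], und[, 2])
  table(key)
}

#' Watertightness and boundary of a mesh
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces. `mesh_boundary_vertices()` returns indices of vertices on edges
#' shared by a single face (the boundary rings of open tube meshes).
#'
#' @param m a `cp_mesh`.
#' @return Logical / integer vector.
#' @export
mesh_is_watertight <- function(m) {
  all(mesh_edge_table(m) == 2)
}

#' @rdname mesh_is_watertight
#' @export
mesh_boundary_vertices <- function(m) {
  tab <- mesh_edge_table(m)
  b <- names(tab)[tab == 1]
  if (length(b) == 0) return(integer())
  sort(unique(as.integer(unlist(strsplit(b, " ")))))
}

face_geometry <- function(m) {
  v1 <- m$vertices[m$faces[, 1], , drop = FALSE]
  v2 <- m$vertices[m$faces[, 2], , drop = FALSE]
  v3 <- m$vertices[m$faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(nrm^2))
  list(v1 = v1, v2 = v2, v3 = v3, normal = nrm, area = area2 / 2)
}

#' Discrete estimators on triangle meshes
#'
#' `mesh_area()` sums triangle areas; `mesh_volume()` integrates the
#' divergence theorem (watertight meshes only); `mesh_gauss_total()` sums
#' angle defects (`2 pi - sum of incident angles` at interior vertices,
#' `pi - sum` on boundaries), which equals `2 pi chi` exactly for closed
#' meshes -- this validates the topological Gauss-Bonnet shortcut of the
#' energy model; `mesh_bending_integral()` estimates
#' `integral (c1 + c2 - c0)^2 dA` via the cotangent-Laplacian mean-curvature
#' normal with barycentric vertex areas, boundary vertices excluded.
#'
#' @param m a `cp_mesh`.
#' @param c0 spontaneous curvature, 1/nm.
#' @return A scalar.
#' @export
mesh_area <- function(m) sum(face_geometry(m)$area)

#' @rdname mesh_area
#' @export
mesh_volume <- function(m) {
  if (!mesh_is_watertight(m)) {
    abort("mesh_volume() requires a watertight mesh.",
          class = "cellplate_mesh_error")
  }
  abs(mesh_signed_volume(m))
}

#' @rdname mesh_area
#' @export
mesh_gauss_total <- function(m) {
  fg <- face_geometry(m)
  nv <- nrow(m$vertices)
  angsum <- numeric(nv)
  corner <- function(p, q, r) {
    # angle at p
    u <- q - p; v <- r - p
    acos(pmin(pmax(rowSums(u * v) /
                     sqrt(rowSums(u^2) * rowSums(v^2)), -1), 1))
  }
  a1 <- corner(fg$v1, fg$v2, fg$v3)
  a2 <- corner(fg$v2, fg$v3, fg$v1)
  a3 <- corner(fg$v3, fg$v1, fg$v2)
  for (k in 1:3) {
    ang <- list(a1, a2, a3)[[k]]
    acc <- tapply(ang, m$faces[, k], sum)
    angsum[as.integer(names(acc))] <- angsum[as.integer(names(acc))] + acc
  }
  bnd <- mesh_boundary_vertices(m)
  defect <- 2 * pi - angsum
  if (length(bnd) > 0) defect[bnd] <- pi - angsum[bnd]
  sum(defect)
}

#' @rdname mesh_area
#' @export
mesh_bending_integral <- function(m, c0 = 0) {
  fg <- face_geometry(m)
  nv <- nrow(m$vertices)
  f <- m$faces

  cot_at <- function(p, q, r) {
    # cot of angle at p in triangle (p, q, r)
    u <- q - p; v <- r - p
    cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                u[, 1] * v[, 2] - u[, 2] * v[, 1])
    rowSums(u * v) / sqrt(rowSums(cr^2))
  }
  c1 <- cot_at(fg$v1, fg$v2, fg$v3)  # opposite edge (2,3)
  c2 <- cot_at(fg$v2, fg$v3, fg$v1)  # opposite edge (3,1)
  c3 <- cot_at(fg$v3, fg$v1, fg$v2)  # opposite edge (1,2)

  ii <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  ww <- c(c1, c1, c2, c2, c3, c3)

  lap <- matrix(0, nv, 3)
  diff <- m$vertices[jj, , drop = FALSE] - m$vertices[ii, , drop = FALSE]
  for (d in 1:3) {
    acc <- tapply(ww * diff[, d], ii, sum)
    lap[as.integer(names(acc)), d] <- acc
  }
  avert <- numeric(nv)
  for (k in 1:3) {
    acc <- tapply(fg$area / 3, f[, k], sum)
    avert[as.integer(names(acc))] <- avert[as.integer(names(acc))] + acc
  }
  lap <- lap / (2 * avert)

  # outward vertex normals: accumulate (area-weighted) face normals
  vn <- matrix(0, nv, 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fg$normal[, d], f[, k], sum)
      vn[as.integer(names(acc)), d] <- vn[as.integer(names(acc)), d] + acc
    }
  }
  vn <- vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
  h <- -rowSums(lap * vn)  # c1 + c2 with sphere-positive sign

  keep <- setdiff(seq_len(nv), mesh_boundary_vertices(m))
  sum((h[keep] - c0)^2 * avert[keep])
}

#' Export meshes to OBJ / PLY
#'
#' Plain-text Wavefront OBJ or ASCII PLY triangle meshes, nm units, z-up.
#'
#' @param m a `cp_mesh`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_obj <- function(m, path) {
  stopifnot(inherits(m, "cp_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", m$provenance), con)
  writeLines(sprintf("v %.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                     m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3]),
             con)
  invisible(path)
}

#' @rdname write_obj
#' @export
write_ply <- function(m, path) {
  stopifnot(inherits(m, "cp_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", m$provenance),
               sprintf("element vertex %d", nrow(m$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(m$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", m$vertices[, 1], m$vertices[, 2],
                     m$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", m$faces[, 1] - 1, m$faces[, 2] - 1,
                     m$faces[, 3] - 1), con)
  invisible(path)
}

#' Triangle-soup mesh of an assembled conformation
#'
#' Positions a spheroid mesh at every vesicle center (with faces inside the
#' junction cap cones dropped) and a tube mesh along every edge, and merges
#' them into one mesh for export. Seams at the junction circles are
#' coincident but not stitched (a visualization/export aid, not an
#' integration surface).
#'
#' @param s a `cp_surface` from [assemble()].
#' @param n per-primitive mesh resolution.
#' @return A `cp_mesh`.
#' @export
composite_mesh <- function(s, n = 48) {
  stopifnot(inherits(s, "cp_surface"))
  conf <- s$conf
  meshes <- list()
  for (i in seq_len(conf$v)) {
    m <- mesh_spheroid(s$a, s$c, n)
    if (conf$t > 0) {
      cent <- fg_centroids <- (m$vertices[m$faces[, 1], ] +
                                 m$vertices[m$faces[, 2], ] +
                                 m$vertices[m$faces[, 3], ]) / 3
      keep <- rep(TRUE, nrow(m$faces))
      nb <- which(conf$edges[, 1] == i | conf$edges[, 2] == i)
      for (e in nb) {
        other <- setdiff(conf$edges[e, ], i)
        dir <- s$centers[other, ] - s$centers[i, ]
        dir <- dir / sqrt(sum(dir^2))
        keep <- keep & (cent[, 1] * dir[1] + cent[, 2] * dir[2] < s$tube$xj)
      }
      m$faces <- m$faces[keep, , drop = FALSE]
    }
    m$vertices[, 1] <- m$vertices[, 1] + s$centers[i, 1]
    m$vertices[, 2] <- m$vertices[, 2] + s$centers[i, 2]
    meshes[[length(meshes) + 1]] <- m
  }
  if (conf$t > 0) {
    for (e in seq_len(conf$t)) {
      m <- mesh_tube(s$tube, n)
      p1 <- s$centers[conf$edges[e, 1], ]; p2 <- s$centers[conf$edges[e, 2], ]
      mid <- (p1 + p2) / 2
      ang <- atan2(p2[2] - p1[2], p2[1] - p1[1])
      rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
      xy <- m$vertices[, 1:2] %*% t(rot)
      m$vertices <- cbind(xy[, 1] + mid[1], xy[, 2] + mid[2], m$vertices[, 3])
      meshes[[length(meshes) + 1]] <- m
    }
  }
  verts <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  offs <- cumsum(c(0, head(vapply(meshes, function(m) nrow(m$vertices),
                                  integer(1)), -1)))
  faces <- do.call(rbind, Map(function(m, o) m$faces + o, meshes, offs))
  new_mesh(verts, faces, sprintf("composite %s", format(conf)))
}
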