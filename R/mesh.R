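#' Triangulated unit sphere by octahedron subdivision
#'
#' Starts from a regular octahedron and subdivides each face `n` times,
#' projecting new vertices onto the unit sphere. The triangulation is
#' symmetric under all octant reflections, which keeps angular asymmetry
#' metrics free of mesh bias.
#'
#' @param n non-negative integer number of subdivision levels; the surface has
#'   `8 * 4^n` triangles.
#' @return list with `vertices` (V x 3 unit vectors) and `faces`
#'   (F x 3 vertex indices, outward-oriented).
#' @export
sphere_triangulation <- function(n = 2) {
  stopifnot(n >= 0)
  V <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  F <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (lev in seq_len(n)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    Vlist <- asplit(V, 1)
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      id <- mids[[k]]
      if (is.null(id)) {
        p <- (V[a, ] + V[b, ])
        p <- p / sqrt(sum(p^2))
        Vlist[[length(Vlist) + 1]] <<- p
        id <- length(Vlist)
        mids[[k]] <- id
      }
      id
    }
    newF <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newF[4 * f - 3, ] <- c(a, ab, ca)
      newF[4 * f - 2, ] <- c(b, bc, ab)
      newF[4 * f - 1, ] <- c(c, ca, bc)
      newF[4 * f, ] <- c(ab, bc, ca)
    }
    V <- do.call(rbind, Vlist)
    F <- newF
  }
  # enforce outward orientation (positive signed volume contribution)
  s <- vapply(seq_len(nrow(F)), function(f) {
    det(rbind(V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ]))
  }, numeric(1))
  flip <- s < 0
  F[flip, c(2, 3)] <- F[flip, c(3, 2)]
  list(vertices = V, faces = F)
}

#' Default radial shell layout for the concentric-spheres domain
#'
#' Shells are placed so that one shell lies exactly on the tumor seed surface,
#' the seed rim is refined (interstitial pressure and stress develop boundary
#' layers there) and the far field is graded geometrically out to the fixed
#' outer boundary.
#'
#' @param tumor_radius,outer_radius mm.
#' @param rim_width mm of refined rim outside the seed.
#' @param n_tumor shells inside the seed (excluding the center point,
#'   including the seed surface).
#' @param n_rim,n_far shells in the rim and far field.
#' @return increasing vector of radii ending at `outer_radius` and containing
#'   `tumor_radius`.
#' @export
ball_shells <- function(tumor_radius = 5, outer_radius = 50, rim_width = 3,
                        n_tumor = 3, n_rim = 3, n_far = 6,
                        interface_refine = TRUE, boundary_refine = TRUE) {
  stopifnot(tumor_radius > 0, outer_radius > tumor_radius + rim_width)
  inner <- tumor_radius * seq_len(n_tumor) / n_tumor
  if (interface_refine) {
    # extra shells hugging the seed surface: the stress and pressure fields
    # develop their sharpest structure at the tumor-host interface
    inner <- sort(unique(c(inner, tumor_radius * c(0.84, 0.94))))
    rim0 <- tumor_radius * c(1.07, 1.16)
  } else rim0 <- NULL
  rim <- tumor_radius + rim_width * seq_len(n_rim) / n_rim
  r0 <- tumor_radius + rim_width
  far <- r0 * (outer_radius / r0)^(seq_len(n_far) / n_far)
  # resolve the outer-boundary layer of the pressure gauge pinning
  outer_bl <- if (boundary_refine) outer_radius * c(0.915, 0.96) else NULL
  sort(unique(c(inner, rim0, rim, far, outer_bl)))
}

#' Layered tetrahedral mesh of a ball with an embedded spherical tumor seed
#'
#' Builds a tetrahedral mesh of a ball of radius `max(shells)` from radial
#' copies of a subdivided-octahedron sphere triangulation: a fan of
#' tetrahedra around the center plus prism layers between consecutive shells,
#' each prism split into three tetrahedra with diagonals chosen by the
#' global-least-vertex rule (guaranteed consistent).
#'
#' @param shells increasing radii (mm) of the spherical node shells; must
#'   contain `tumor_radius`.
#' @param subdiv angular resolution (see [sphere_triangulation()]).
#' @param tumor_radius radius (mm) of the tumor seed region.
#' @return an object of class `gm_mesh`: list with `nodes` (n x 3 mm),
#'   `tets` (m x 4), `region` (factor `tumor`/`host` per element),
#'   `outer_nodes`, `seed_nodes`, `seed_faces` (triangulation of the seed
#'   surface in global node ids), `directions` and `solid_angle` (per
#'   seed-surface node, for star-shaped tumor geometry), `vol` and `grads`
#'   (precomputed element geometry), `tumor_radius`, `outer_radius`.
#' @export
ball_mesh <- function(shells = ball_shells(), subdiv = 2, tumor_radius = 5) {
  shells <- sort(unique(shells))
  stopifnot(all(shells > 0),
            any(abs(shells - tumor_radius) < 1e-9))
  tri <- sphere_triangulation(subdiv)
  V <- tri$vertices
  Fc <- tri$faces
  nv <- nrow(V)
  ns <- length(shells)
  nodes <- rbind(c(0, 0, 0),
                 do.call(rbind, lapply(shells, function(r) V * r)))
  shell_idx <- function(s) 1L + (s - 1L) * nv + seq_len(nv)

  tets <- vector("list", ns)
  # center fan
  f1 <- 1L + Fc
  tets[[1]] <- cbind(1L, f1[, 1], f1[, 2], f1[, 3])
  # prism layers
  split_prism <- function(bot, top) {
    # bot, top: 3-vectors of global ids, corresponding vertices aligned.
    # Each quad face takes the diagonal through its least global vertex; the
    # total order on ids makes the three choices mutually consistent.
    imin <- which.min(c(bot, top))
    if (imin > 3) { tmp <- bot; bot <- top; top <- tmp; imin <- imin - 3L }
    rot <- switch(imin, c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
    b <- bot[rot]; t <- top[rot]
    # b1 is the least vertex: diagonals b1-t2 and b1-t3 on its two quads
    if (min(b[2], t[3]) < min(b[3], t[2])) {
      # remaining quad (b2,b3,t3,t2) takes diagonal b2-t3
      rbind(c(b[1], b[2], b[3], t[3]),
            c(b[1], b[2], t[3], t[2]),
            c(b[1], t[2], t[3], t[1]))
    } else {
      # remaining quad takes diagonal b3-t2
      rbind(c(b[1], b[2], b[3], t[2]),
            c(b[1], b[3], t[2], t[3]),
            c(b[1], t[1], t[2], t[3]))
    }
  }
  for (s in seq_len(ns - 1L)) {
    off_b <- 1L + (s - 1L) * nv
    off_t <- 1L + s * nv
    lay <- matrix(0L, nrow = 3L * nrow(Fc), ncol = 4)
    for (f in seq_len(nrow(Fc))) {
      lay[(3 * f - 2):(3 * f), ] <- split_prism(off_b + Fc[f, ], off_t + Fc[f, ])
    }
    tets[[s + 1L]] <- lay
  }
  tets <- do.call(rbind, tets)
  # orient all tets positively
  v1 <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  v2 <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  v3 <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  svol <- (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
           v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
           v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
  neg <- svol < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]

  geo <- .fem_geometry(nodes, tets)
  # label elements by construction layer (robust on coarse triangulations,
  # where element centroids of an outer layer can fall inside the seed radius)
  s_seed <- which(abs(shells - tumor_radius) < 1e-9)
  layer <- c(rep(1L, nrow(f1)),
             rep(seq_len(ns - 1L) + 1L, each = 3L * nrow(Fc)))
  region <- factor(ifelse(layer <= s_seed, "tumor", "host"),
                   levels = c("tumor", "host"))
  node_shell <- c(0L, rep(seq_len(ns), each = nv))
  seed_nodes <- shell_idx(s_seed)
  seed_faces <- matrix(seed_nodes[Fc], ncol = 3)
  # solid angle carried by each direction (Van Oosterom & Strackee)
  omega_f <- vapply(seq_len(nrow(Fc)), function(f) {
    v <- V[Fc[f, ], , drop = FALSE]
    num <- abs(det(v))
    den <- 1 + sum(v[1, ] * v[2, ]) + sum(v[2, ] * v[3, ]) + sum(v[1, ] * v[3, ])
    2 * atan2(num, den)
  }, numeric(1))
  solid_angle <- numeric(nv)
  for (f in seq_len(nrow(Fc)))
    solid_angle[Fc[f, ]] <- solid_angle[Fc[f, ]] + omega_f[f] / 3

  structure(list(
    nodes = nodes, tets = tets, region = region, layer = layer,
    node_shell = node_shell, seed_shell = s_seed,
    outer_nodes = shell_idx(ns), seed_nodes = seed_nodes,
    seed_faces = seed_faces, directions = V, solid_angle = solid_angle,
    vol = geo$vol, grads = geo$grads,
    tumor_radius = tumor_radius, outer_radius = shells[ns]
  ), class = "gm_mesh")
}

#' @export
print.gm_mesh <- function(x, ...) {
  cat(sprintf(
    "<gm_mesh> %d nodes, %d tetrahedra (%d tumor), R_tumor = %g mm, R_outer = %g mm\n",
    nrow(x$nodes), nrow(x$tets), sum(x$region == "tumor"),
    x$tumor_radius, x$outer_radius))
  invisible(x)
}

#' Map element-level values to nodes (volume-weighted average)
#' @param mesh a `gm_mesh`.
#' @param x vector of per-element values.
#' @return per-node vector.
#' @export
elem_to_node <- function(mesh, x) {
  n <- nrow(mesh$nodes)
  num <- numeric(n)
  den <- numeric(n)
  w <- mesh$vol / 4
  for (a in 1:4) {
    idx <- mesh$tets[, a]
    num <- num + unname(tapply_add(idx, x * w, n))
    den <- den + unname(tapply_add(idx, w, n))
  }
  num / den
}

#' Average nodal values onto elements
#' @param mesh a `gm_mesh`.
#' @param x per-node vector.
#' @return per-element vector.
#' @export
node_to_elem <- function(mesh, x) {
  (x[mesh$tets[, 1]] + x[mesh$tets[, 2]] + x[mesh$tets[, 3]] + x[mesh$tets[, 4]]) / 4
}

# fast grouped sum into a length-n vector
tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, group = idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Nodes belonging to the tumor seed region
#'
#' Identified by construction shell (all shells up to and including the seed
#' surface), falling back to a radius test for meshes without shell
#' bookkeeping.
#'
#' @param mesh a `gm_mesh`.
#' @param tol mm tolerance beyond the seed radius (fallback path only).
#' @return integer node ids.
#' @export
tumor_nodes <- function(mesh, tol = 1e-9) {
  if (!is.null(mesh$node_shell))
    return(which(mesh$node_shell <= mesh$seed_shell))
  which(sqrt(rowSums(mesh$nodes^2)) <= mesh$tumor_radius + tol)
}
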