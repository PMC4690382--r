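## Linear (small-strain) St. Venant-Kirchhoff elastostatics on tetrahedral
## meshes. Displacement-based P1 elements; prescribed-displacement, free
## (traction) and sliding (u . n = 0) boundary conditions; strain-energy and
## deformed-volume accounting.
##
## Near-incompressible material (nu -> 0.5) makes plain P1 elements lock
## volumetrically. The solver therefore evaluates the volumetric part of the
## energy on a node-averaged divergence field (averaged nodal pressure),
## which restores the correct isochoric response on coarse meshes while
## leaving the deviatoric P1 operator untouched. The stabilisation is exact
## for uniform-strain fields, so the patch test is unaffected.

#' Elastic material description
#'
#' Isotropic linear elastic material, optionally with a different Young's
#' modulus in the equatorial (furrow) region. Only the modulus ratio matters
#' for displacement-driven problems; the absolute scale defaults to 1.
#'
#' @param young_modulus Young's modulus E of the polar (default) region.
#' @param poisson_ratio Poisson's ratio; the solver requires `nu < 0.5`.
#'   The default 0.499 approximates incompressible cytoplasm.
#' @param equatorial_modulus optional E of the equatorial region.
#' @param equatorial_halfwidth elements whose centroid satisfies
#'   `|z| <= equatorial_halfwidth` belong to the equatorial region.
#' @param stabilize evaluate the volumetric energy on a node-averaged
#'   divergence field (averaged nodal pressure). The default FALSE is the
#'   plain displacement P1 formulation; the stabilised variant gives a
#'   softer, locking-free response in the incompressible limit.
#' @return an object of class `elastic_material`.
#' @export
material <- function(young_modulus = 1, poisson_ratio = 0.499,
                     equatorial_modulus = NULL,
                     equatorial_halfwidth = NULL, stabilize = FALSE) {
  if (!is.finite(young_modulus) || young_modulus <= 0)
    stop("young_modulus must be positive")
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in [0, 0.5) for a displacement solve")
  if (!is.null(equatorial_modulus) && is.null(equatorial_halfwidth))
    stop("equatorial_modulus requires equatorial_halfwidth")
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio,
                 equatorial_modulus = equatorial_modulus,
                 equatorial_halfwidth = equatorial_halfwidth,
                 stabilize = isTRUE(stabilize)),
            class = "elastic_material")
}

lame_constants <- function(E, nu)
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))

elem_modulus <- function(mesh, mat) {
  m <- nrow(mesh$elems)
  E <- rep(mat$young_modulus, m)
  if (!is.null(mat$equatorial_modulus)) {
    zc <- (mesh$nodes[mesh$elems[, 1], 3] + mesh$nodes[mesh$elems[, 2], 3] +
             mesh$nodes[mesh$elems[, 3], 3] + mesh$nodes[mesh$elems[, 4], 3]) / 4
    E[abs(zc) <= mat$equatorial_halfwidth] <- mat$equatorial_modulus
  }
  E
}

## Shape-function gradients of the four barycentric P1 functions on every
## tetrahedron. Returns list(g = list of 4 m x 3 matrices, vol = volumes).
shape_gradients <- function(nodes, elems) {
  x1 <- nodes[elems[, 1], , drop = FALSE]
  e1 <- nodes[elems[, 2], , drop = FALSE] - x1
  e2 <- nodes[elems[, 3], , drop = FALSE] - x1
  e3 <- nodes[elems[, 4], , drop = FALSE] - x1
  det <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
         e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
         e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  inv <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                              a[, 3] * b[, 1] - a[, 1] * b[, 3],
                              a[, 1] * b[, 2] - a[, 2] * b[, 1]) / det
  g2 <- inv(e2, e3); g3 <- inv(e3, e1); g4 <- inv(e1, e2)
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det / 6)
}

## Standard P1 isotropic stiffness matrix from per-element Lame constants.
assemble_standard <- function(mesh, lambda_e, mu_e, grads = NULL) {
  if (is.null(grads)) grads <- shape_gradients(mesh$nodes, mesh$elems)
  g <- grads$g; V <- grads$vol
  m <- nrow(mesh$elems); n <- nrow(mesh$nodes)
  nn <- 16L * 9L * m
  I <- integer(nn); J <- integer(nn); X <- numeric(nn)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    ga <- g[[a]]; gb <- g[[b]]
    gdot <- ga[, 1] * gb[, 1] + ga[, 2] * gb[, 2] + ga[, 3] * gb[, 3]
    ra <- 3L * (mesh$elems[, a] - 1L); rb <- 3L * (mesh$elems[, b] - 1L)
    for (i in 1:3) for (j in 1:3) {
      val <- V * (lambda_e * ga[, i] * gb[, j] + mu_e * ga[, j] * gb[, i] +
                    if (i == j) mu_e * gdot else 0)
      idx <- pos + seq_len(m)
      I[idx] <- ra + i; J[idx] <- rb + j; X[idx] <- val
      pos <- pos + m
    }
  }
  Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(3L * n, 3L * n))
}

## Node-averaged divergence operator and nodal volumes.
## theta_node = sum_{e ni node} (V_e/4) theta_e / V_node.
averaged_divergence <- function(mesh, grads) {
  g <- grads$g; V <- grads$vol
  m <- nrow(mesh$elems); n <- nrow(mesh$nodes)
  ## D: m x 3n, theta_e = sum_a g_a . u_a
  I <- rep(seq_len(m), 12L)
  J <- integer(12L * m); X <- numeric(12L * m)
  pos <- 0L
  for (a in 1:4) for (i in 1:3) {
    idx <- pos + seq_len(m)
    J[idx] <- 3L * (mesh$elems[, a] - 1L) + i
    X[idx] <- g[[a]][, i]
    pos <- pos + m
  }
  D <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(m, 3L * n))
  Vn <- as.numeric(Matrix::sparseMatrix(i = as.vector(mesh$elems),
                                        j = rep(1L, 4L * m),
                                        x = rep(V / 4, 4L),
                                        dims = c(n, 1L)))
  A <- Matrix::sparseMatrix(i = as.vector(mesh$elems), j = rep(seq_len(m), 4L),
                            x = rep(V / 4, 4L) / Vn[as.vector(mesh$elems)],
                            dims = c(n, m))
  list(D = D, A = A, Vn = Vn)
}

#' Assemble the global stiffness matrix
#'
#' @param mesh a `volume_mesh`.
#' @param mat an [material()] object.
#' @param grads optional precomputed [shape_gradients()].
#' @return list with the sparse stiffness matrix `K`, `grads`, and the
#'   per-element modulus `E_e`.
#' @keywords internal
assemble_stiffness <- function(mesh, mat, grads = NULL) {
  if (is.null(grads)) grads <- shape_gradients(mesh$nodes, mesh$elems)
  E_e <- elem_modulus(mesh, mat)
  lc <- lame_constants(E_e, mat$poisson_ratio)
  if (mat$stabilize) {
    ## deviatoric part as a standard assembly with lambda* = -2 mu / 3
    K <- assemble_standard(mesh, -2 * lc$mu / 3, lc$mu, grads)
    kappa_e <- lc$lambda + 2 * lc$mu / 3
    ad <- averaged_divergence(mesh, grads)
    AD <- ad$A %*% ad$D
    kappa_n <- as.numeric(ad$A %*% kappa_e)
    W <- Matrix::Diagonal(x = ad$Vn * kappa_n)
    K <- K + Matrix::crossprod(AD, W %*% AD)
  } else {
    K <- assemble_standard(mesh, lc$lambda, lc$mu, grads)
  }
  list(K = Matrix::forceSymmetric(K), grads = grads, E_e = E_e)
}

#' Boundary condition specification
#'
#' Nodes not mentioned are traction-free (homogeneous Neumann). Prescribed
#' displacements are imposed exactly; directional constraints fix the
#' displacement component along a given unit direction per node (value 0
#' gives the sliding condition `u . n = 0`, leaving tangential motion free).
#'
#' @param dirichlet list of `list(nodes =, value =)` entries; `value` is a
#'   length-3 vector applied to all nodes or an `n x 3` matrix.
#' @param directional list of `list(nodes =, dirs =, values =)` entries;
#'   `dirs` is an `n x 3` matrix of unit directions, `values` a scalar or
#'   length-n vector of prescribed normal components (0 = sliding).
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(dirichlet = list(), directional = list()) {
  structure(list(dirichlet = dirichlet, directional = directional),
            class = "boundary_spec")
}

## Build the null-space basis Z (3n x nf) of the constraints and the
## particular solution u_p (3n). A node may be fully prescribed (3 dofs) or
## constrained along one unit direction.
constraint_basis <- function(n_nodes, bc) {
  con_type <- integer(n_nodes)            # 0 free, 1 directional, 2 dirichlet
  up <- numeric(3L * n_nodes)
  dir_n <- matrix(0, n_nodes, 3)
  dir_g <- numeric(n_nodes)
  for (d in bc$dirichlet) {
    nodes <- d$nodes
    if (any(con_type[nodes] != 0L)) stop("node constrained twice")
    con_type[nodes] <- 2L
    val <- d$value
    if (is.null(dim(val))) val <- matrix(val, length(nodes), 3, byrow = TRUE)
    up[3L * (nodes - 1L) + 1L] <- val[, 1]
    up[3L * (nodes - 1L) + 2L] <- val[, 2]
    up[3L * (nodes - 1L) + 3L] <- val[, 3]
  }
  for (d in bc$directional) {
    nodes <- d$nodes
    if (any(con_type[nodes] != 0L)) stop("node constrained twice")
    con_type[nodes] <- 1L
    nv <- d$dirs / sqrt(rowSums(d$dirs^2))
    dir_n[nodes, ] <- nv
    g <- if (is.null(d$values)) 0 else d$values
    dir_g[nodes] <- g
    up[3L * (nodes - 1L) + 1L] <- nv[, 1] * g
    up[3L * (nodes - 1L) + 2L] <- nv[, 2] * g
    up[3L * (nodes - 1L) + 3L] <- nv[, 3] * g
  }
  free <- which(con_type == 0L)
  slid <- which(con_type == 1L)
  nf <- 3L * length(free) + 2L * length(slid)
  nnz <- 3L * length(free) + 6L * length(slid)
  I <- integer(nnz); J <- integer(nnz); X <- numeric(nnz)
  pos <- 0L; col <- 0L
  if (length(free)) {
    idx <- seq_len(3L * length(free))
    I[idx] <- as.vector(t(outer(3L * (free - 1L), 1:3, `+`)))
    J[idx] <- seq_len(3L * length(free))
    X[idx] <- 1
    pos <- 3L * length(free); col <- 3L * length(free)
  }
  if (length(slid)) {
    nrm <- dir_n[slid, , drop = FALSE]
    ## tangent basis: t1 = normalize(n x e), e the axis least aligned with n
    e <- diag(3)[apply(abs(nrm), 1, which.min), , drop = FALSE]
    t1 <- cbind(nrm[, 2] * e[, 3] - nrm[, 3] * e[, 2],
                nrm[, 3] * e[, 1] - nrm[, 1] * e[, 3],
                nrm[, 1] * e[, 2] - nrm[, 2] * e[, 1])
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
                nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
                nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
    for (k in seq_along(slid)) {
      rows <- 3L * (slid[k] - 1L) + 1:3
      idx <- pos + 1:6
      I[idx] <- rep(rows, 2L)
      J[idx] <- rep(col + c(1L, 2L), each = 3L)
      X[idx] <- c(t1[k, ], t2[k, ])
      pos <- pos + 6L; col <- col + 2L
    }
  }
  Z <- Matrix::sparseMatrix(i = I[seq_len(pos)], j = J[seq_len(pos)],
                            x = X[seq_len(pos)],
                            dims = c(3L * n_nodes, nf))
  list(Z = Z, up = up, n_constrained = sum(con_type > 0L))
}

rigid_mode_check <- function(Kr, Z, nodes) {
  ctr <- colMeans(nodes)
  x <- sweep(nodes, 2, ctr)
  modes <- list(tx = cbind(1, 0, 0), ty = cbind(0, 1, 0), tz = cbind(0, 0, 1),
                rx = cbind(0, -x[, 3], x[, 2]),
                ry = cbind(x[, 3], 0, -x[, 1]),
                rz = cbind(-x[, 2], x[, 1], 0))
  bad <- character(0)
  for (nm in names(modes)) {
    v <- modes[[nm]]
    if (nrow(v) == 1) v <- matrix(v, nrow(nodes), 3, byrow = TRUE)
    r <- Matrix::crossprod(Z, as.vector(t(v)))
    nr <- sqrt(sum(r^2))
    if (nr < 1e-12) next                  # mode eliminated by constraints
    q <- Kr %*% (r / nr)
    if (sqrt(sum(q^2)) < 1e-8 * Matrix::norm(Kr, "I")) bad <- c(bad, nm)
  }
  bad
}

#' Prepare a reusable elastostatic operator
#'
#' Assembles and factorises the constrained stiffness system once, so that
#' repeated solves with the same mesh, material, and constraint structure
#' but different prescribed values (e.g., a parameter search within one
#' incremental step) cost only a triangular back-substitution.
#'
#' @param mesh a `volume_mesh`.
#' @param mat an [material()] object.
#' @param bc a [boundary_spec()]; the constraint structure (which nodes,
#'   which directions) is fixed, the values may be overridden per solve.
#' @return an object of class `elastic_operator` with a `$solve(bc)` method.
#' @export
elastic_operator <- function(mesh, mat, bc) {
  asm <- assemble_stiffness(mesh, mat)
  cb <- constraint_basis(nrow(mesh$nodes), bc)
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(cb$Z, asm$K %*% cb$Z))
  fact <- tryCatch(Matrix::Cholesky(Kr, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
  if (is.null(fact)) {
    bad <- rigid_mode_check(Kr, cb$Z, mesh$nodes)
    stop("elastostatic system is singular",
         if (length(bad)) paste0("; unconstrained rigid mode(s): ",
                                 paste(bad, collapse = ", "))
         else "; check the boundary conditions")
  }
  self <- list(mesh = mesh, mat = mat, bc = bc, K = asm$K,
               grads = asm$grads, E_e = asm$E_e, Z = cb$Z, fact = fact)
  self$solve <- function(bc_values = NULL) {
    cb2 <- if (is.null(bc_values)) cb
           else constraint_basis(nrow(mesh$nodes), bc_values)
    rhs <- -Matrix::crossprod(self$Z, self$K %*% cb2$up)
    q <- as.numeric(Matrix::solve(self$fact, rhs))
    u <- cb2$up + as.numeric(self$Z %*% q)
    structure(list(u = matrix(u, ncol = 3, byrow = TRUE), mesh = mesh,
                   mat = mat, grads = self$grads, E_e = self$E_e),
              class = "displacement_field")
  }
  class(self) <- "elastic_operator"
  self
}

#' Solve the elastostatic boundary-value problem
#'
#' Solves the linearised equilibrium equations (divergence of the stress
#' vanishing, loads given implicitly as prescribed boundary displacements)
#' for the nodal displacement field.
#'
#' @inheritParams elastic_operator
#' @return a `displacement_field`: `u` (n x 3 nodal displacements), plus the
#'   mesh, material and cached shape gradients for strain evaluation.
#' @export
solve_elastostatic <- function(mesh, mat, bc) {
  op <- elastic_operator(mesh, mat, bc)
  op$solve()
}

#' Per-element linearised strain tensors
#' @param field a `displacement_field`.
#' @return m x 6 matrix of strain components (xx, yy, zz, xy, yz, xz).
#' @export
elem_strains <- function(field) {
  mesh <- field$mesh; g <- field$grads$g; u <- field$u
  comp <- function(i, j) {
    acc <- 0
    for (a in 1:4)
      acc <- acc + 0.5 * (g[[a]][, i] * u[mesh$elems[, a], j] +
                            g[[a]][, j] * u[mesh$elems[, a], i])
    acc
  }
  cbind(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
        xy = comp(1, 2), yz = comp(2, 3), xz = comp(1, 3))
}

#' Per-element Cauchy stress tensors
#' @param field a `displacement_field`.
#' @return m x 6 matrix of stress components (xx, yy, zz, xy, yz, xz).
#' @export
elem_stresses <- function(field) {
  eps <- elem_strains(field)
  lc <- lame_constants(field$E_e, field$mat$poisson_ratio)
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  s <- 2 * lc$mu * eps
  s[, 1:3] <- s[, 1:3] + lc$lambda * tr
  s
}

#' Total strain energy of a displacement field
#'
#' Volume integral (sum over tetrahedra) of the strain energy density
#' `lambda/2 (tr eps)^2 + mu tr(eps^2)`. In incompressible mode the first
#' (volumetric) term is dropped, as appropriate for `nu = 0.5` material.
#'
#' @param field a `displacement_field`.
#' @param incompressible drop the volumetric term; default (`NULL`) drops it
#'   when the material's Poisson ratio is 0.49 or above.
#' @return the strain energy (model units).
#' @export
strain_energy <- function(field, incompressible = NULL) {
  eps <- elem_strains(field)
  lc <- lame_constants(field$E_e, field$mat$poisson_ratio)
  if (is.null(incompressible))
    incompressible <- field$mat$poisson_ratio >= 0.49
  tr2 <- (eps[, 1] + eps[, 2] + eps[, 3])^2
  eps2 <- eps[, 1]^2 + eps[, 2]^2 + eps[, 3]^2 +
    2 * (eps[, 4]^2 + eps[, 5]^2 + eps[, 6]^2)
  dens <- lc$mu * eps2
  if (!incompressible) dens <- dens + lc$lambda / 2 * tr2
  sum(dens * field$grads$vol)
}

#' Volume of the deformed configuration
#'
#' @param mesh a `volume_mesh`.
#' @param field a `displacement_field` on that mesh (or an n x 3
#'   displacement matrix).
#' @return total tetrahedral volume at node positions `x + u`.
#' @export
deformed_volume <- function(mesh, field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  if (!is.matrix(u) || nrow(u) != nrow(mesh$nodes))
    stop("displacement field does not match the mesh")
  v <- tet_volumes(mesh$nodes + u, mesh$elems)
  if (any(v <= 0))
    stop("deformed configuration has inverted element(s): ",
         paste(utils::head(which(v <= 0), 10), collapse = ", "))
  sum(v)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("Displacement field on", nrow(x$u), "nodes; max |u| =",
      format(max(sqrt(rowSums(x$u^2)))), "\n")
  invisible(x)
}
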