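## Shared fixtures and independent oracles for the test suite.

## structured unit-cube tetrahedral mesh (Kuhn subdivision of an n^3 grid)
cube_mesh <- function(n = 2) {
  xs <- seq(0, 1, length.out = n + 1)
  idx <- function(i, j, k) i + (n + 1) * (j - 1) + (n + 1)^2 * (k - 1)
  nodes <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  dimnames(nodes) <- NULL
  perms <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  elems <- NULL
  for (k in 1:n) for (j in 1:n) for (i in 1:n) {
    v <- c(idx(i, j, k), idx(i + 1, j, k), idx(i, j + 1, k),
           idx(i + 1, j + 1, k), idx(i, j, k + 1), idx(i + 1, j, k + 1),
           idx(i, j + 1, k + 1), idx(i + 1, j + 1, k + 1))
    elems <- rbind(elems, matrix(v[t(perms)], ncol = 4, byrow = TRUE))
  }
  storage.mode(elems) <- "integer"
  mesh_from_elems(nodes, elems)
}

## classic 5-tet decomposition of the unit cube
cube5_mesh <- function() {
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(nodes) <- NULL
  ## vertex order from expand.grid: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0)
  ## 5:(0,0,1) 6:(1,0,1) 7:(0,1,1) 8:(1,1,1)
  elems <- rbind(c(1, 2, 3, 5), c(2, 3, 4, 8), c(2, 5, 6, 8),
                 c(3, 5, 7, 8), c(2, 3, 5, 8))
  storage.mode(elems) <- "integer"
  mesh_from_elems(nodes, elems)
}

## a free-standing pair of tetrahedra sharing a face
twotet_mesh <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(0.9, 0.9, 0.9))
  elems <- rbind(c(1L, 2L, 3L, 4L), c(2L, 3L, 4L, 5L))
  mesh_from_elems(nodes, elems)
}

mesh_from_elems <- function(nodes, elems) {
  elems <- cytomech:::fix_orientation(nodes, elems)
  bnd <- cytomech:::boundary_faces(nodes, elems)
  structure(list(nodes = nodes, elems = elems, boundary = bnd$tris,
                 surface_nodes = sort(unique(as.vector(bnd$tris))),
                 surface_info = NULL, tags = list(), params = list()),
            class = "volume_mesh")
}

## dense brute-force P1 isotropic stiffness assembly, coded independently
## of the package: numerical 1-point quadrature with shape gradients from
## solve() on the element Jacobian, B-matrix formalism and the standard
## 6x6 isotropic elasticity matrix.
dense_stiffness_oracle <- function(mesh, E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  n <- nrow(mesh$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (e in seq_len(nrow(mesh$elems))) {
    vid <- mesh$elems[e, ]
    X <- mesh$nodes[vid, ]
    J <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
    vol <- abs(det(J)) / 6
    dN <- solve(J, diag(3))            # gradients of local coords
    g <- rbind(-colSums(t(dN)), t(dN)) # 4 x 3 shape gradients
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- g[a, 1]
      B[2, c0 + 2] <- g[a, 2]
      B[3, c0 + 3] <- g[a, 3]
      B[4, c0 + 1] <- g[a, 2]; B[4, c0 + 2] <- g[a, 1]
      B[5, c0 + 2] <- g[a, 3]; B[5, c0 + 3] <- g[a, 2]
      B[6, c0 + 1] <- g[a, 3]; B[6, c0 + 3] <- g[a, 1]
    }
    Ke <- vol * t(B) %*% D %*% B
    dof <- as.vector(t(outer(3 * (vid - 1), 1:3, `+`)))
    K[dof, dof] <- K[dof, dof] + Ke
  }
  K
}

## brute-force truncated-window lower median, the oracle for smooth_series
median_filter_oracle <- function(v, width = 5) {
  n <- length(v)
  h <- width %/% 2
  vapply(seq_len(n), function(i) {
    w <- sort(v[max(1, i - h):min(n, i + h)])
    w[(length(w) + 1) %/% 2]
  }, numeric(1))
}

## brute-force exhaustive permutation test on per-curve means
permutation_oracle <- function(a, b) {
  sa <- rowMeans(a); sb <- rowMeans(b)
  obs <- abs(mean(sa) - mean(sb))
  pooled <- c(sa, sb)
  na <- length(sa); ntot <- length(pooled)
  sel <- utils::combn(ntot, na)
  stats <- apply(sel, 2, function(ii)
    abs(mean(pooled[ii]) - mean(pooled[-ii])))
  mean(stats >= obs - 1e-12)
}

## quick access to the packaged tables
tab_fix <- elongation_tables()
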