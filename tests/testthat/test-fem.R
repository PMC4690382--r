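test_that("stiffness action matches a dense brute-force assembly", {
  for (mesh in list(twotet_mesh(), cube5_mesh())) {
    asm <- cytomech:::assemble_stiffness(mesh, material(2.5, 0.3,
                                                        stabilize = FALSE))
    Kd <- dense_stiffness_oracle(mesh, 2.5, 0.3)
    set.seed(7)
    for (r in 1:3) {
      v <- rnorm(3 * nrow(mesh$nodes))
      expect_lt(max(abs(as.numeric(asm$K %*% v) - as.numeric(Kd %*% v))),
                1e-10)
    }
  }
})

test_that("a uniform strain field passes the patch test", {
  A <- matrix(c(0.01, 0.002, 0, 0.003, -0.005, 0.001, 0, 0.004, 0.002),
              3, 3, byrow = TRUE)
  for (stab in c(FALSE, TRUE)) {
    m <- cube_mesh(3)
    uall <- m$nodes %*% t(A)
    bc <- boundary_spec(dirichlet = list(list(nodes = m$surface_nodes,
                                              value = uall[m$surface_nodes, ])))
    f <- solve_elastostatic(m, material(1, 0.499, stabilize = stab), bc)
    expect_lt(max(abs(f$u - uall)) / max(abs(uall)), 1e-6)
    eps <- elem_strains(f)
    sym <- (A + t(A)) / 2
    expect_lt(max(abs(eps[, 1] - sym[1, 1])), 1e-8)
    expect_lt(max(abs(eps[, 4] - sym[1, 2])), 1e-8)
  }
})

test_that("uniaxial stretch recovers the Poisson ratio", {
  n <- 6
  m <- cube_mesh(n)
  z <- m$nodes[, 3]
  ends <- which(z < 1e-9 | z > 1 - 1e-9)
  delta <- 0.01
  vals <- ifelse(m$nodes[ends, 3] > 0.5, delta, -delta)
  dirs <- matrix(c(0, 0, 1), length(ends), 3, byrow = TRUE)
  bc <- boundary_spec(directional = list(
    list(nodes = ends, dirs = dirs, values = vals),
    ## pin lateral rigid modes at interior nodes
    list(nodes = which.min(rowSums((m$nodes -
      matrix(c(.5, .5, .5), nrow(m$nodes), 3, byrow = TRUE))^2)),
      dirs = matrix(c(1, 0, 0), 1), values = 0),
    list(nodes = which.min(rowSums((m$nodes -
      matrix(c(.5, .5, .25), nrow(m$nodes), 3, byrow = TRUE))^2)),
      dirs = matrix(c(0, 1, 0), 1), values = 0),
    list(nodes = which.min(rowSums((m$nodes -
      matrix(c(1, .5, .5), nrow(m$nodes), 3, byrow = TRUE))^2)),
      dirs = matrix(c(0, 1, 0), 1), values = 0)))
  f <- solve_elastostatic(m, material(1, 0.3), bc)
  left <- which(m$nodes[, 1] < 1e-9)
  right <- which(m$nodes[, 1] > 1 - 1e-9)
  lat <- mean(f$u[right, 1]) - mean(f$u[left, 1])
  nu_rec <- -lat / (2 * delta)
  expect_lt(abs(nu_rec - 0.3) / 0.3, 0.02)
})

test_that("strain energy follows its closed forms and invariances", {
  m <- cube_mesh(2)
  all_nodes <- seq_len(nrow(m$nodes))
  ## zero displacement: zero energy
  f0 <- solve_elastostatic(m, material(), boundary_spec(
    dirichlet = list(list(nodes = m$surface_nodes, value = c(0, 0, 0)))))
  expect_equal(max(abs(f0$u)), 0)
  expect_equal(strain_energy(f0), 0)
  ## uniform simple shear on the unit cube: W = mu gamma^2 / 2
  gam <- 0.02
  ush <- cbind(gam * m$nodes[, 3], 0, 0)
  fs <- solve_elastostatic(m, material(1, 0.3), boundary_spec(
    dirichlet = list(list(nodes = all_nodes, value = ush))))
  mu <- 1 / (2 * 1.3)
  expect_equal(strain_energy(fs, incompressible = FALSE), mu * gam^2 / 2,
               tolerance = 1e-10)
  ## quadratic scaling in the displacement amplitude
  fs2 <- solve_elastostatic(m, material(1, 0.3), boundary_spec(
    dirichlet = list(list(nodes = all_nodes, value = 3 * ush))))
  expect_equal(strain_energy(fs2, incompressible = FALSE),
               9 * strain_energy(fs, incompressible = FALSE),
               tolerance = 1e-9)
  ## incompressible mode drops the volumetric term
  ud <- 0.01 * m$nodes
  fd <- solve_elastostatic(m, material(1, 0.3), boundary_spec(
    dirichlet = list(list(nodes = all_nodes, value = ud))))
  expect_lt(strain_energy(fd, incompressible = TRUE),
            strain_energy(fd, incompressible = FALSE))
})

test_that("displacement-driven problems are linear in load and modulus", {
  m <- make_sphere_mesh(20, 4)
  m <- tag_regions(m, 4)
  band <- m$tags$furrow_band
  val <- cbind(-0.05 * m$nodes[band, 1], -0.05 * m$nodes[band, 2], 0)
  bc1 <- boundary_spec(dirichlet = list(list(nodes = band, value = val)))
  bc2 <- boundary_spec(dirichlet = list(list(nodes = band, value = 2 * val)))
  f1 <- solve_elastostatic(m, material(1), bc1)
  f2 <- solve_elastostatic(m, material(1), bc2)
  expect_lt(max(abs(f2$u - 2 * f1$u)), 1e-8 * max(abs(f1$u)))
  ## scaling E leaves u unchanged and scales W
  f3 <- solve_elastostatic(m, material(5), bc1)
  expect_lt(max(abs(f3$u - f1$u)), 1e-9)
  expect_equal(strain_energy(f3), 5 * strain_energy(f1), tolerance = 1e-9)
})

test_that("sliding constraints suppress the normal component exactly", {
  m <- make_sphere_mesh(20, 4)
  m <- tag_regions(m, 4)
  band <- m$tags$furrow_band
  sn <- setdiff(m$surface_nodes, band)
  nrm <- m$nodes[sn, ] / sqrt(rowSums(m$nodes[sn, ]^2))
  bc <- boundary_spec(
    dirichlet = list(list(nodes = band,
                          value = cbind(-0.05 * m$nodes[band, 1],
                                        -0.05 * m$nodes[band, 2], 0))),
    directional = list(list(nodes = sn, dirs = nrm, values = 0)))
  f <- solve_elastostatic(m, material(), bc)
  un <- rowSums(f$u[sn, ] * nrm)
  expect_lt(max(abs(un)), 1e-8 * max(abs(f$u)))
})

test_that("unconstrained rigid modes are reported by name", {
  m <- cube_mesh(2)
  top <- which(m$nodes[, 3] > 1 - 1e-9)
  dirs <- matrix(c(0, 0, 1), length(top), 3, byrow = TRUE)
  bc <- boundary_spec(directional = list(list(nodes = top, dirs = dirs,
                                              values = 0.01)))
  expect_error(solve_elastostatic(m, material(1, 0.3), bc), "rigid mode")
})

test_that("deformed volume follows analytic dilatation", {
  m <- cube_mesh(2)
  expect_equal(deformed_volume(m, matrix(0, nrow(m$nodes), 3)), 1)
  alpha <- 0.1
  expect_equal(deformed_volume(m, alpha * m$nodes), (1 + alpha)^3,
               tolerance = 1e-10)
  ## inverted elements are reported
  u_bad <- matrix(0, nrow(m$nodes), 3)
  ctr <- which.min(rowSums((m$nodes -
    matrix(0.5, nrow(m$nodes), 3))^2))
  u_bad[ctr, ] <- c(2, 2, 2)
  expect_error(deformed_volume(m, u_bad), "inverted")
})
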