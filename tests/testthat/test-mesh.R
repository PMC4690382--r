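test_that("sphere mesh volume converges to the analytic value", {
  R <- 50
  errs <- vapply(c(10, 5, 2.5), function(te) {
    m <- make_sphere_mesh(R, te)
    abs(mesh_volume(m) / (4 / 3 * pi * R^3) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.02)           # target_edge = radius/10
  expect_true(all(diff(errs) < 0))   # monotone refinement
})

test_that("meshes are watertight with positively oriented tetrahedra", {
  m <- make_sphere_mesh(50, 8, fine_band = 1)
  expect_gt(min(cytomech:::tet_volumes(m$nodes, m$elems)), 0)
  expect_silent(cytomech:::check_closed_surface(extract_boundary(m)))
  ## meshing is deterministic regardless of the seed argument
  m2 <- make_sphere_mesh(50, 8, seed = 123, fine_band = 1)
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$elems, m2$elems)
})

test_that("region tagging follows the axial band definition", {
  m <- make_sphere_mesh(50, 6, fine_band = 1)
  m <- tag_regions(m, 2, spindle_length = 15)
  band <- m$tags$furrow_band
  expect_gt(length(band), 0)
  expect_true(all(abs(m$nodes[band, 3]) <= 1 + 1e-9))
  ## anchors sit near (0, 0, +-7.5)
  zp <- m$nodes[m$tags$anchor_plus, 3]
  zm <- m$nodes[m$tags$anchor_minus, 3]
  expect_true(all(abs(zp - 7.5) < 4))
  expect_true(all(abs(zm + 7.5) < 4))
  expect_error(tag_regions(m, 0), "positive")
})

test_that("remeshing a surface preserves volume and validity", {
  m <- make_sphere_mesh(50, 6)
  s <- extract_boundary(m)
  m2 <- remesh_from_surface(s, target_edge = 6)
  expect_lt(abs(mesh_volume(m2) / mesh_volume(m) - 1), 0.02)
  expect_gt(min(cytomech:::tet_volumes(m2$nodes, m2$elems)), 0)
  expect_silent(cytomech:::check_closed_surface(extract_boundary(m2)))
})

test_that("broken surfaces are rejected by the remesher", {
  m <- make_sphere_mesh(50, 10)
  s <- extract_boundary(m)
  s$tris <- s$tris[-5, ]                      # delete one triangle
  expect_error(remesh_from_surface(s), "manifold")
  ## strongly non-axisymmetric input
  s2 <- extract_boundary(m)
  s2$nodes[, 1] <- s2$nodes[, 1] * (1 + 0.8 * (s2$nodes[, 2] > 0))
  s2$info <- NULL
  expect_error(remesh_from_surface(s2), "axisymmetric")
})

test_that("surface volume matches the tetrahedral volume", {
  m <- make_sphere_mesh(40, 6)
  expect_lt(abs(surface_volume(extract_boundary(m)) / mesh_volume(m) - 1),
            1e-9)
})
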