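test_that("default cylinder mesh hits the published element count and edge
           band", {
  mesh <- build_mesh(specimen_geometry())
  expect_identical(mesh$n_elements, 1520L)
  edges <- mesh_edge_lengths(mesh)
  expect_gte(min(edges), 0.8e-3)
  expect_lte(max(edges), 3e-3)
})

test_that("meshes are geometrically sound: node sets, Jacobians, volume", {
  geo <- specimen_geometry()
  mesh <- build_mesh(geo, refinement = "coarse")
  expect_true(all(abs(mesh$nodes[mesh$bottom_face_nodes, 3]) < 1e-12))
  expect_true(all(abs(mesh$nodes[mesh$top_face_nodes, 3] - geo$height) < 1e-12))
  # all element volumes positive (positive Jacobians at integration points)
  vols <- viscofit:::element_volumes(mesh)
  expect_true(all(vols > 0))
  # cylinder volume within 2% (surface faceting), cube exact
  expect_equal(mesh_volume(mesh), pi * 0.009^2 * 0.012, tolerance = 0.02)
  mesh_d <- build_mesh(geo)
  expect_equal(mesh_volume(mesh_d), pi * 0.009^2 * 0.012, tolerance = 0.02)
  cube <- build_mesh(specimen_geometry("cube"), refinement = c(4, 4, 3))
  geo_c <- specimen_geometry("cube")
  expect_equal(mesh_volume(cube), geo_c$side^2 * geo_c$height,
               tolerance = 1e-12)
})

test_that("cube with edge target equal to its side gives a single element", {
  geo <- specimen_geometry("cube", height = 1, side = 1)
  mesh <- build_mesh(geo, target_edge_length = 1)
  expect_identical(mesh$n_elements, 1L)
  expect_identical(nrow(mesh$nodes), 8L)
})

test_that("area matching and refinement behave as specified", {
  geo <- specimen_geometry("cube")
  expect_equal(geo$side, sqrt(pi * 0.018^2 / 4))
  expect_equal(geo$area, pi * 0.018^2 / 4)

  # finer edge targets never decrease the element count
  counts <- vapply(c(4e-3, 3e-3, 2e-3, 1.5e-3, 1.2e-3, 1e-3), function(h) {
    build_mesh(specimen_geometry(), target_edge_length = h)$n_elements
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(build_mesh(specimen_geometry(), target_edge_length = 0.02),
               "height")

  levels <- mesh_refinement_levels()
  nel <- vapply(names(levels), function(l) {
    build_mesh(specimen_geometry(), refinement = l)$n_elements
  }, integer(1))
  expect_identical(unname(nel), c(176L, 567L, 1520L, 3185L))
})

test_that("scale_height keeps the cross-section and rescales the height", {
  geo <- specimen_geometry()
  short <- scale_height(geo, 0.7)
  expect_equal(short$height, 0.7 * geo$height)
  expect_equal(short$area, geo$area)
})
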