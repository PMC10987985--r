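test_that("generated vault reproduces the requested dimensions", {
  sk <- fix_skull()
  d <- measure_bpd_ofd(sk)
  h <- sk$params$mesh_size_mm
  expect_lt(abs(d[["ofd_mm"]] - 152.6), h)
  expect_lt(abs(d[["bpd_mm"]] - 108.3), h)
  expect_lt(abs(max(sk$nodes[, 3]) - sk$params$height_mm), h)
  # scaphocephalic proportions
  expect_lt(d[["bpd_mm"]] / d[["ofd_mm"]], 1)
})

test_that("near-equal axes drive the cranial index towards 1", {
  p <- skull_params(ofd_mm = 152.6, bpd_mm = 152.1, mesh_size_mm = 16)
  d <- measure_bpd_ofd(generate_skull(p))
  expect_gt(d[["bpd_mm"]] / d[["ofd_mm"]], 0.98)
  # invalid (non-scaphocephalic) proportions are rejected
  expect_error(skull_params(ofd_mm = 100, bpd_mm = 120), "scaphocephalic")
})

test_that("mesh is bilaterally symmetric in nodes and labels", {
  sk <- fix_skull()
  expect_setequal_points(sk$nodes, mirror_y(sk$nodes), tol = 1e-6)
  # element regions are symmetric too: mirror centroids and re-look-up
  cent <- (sk$nodes[sk$elems[, 1], ] + sk$nodes[sk$elems[, 2], ] +
             sk$nodes[sk$elems[, 3], ] + sk$nodes[sk$elems[, 4], ]) / 4
  key <- function(m) paste(round(m[, 1], 4), round(abs(m[, 2]), 4),
                           round(m[, 3], 4))
  tab <- split(as.character(sk$region), key(cent))
  expect_true(all(vapply(tab, function(v) length(unique(v)) == 1,
                         logical(1))))
})

test_that("the five region labels tile the element set with non-empty sutures", {
  sk <- fix_skull()
  counts <- table(sk$region)
  expect_identical(sort(names(counts)),
                   sort(c("frontal", "coronal_suture", "parietal",
                          "lambdoid_suture", "occipital")))
  expect_true(all(counts > 0))
  expect_identical(sum(counts), length(sk$region))
  # suture bands sit an order of magnitude softer by default
  expect_equal(unique(sk$elem_scale[sk$region == "coronal_suture"]), 0.1)
  expect_equal(unique(sk$elem_scale[sk$region == "parietal"]), 1)
})

test_that("base node set collects the reference-plane rim", {
  sk <- fix_skull()
  expect_gt(length(sk$base_nodes), 0)
  expect_true(all(sk$nodes[sk$base_nodes, 3] <=
                    0.15 * sk$params$thickness_mm + 1e-9))
  # the rim spans the full width and length of the footprint
  rim <- sk$nodes[sk$base_nodes, ]
  expect_gt(diff(range(rim[, 1])), 0.9 * 152.6)
})

test_that("uniform-thickness shell measures back its thickness", {
  th <- measure_thickness(fix_skull())
  expect_equal(th$mean_mm, 2.02, tolerance = 1e-6)
  expect_lt(th$sd_mm, 1e-9)
  # doubling the generator thickness doubles the measured mean
  p2 <- test_params(thickness_mm = 2 * 2.02)
  th2 <- measure_thickness(generate_skull(p2))
  expect_equal(th2$mean_mm, 2 * th$mean_mm, tolerance = 1e-6)
  # measured points are confined to the top quarter of the height
  expect_true(all(th$map$z >= 0.75 * max(fix_skull()$nodes[, 3]) - 1e-9))
})

test_that("osteotomies cut the parietal region and place notch pairs", {
  cut <- fix_cut()
  expect_length(cut$notch_pairs, 2)
  expect_named(cut$notch_pairs, c("anterior", "posterior"))
  # duplicated-node crack bookkeeping: one duplicate per cut-face node
  n_dup <- length(cut$cut_faces$right$duplicate) +
    length(cut$cut_faces$left$duplicate)
  expect_identical(nrow(cut$nodes) - nrow(fix_skull()$nodes), n_dup)
  # nodes across each cut are coincident but topologically disconnected
  for (side in cut$cut_faces) {
    expect_equal(cut$nodes[side$original, ], cut$nodes[side$duplicate, ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # region labels preserved by cutting: identical to the uncut twin built
  # on the same (station-remapped) geometry
  twin <- generate_skull(cut$params, y_stations = cut$y_stations)
  expect_identical(as.character(cut$region), as.character(twin$region))
  # element count unchanged (cracks duplicate nodes, not elements)
  expect_identical(nrow(cut$elems), nrow(fix_skull()$elems))
})

test_that("notch pairs sit at the requested arc positions and separation", {
  cut <- fix_cut()
  spec <- cut$osteotomy
  h <- cut$params$mesh_size_mm
  expect_equal(cut$notch_pairs$anterior$arc_mm, spec$a_mm)
  expect_equal(cut$notch_pairs$posterior$arc_mm, spec$a_mm + spec$b_mm)
  for (np in cut$notch_pairs) {
    cl <- colMeans(cut$nodes[np$left, , drop = FALSE])
    cr <- colMeans(cut$nodes[np$right, , drop = FALSE])
    # wall-to-wall separation calibrated to LAT
    expect_equal(sqrt(sum((cr - cl)^2)), spec$lat_mm, tolerance = 0.01)
    # mirror symmetry of the pair
    expect_equal(cl[c(1, 3)], cr[c(1, 3)], tolerance = 1e-6)
    expect_equal(cl[2], -cr[2], tolerance = 1e-6)
  }
  # measured arc positions from the coronal suture match the spec within
  # one edge length
  arcs <- craniospring:::.cut_line_arcs(cut, cut$cut_faces$right$station)
  for (np in cut$notch_pairs) {
    cr <- colMeans(cut$nodes[np$right, , drop = FALSE])
    i_near <- which.min(abs(arcs$s - {
      # arc coordinate of the notch centroid along the cut line
      pts <- cut$nodes[cut$node_grid[, cut$cut_faces$right$station, 1], ]
      arcs$s[which.min(colSums((t(pts) - cr)^2))]
    }))
    expect_lt(abs(arcs$s[i_near] - arcs$s_coronal - np$arc_mm), h)
  }
})

test_that("degenerate and infeasible osteotomies are rejected", {
  expect_error(osteotomy_spec(18.3, 47.9, 0), "coincident")
  expect_error(apply_osteotomies(fix_skull(),
                                 osteotomy_spec(18.3, 140, 26.2)),
               "outside parietal segment")
  expect_error(apply_osteotomies(fix_cut(), mean_osteotomy()),
               "already carries")
})

test_that("refinement preserves geometry while increasing resolution", {
  sk <- generate_skull(skull_params(mesh_size_mm = 18))
  fine <- refine_skull(sk, 1.5)
  expect_gt(nrow(fine$elems), nrow(sk$elems))
  d0 <- measure_bpd_ofd(sk)
  d1 <- measure_bpd_ofd(fine)
  expect_lt(abs(d0[["ofd_mm"]] - d1[["ofd_mm"]]), 0.5)
  expect_lt(abs(d0[["bpd_mm"]] - d1[["bpd_mm"]]), 0.5)
  # region proportions conserved under refinement
  p0 <- prop.table(table(sk$region))
  p1 <- prop.table(table(fine$region))
  expect_lt(max(abs(p0 - p1)), 0.08)
  # two successive refinements bracket one refinement of the squared factor
  f2 <- refine_skull(refine_skull(sk, 1.4), 1.4)
  f4 <- refine_skull(sk, 1.4^2)
  expect_gt(nrow(f2$elems), nrow(sk$elems))
  expect_lt(abs(nrow(f2$elems) - nrow(f4$elems)) / nrow(f4$elems), 0.3)
  # cuts and notch pairs survive refinement
  fine_cut <- refine_skull(fix_cut(), 1.2)
  expect_length(fine_cut$notch_pairs, 2)
  expect_false(is.null(fine_cut$osteotomy))
})
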