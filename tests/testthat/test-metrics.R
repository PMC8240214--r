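test_that("DSC hits its analytic values", {
  g <- image_grid(c(20, 20, 20))
  a <- box_mask(g, c(3, 3, 3), c(12, 12, 12))
  expect_identical(dice(a, a), 1)
  disjoint <- box_mask(g, c(15, 15, 15), c(18, 18, 18))
  expect_identical(dice(a, disjoint), 0)
  shifted <- box_mask(g, c(8, 3, 3), c(17, 12, 12))   # +5 voxels along x
  expect_identical(dice(a, shifted), 0.5)
  expect_identical(dice(shifted, a), dice(a, shifted))
  both_empty <- structure_mask(array(FALSE, c(20, 20, 20)), g)
  expect_error(dice(both_empty, both_empty), "empty")
  expect_error(dice(a, structure_mask(array(FALSE, c(21, 20, 20)),
                                      image_grid(c(21, 20, 20)))),
               "grid mismatch")
})

test_that("surface extraction counts boundary voxels under 6-connectivity", {
  g5 <- image_grid(c(5, 5, 5))
  expect_identical(extract_surface(box_mask(g5, c(2, 2, 2), c(4, 4, 4)))$count,
                   26L)                      # 3^3 minus center
  expect_identical(extract_surface(box_mask(g5, c(3, 3, 3), c(3, 3, 3)))$count,
                   1L)
  g7 <- image_grid(c(7, 7, 7))
  expect_identical(extract_surface(box_mask(g7, c(2, 2, 2), c(6, 6, 6)))$count,
                   98L)                      # 5^3 - 3^3
  # volume-edge voxels count as boundary: a full volume is all surface shell
  gfull <- image_grid(c(4, 4, 4))
  full <- structure_mask(array(TRUE, c(4, 4, 4)), gfull)
  expect_identical(extract_surface(full)$count, 56L)  # 4^3 - 2^3
  empty <- structure_mask(array(FALSE, c(4, 4, 4)), gfull)
  expect_identical(extract_surface(empty)$count, 0L)
})

test_that("directed distances follow the mm geometry", {
  g <- image_grid(c(8, 8, 8), c(1, 1, 3))
  a <- box_mask(g, c(3, 3, 2), c(3, 3, 2))
  b <- box_mask(g, c(3, 3, 5), c(3, 3, 5))   # 3 slices = 9 mm apart
  expect_identical(directed_distances(extract_surface(a),
                                      extract_surface(b)), 9)
  big <- box_mask(g, c(2, 2, 2), c(6, 6, 6))
  sub <- box_mask(g, c(2, 2, 2), c(6, 6, 2))  # one face of big
  expect_identical(unique(directed_distances(extract_surface(sub),
                                             extract_surface(big))), 0)
  expect_error(directed_distances(extract_surface(a),
                                  extract_surface(structure_mask(
                                    array(FALSE, c(8, 8, 8)), g))),
               "empty")
})

test_that("production distances equal the brute-force oracle bit-for-bit", {
  set.seed(202)
  for (rep in 1:12) {
    shape <- sample(8:15, 3, replace = TRUE)
    spacing <- sample(c(0.8, 1, 2, 3), 3, replace = TRUE)
    g <- image_grid(shape, spacing, origin = stats::runif(3, -5, 5))
    a <- random_blob_mask(g)
    b <- random_blob_mask(g)
    sa <- extract_surface(a); sb <- extract_surface(b)
    oa <- oracle_surface_points(a); ob <- oracle_surface_points(b)
    expect_identical(sa$points, oa)
    expect_identical(directed_distances(sa, sb), oracle_directed(oa, ob))
    expect_identical(directed_distances(sb, sa), oracle_directed(ob, oa))
  }
})

test_that("MSD and HD95 hit analytic plate and identity cases", {
  g <- image_grid(c(12, 12, 6), c(1, 1, 1))
  p0 <- box_mask(g, c(2, 2, 1), c(11, 11, 1))
  p3 <- box_mask(g, c(2, 2, 4), c(11, 11, 4))   # parallel plates, z = 0 and 3
  expect_identical(msd(p0, p3), 3)
  expect_identical(hd95(p0, p3), 3)
  blob <- sphere_mask(image_grid(c(16, 16, 16)), c(8, 8, 8), 5)
  expect_identical(msd(blob, blob), 0)
  expect_identical(hd95(blob, blob), 0)
  empty <- structure_mask(array(FALSE, c(16, 16, 16)),
                          image_grid(c(16, 16, 16)))
  expect_error(msd(blob, empty), "empty")
  expect_error(hd95(empty, blob), "empty")
})

test_that("MSD/HD95 match the oracle on dilations and spiked cubes", {
  g <- image_grid(c(26, 26, 26))
  cube <- box_mask(g, c(4, 4, 4), c(23, 23, 23))    # 20^3 cube
  dil <- dilate6(cube)
  expect_equal(msd(cube, dil), oracle_msd(cube, dil), tolerance = 1e-12)
  expect_equal(hd95(cube, dil), oracle_hd95(cube, dil), tolerance = 1e-12)

  spiked <- box_mask(g, c(6, 6, 6), c(15, 15, 15))
  socc <- spiked$occupancy
  socc[10, 10, 16:20] <- TRUE                      # 1x1x5 protruding spike
  spiked2 <- structure_mask(socc, g)
  base <- box_mask(g, c(6, 6, 6), c(15, 15, 15))
  h95 <- hd95(base, spiked2)
  hmax <- max(c(oracle_pooled(base, spiked2)))
  expect_lt(h95, hmax)
  expect_equal(h95, oracle_hd95(base, spiked2), tolerance = 1e-12)
  expect_equal(msd(base, spiked2), oracle_msd(base, spiked2),
               tolerance = 1e-12)
})

test_that("metrics are symmetric, translation-invariant and scale with spacing", {
  set.seed(303)
  for (rep in 1:6) {
    g <- image_grid(c(18, 18, 14), c(1, 1, 2))
    a <- random_blob_mask(g)
    b <- random_blob_mask(g)
    expect_identical(dice(a, b), dice(b, a))
    expect_equal(msd(a, b), msd(b, a), tolerance = 1e-13)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-13)
    expect_gte(dice(a, b), 0); expect_lte(dice(a, b), 1)
    pooled_max <- max(oracle_pooled(a, b))
    expect_lte(msd(a, b), pooled_max + 1e-12)
    expect_lte(hd95(a, b), pooled_max + 1e-12)

    # same integer-voxel translation of both masks
    off <- c(2L, 1L, 1L)
    shift_mask <- function(m) {
      d <- m$grid$shape
      occ <- array(FALSE, d)
      occ[(1 + off[1]):d[1], (1 + off[2]):d[2], (1 + off[3]):d[3]] <-
        m$occupancy[1:(d[1] - off[1]), 1:(d[2] - off[2]), 1:(d[3] - off[3])]
      structure_mask(occ, m$grid)
    }
    # keep away from the edge so nothing is clipped
    inner <- function(m) {
      occ <- m$occupancy
      occ[c(1:3, 16:18), , ] <- FALSE
      occ[, c(1:3, 16:18), ] <- FALSE
      occ[, , c(1:3, 12:14)] <- FALSE
      if (!any(occ)) occ[9, 9, 7] <- TRUE
      structure_mask(occ, m$grid)
    }
    ai <- inner(a); bi <- inner(b)
    expect_equal(dice(shift_mask(ai), shift_mask(bi)), dice(ai, bi),
                 tolerance = 1e-13)
    expect_equal(msd(shift_mask(ai), shift_mask(bi)), msd(ai, bi),
                 tolerance = 1e-12)
    expect_equal(hd95(shift_mask(ai), shift_mask(bi)), hd95(ai, bi),
                 tolerance = 1e-12)

    # scaling spacing by c scales distances by c and leaves DSC unchanged
    for (cf in c(0.5, 2.5)) {
      gs <- image_grid(c(18, 18, 14), c(1, 1, 2) * cf)
      as_ <- structure_mask(a$occupancy, gs)
      bs <- structure_mask(b$occupancy, gs)
      expect_identical(dice(as_, bs), dice(a, b))
      expect_equal(msd(as_, bs), cf * msd(a, b), tolerance = 1e-12)
      expect_equal(hd95(as_, bs), cf * hd95(a, b), tolerance = 1e-12)
    }
  }
})

test_that("DSC is volume-biased while MSD is stable under a 1-voxel dilation", {
  g <- image_grid(c(48, 48, 48))
  dscs <- msds <- numeric(0)
  for (r in c(5, 10, 20)) {
    s <- sphere_mask(g, c(24, 24, 24), r)
    d <- dilate6(s)
    dscs <- c(dscs, dice(s, d))
    msds <- c(msds, msd(s, d))
  }
  expect_true(all(diff(dscs) > 0))
  expect_true(all(msds >= 0.5 & msds <= 1.5))
})

test_that("digitized nested-sphere DSC approaches the continuum ratio", {
  g <- image_grid(c(52, 52, 52))
  for (r in c(10, 14, 18)) {
    dlt <- 2
    inner <- sphere_mask(g, c(26, 26, 26), r)
    outer_ <- sphere_mask(g, c(26, 26, 26), r + dlt)
    expected <- 2 * r^3 / (r^3 + (r + dlt)^3)
    expect_lt(abs(dice(inner, outer_) - expected), 0.03)
  }
})

test_that("directed MSD option reports both one-sided means", {
  g <- image_grid(c(20, 20, 20))
  a <- box_mask(g, c(5, 5, 5), c(14, 14, 14))
  b <- dilate6(a)
  d <- msd(a, b, directed = TRUE)
  expect_equal(d$symmetric, msd(a, b), tolerance = 1e-13)
  sa <- extract_surface(a); sb <- extract_surface(b)
  expect_equal(d$a_to_b, mean(directed_distances(sa, sb)), tolerance = 1e-13)
  expect_equal(d$b_to_a, mean(directed_distances(sb, sa)), tolerance = 1e-13)
})

test_that("compare_masks maps empty and absent inputs to explicit statuses", {
  g <- image_grid(c(12, 12, 12), c(1, 1, 3))
  ref <- box_mask(g, c(3, 3, 3), c(8, 8, 8))
  empty <- structure_mask(array(FALSE, c(12, 12, 12)), g)

  nd <- compare_masks(ref, NULL)
  expect_identical(nd$status, "NOT_DELINEATED")
  expect_true(is.na(nd$dsc) && is.na(nd$msd_mm) && is.na(nd$hd95_mm))

  te <- compare_masks(ref, empty)
  expect_identical(te$status, "TEST_EMPTY")
  expect_identical(te$dsc, 0)
  expect_true(is.na(te$msd_mm))

  re <- compare_masks(empty, ref)
  expect_identical(re$status, "REF_EMPTY")
  expect_identical(re$dsc, 0)

  be <- compare_masks(empty, empty)
  expect_identical(be$status, "BOTH_EMPTY")
  expect_true(is.na(be$dsc))

  ok <- compare_masks(ref, ref)
  expect_identical(ok$status, "OK")
  expect_identical(ok$dsc, 1)
  expect_identical(ok$msd_mm, 0)
  expect_identical(ok$hd95_mm, 0)
  expect_equal(ok$volume_ref_cc, sum(ref$occupancy) * 3 / 1000)
  expect_error(compare_masks(NULL, ref), "reference")
})

test_that("volume_cc multiplies voxel count by voxel volume", {
  g1 <- image_grid(c(10, 10, 10))
  m <- box_mask(g1, c(1, 1, 1), c(10, 10, 10))
  expect_identical(volume_cc(m), 1)
  g3 <- image_grid(c(64, 64, 40), c(1, 1, 3))
  occ <- array(FALSE, c(64, 64, 40)); occ[1:100] <- TRUE
  expect_equal(volume_cc(structure_mask(occ, g3)), 0.3)
  expect_identical(volume_cc(structure_mask(array(FALSE, c(10, 10, 10)), g1)),
                   0)
})
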