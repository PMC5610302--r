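test_that("inclusion band on a 3x3 slice keeps exactly the voxels within 20% of the seed", {
  sl <- rbind(c(100, 85, 79), c(120, 121, 60), c(50, 40, 30))
  vol <- image_volume(array(sl, dim = c(3, 3, 1)), c(1, 1, 1))
  m <- region_grow(vol, rbind(c(0, 0, 0)))  # seed 100 -> band [80, 120]
  got <- which(m$data[, , 1], arr.ind = TRUE)
  expect_setequal(paste(got[, 1], got[, 2]), c("1 1", "1 2", "2 1"))
  # 121 (over band) and 79 (under band) stay out
  expect_false(m$data[2, 2, 1])
  expect_false(m$data[1, 3, 1])
  # every included voxel satisfies the predicate, every excluded 8-neighbour
  # of the region fails it
  inband <- sl >= 80 & sl <= 120
  expect_true(all(inband[m$data[, , 1]]))
  boundary <- elfdose:::dilate2d(m$data[, , 1], 8L) & !m$data[, , 1]
  expect_true(all(!inband[boundary]))
})

test_that("noiseless phantom is recovered exactly from per-slice seeds", {
  sp <- quick_spec(noise_sd = 0, spacing = c(1, 1, 2),
                   shape = c(40L, 40L, 12L), semiaxes = c(12, 10, 8),
                   center = c(19.5, 19.5, 11))
  pair <- make_phantom_pair(sp, sp)
  m <- region_grow(pair$dwi, seeds_from_mask(pair$truth_pre))
  expect_identical(m$data, pair$truth_pre$data)
})

test_that("output is invariant to seed order, seed multiplicity, and traversal strategy", {
  set.seed(11)
  vol <- image_volume(array(runif(32 * 32 * 3, 50, 150),
                            dim = c(32, 32, 3)), c(1, 1, 5))
  seeds <- cbind(sample(0:31, 6, TRUE), sample(0:31, 6, TRUE),
                 sample(0:2, 6, TRUE))
  m1 <- region_grow(vol, seeds)
  m2 <- region_grow(vol, seeds[sample(nrow(seeds)), ])
  expect_identical(m1$data, m2$data)
  # two seeds inside one region add nothing (union idempotence)
  sp <- quick_spec(noise_sd = 0, shape = c(30L, 30L, 6L),
                   semiaxes = c(8, 8, 4), spacing = c(1, 1, 2),
                   center = c(14.5, 14.5, 5))
  pair <- make_phantom_pair(sp, sp)
  s1 <- seeds_from_mask(pair$truth_pre)
  s2 <- rbind(s1, s1[1, ] + c(1L, 0L, 0L))
  expect_identical(region_grow(pair$dwi, s1)$data,
                   region_grow(pair$dwi, s2)$data)
  # fixed-point growth equals explicit DFS and BFS flood fills
  for (ord in c("lifo", "fifo")) {
    for (r in seq_len(nrow(seeds))) {
      s <- seeds[r, ]
      I_seed <- vol$data[s[1] + 1, s[2] + 1, s[3] + 1]
      ff <- flood_fill_slice(vol$data[, , s[3] + 1], s[1:2] + 1L,
                             0.8 * I_seed, 1.2 * I_seed, 8L, ord)
      m <- region_grow(vol, rbind(s))
      expect_identical(m$data[, , s[3] + 1], ff)
    }
  }
})

test_that("mask grows monotonically with the relative threshold", {
  set.seed(21)
  for (rep in 1:3) {
    vol <- image_volume(array(runif(32 * 32 * 2, 50, 150),
                              dim = c(32, 32, 2)), c(1, 1, 5))
    seeds <- cbind(sample(0:31, 4, TRUE), sample(0:31, 4, TRUE),
                   sample(0:1, 4, TRUE))
    prev <- NULL
    for (t in c(0.10, 0.20, 0.40)) {
      m <- region_grow(vol, seeds, rel_threshold = t)
      if (!is.null(prev)) expect_true(all(m$data[prev]))
      prev <- m$data
    }
  }
})

test_that("one-sided band keeps everything at or above 80% of the seed", {
  sl <- rbind(c(100, 130, 200), c(90, 79, 81))
  vol <- image_volume(array(sl, dim = c(2, 3, 1)), c(1, 1, 1))
  m <- region_grow(vol, rbind(c(0, 0, 0)), band = "lower")
  expect_true(all(m$data[, , 1][sl >= 80]))
  expect_false(m$data[2, 2, 1])
})

test_that("3D growth crosses slices while slice mode does not", {
  sp <- quick_spec(noise_sd = 0, shape = c(20L, 20L, 8L),
                   semiaxes = c(6, 6, 5), spacing = c(1, 1, 2),
                   center = c(9.5, 9.5, 7))
  pair <- make_phantom_pair(sp, sp)
  seed_mid <- seeds_from_mask(pair$truth_pre)
  k_mid <- seed_mid[ceiling(nrow(seed_mid) / 2), , drop = FALSE]
  m2d <- region_grow(pair$dwi, k_mid, mode = "slice")
  m3d <- region_grow(pair$dwi, k_mid, mode = "3d")
  expect_identical(m3d$data, pair$truth_pre$data)
  expect_true(sum(m2d$data) < sum(m3d$data))
  expect_true(all(apply(m2d$data, 3, sum)[-(k_mid[3] + 1)] == 0))
})

test_that("seed validation rejects out-of-bounds and non-positive intensities", {
  vol <- image_volume(array(1, dim = c(4, 4, 2)), c(1, 1, 1))
  expect_error(region_grow(vol, rbind(c(4, 0, 0))), "out of grid bounds")
  expect_error(region_grow(vol, rbind(c(-1, 0, 0))), "out of grid bounds")
  vol0 <- image_volume(array(0, dim = c(4, 4, 2)), c(1, 1, 1))
  expect_error(region_grow(vol0, rbind(c(0, 0, 0))), "intensity must be > 0")
  expect_error(region_grow(vol, matrix(numeric(0), ncol = 3)),
               "at least one seed")
})

test_that("edit_mask applies add/remove with remove winning on conflict", {
  sp <- quick_spec(noise_sd = 0, shape = c(20L, 20L, 4L),
                   semiaxes = c(5, 5, 3), spacing = c(1, 1, 2),
                   center = c(9.5, 9.5, 3))
  truth <- make_phantom_pair(sp, sp)$truth_pre
  empty <- lesion_mask(array(FALSE, dim(truth$data)),
                       geometry_from = truth)
  expect_identical(edit_mask(truth, empty, empty)$data, truth$data)
  expect_equal(sum(edit_mask(truth, empty, truth)$data), 0L)
  # disjoint add of n voxels grows the count by exactly n
  add <- empty
  add$data[1:3, 1, 1] <- TRUE
  expect_equal(sum(edit_mask(truth, add, empty)$data),
               sum(truth$data) + 3L)
  # overlap: remove wins
  both <- empty
  both$data[1:3, 1, 1] <- TRUE
  expect_equal(sum(edit_mask(truth, both, both)$data), sum(truth$data))
  # geometry mismatch is an error
  other <- lesion_mask(array(FALSE, c(10, 10, 2)), spacing_mm = c(1, 1, 2))
  expect_error(edit_mask(truth, other, empty), "share grid geometry")
})

test_that("volumetry multiplies voxel count by pixel spacing and slice thickness", {
  mk <- function(n, dims, spacing) {
    a <- array(FALSE, dims)
    a[seq_len(n)] <- TRUE
    lesion_mask(a, spacing_mm = spacing)
  }
  expect_equal(lesion_volume(mk(1000, c(10, 10, 10), c(1, 1, 1))), 1.0)
  expect_equal(lesion_volume(mk(500, c(10, 10, 10), c(0.9, 0.9, 5))), 2.025)
  # linear in each spacing component, additive over disjoint masks
  m <- mk(123, c(10, 10, 10), c(1, 1, 1))
  expect_equal(lesion_volume(m, c(2, 1, 1)), 2 * lesion_volume(m))
  expect_equal(lesion_volume(m, c(1, 3, 1)), 3 * lesion_volume(m))
  a <- mk(40, c(10, 10, 10), c(1, 1, 1))
  b <- mk(100, c(10, 10, 10), c(1, 1, 1))
  b$data[seq_len(40)] <- FALSE  # disjoint remainder
  u <- lesion_mask(a$data | b$data, spacing_mm = c(1, 1, 1))
  expect_equal(lesion_volume(u), lesion_volume(a) + lesion_volume(b))
  # empty mask warns and returns 0
  e <- lesion_mask(array(FALSE, c(4, 4, 4)), spacing_mm = c(1, 1, 1))
  expect_warning(v <- lesion_volume(e), "empty mask")
  expect_equal(v, 0)
})

test_that("per-slice area table matches the mask slice by slice", {
  sp <- quick_spec(noise_sd = 0, shape = c(24L, 24L, 6L),
                   semiaxes = c(5, 5, 4), spacing = c(0.5, 0.5, 2),
                   center = c(5.75, 5.75, 5))
  truth <- make_phantom_pair(sp, sp)$truth_pre
  tab <- slice_area_table(truth)
  expect_equal(nrow(tab), 6L)
  expect_equal(tab$voxels, as.integer(apply(truth$data, 3, sum)))
  expect_equal(tab$area_mm2, tab$voxels * 0.25)
  expect_equal(sum(tab$voxels), sum(truth$data))
})
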