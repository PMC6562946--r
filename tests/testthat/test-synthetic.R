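test_that("identical specs generate bitwise-identical scenes", {
  sp <- scene_spec(96, 96, n_nuclei = 30, seed = 7)
  expect_identical(generate_scene(sp), generate_scene(sp))
})

test_that("an empty spec yields pure background", {
  sc <- generate_scene(scene_spec(64, 64, n_nuclei = 0, seed = 3))
  expect_true(all(sc$labels == 0L))
  expect_equal(dim(sc$image), c(64, 64, 3))
  expect_equal(scene_statistics(sc$labels)$count, 0)
})

test_that("requested instance count and minimum areas are honored", {
  sp <- scene_spec(256, 256, n_nuclei = 40, radius_range = c(4, 10), seed = 1)
  sc <- generate_scene(sp)
  ids <- sort(unique(sc$labels[sc$labels > 0]))
  expect_identical(ids, 1:40)
  areas <- vapply(ids, function(i) sum(sc$labels == i), numeric(1))
  expect_true(all(areas >= sp$min_instance_area))
})

test_that("instance areas and background always partition the frame", {
  for (seed in 1:3) {
    sc <- generate_scene(scene_spec(80, 80, n_nuclei = 15, seed = seed,
                                    max_overlap_fraction = 0.4,
                                    min_instance_area = 10))
    st <- scene_statistics(sc$labels)
    expect_equal(sum(st$areas) + sum(sc$labels == 0), 80 * 80)
  }
})

test_that("a dense preset lands in the dense regime (count > 25)", {
  sc <- generate_scene(scene_spec(256, 256, n_nuclei = 26, seed = 11))
  expect_gt(scene_statistics(sc$labels)$count, 25)
})

test_that("infeasible packing fails with the achieved count", {
  sp <- scene_spec(48, 48, n_nuclei = 200, radius_range = c(8, 10),
                   max_overlap_fraction = 0, seed = 2)
  expect_error(generate_scene(sp), "placed \\d+")
})

test_that("scene statistics match manual pixel counts on a toy map", {
  lab <- matrix(0L, 6, 6)
  lab[1:2, 1:2] <- 1L          # 4 px
  lab[4:6, 1:3] <- 2L          # 9 px
  lab[1:3, 5:6] <- 3L          # 6 px
  st <- scene_statistics(lab)
  expect_equal(st$count, 3)
  expect_equal(unname(st$areas), c(4, 9, 6))
  expect_equal(st$min_area, 4)
  expect_equal(st$max_area, 9)
  expect_equal(st$adjacency_count, 0)
  lab[3, 1:2] <- 1L            # extend instance 1 to touch instance 2
  expect_equal(scene_statistics(lab)$adjacency_count, 1)
})

test_that("imaging modes render their characteristic palettes", {
  bf <- generate_scene(scene_spec(96, 96, n_nuclei = 12, mode = "brightfield",
                                  seed = 5))
  fl <- generate_scene(scene_spec(96, 96, n_nuclei = 12, mode = "fluorescence",
                                  seed = 5))
  bg_bf <- apply(bf$image, 3, function(p) mean(p[bf$labels == 0]))
  nuc_bf <- apply(bf$image, 3, function(p) mean(p[bf$labels > 0]))
  # brightfield: bright pink/grey background, dark blue-dominant nuclei
  expect_gt(mean(bg_bf), 150)
  expect_lt(mean(nuc_bf), 120)
  expect_gt(nuc_bf[3], nuc_bf[2])  # blue over green in nuclei
  bg_fl <- mean(fl$image[cbind(which(fl$labels == 0, arr.ind = TRUE), 2)])
  nuc_fl <- mean(fl$image[cbind(which(fl$labels > 0, arr.ind = TRUE), 2)])
  # fluorescence: dark background, bright blobs
  expect_lt(bg_fl, 40)
  expect_gt(nuc_fl, 100)
})

test_that("invalid specs are rejected", {
  expect_error(scene_spec(n_nuclei = -1), "n_nuclei")
  expect_error(scene_spec(radius_range = c(5, 2)), "radius_range")
  expect_error(scene_spec(max_overlap_fraction = 1.5), "overlap")
  expect_error(scene_spec(min_instance_area = 0), "min_instance_area")
})

test_that("seeded scene generation leaves the caller's RNG untouched", {
  set.seed(99)
  before <- .Random.seed
  generate_scene(scene_spec(48, 48, n_nuclei = 5, seed = 1,
                            min_instance_area = 10))
  expect_identical(.Random.seed, before)
})
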