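test_that("scene generation is a pure function of its spec", {
  sp <- desk_spec(42)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$instances, b$instances)
  sp2 <- sp; sp2$seed <- 43L
  expect_false(identical(generate_scene(sp2)$instances, a$instances))
  # the generator must not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(generate_scene(sp)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("nucleus counts and disjointness honour the spec", {
  empty <- generate_scene(scene_spec(height = 64, width = 64,
                                     n_nuclei = c(0L, 0L), seed = 1,
                                     radius_px = c(5, 8)))
  expect_equal(empty$n_nuclei, 0L)
  expect_equal(max(empty$instances), 0L)
  five <- generate_scene(scene_spec(height = 128, width = 128,
                                    n_nuclei = c(5L, 5L),
                                    radius_px = c(4, 6),
                                    overlap_fraction = 0, seed = 7))
  expect_equal(five$n_nuclei, 5L)
  expect_identical(sort(unique(as.vector(five$instances))), c(0L, 1:5))
  # binary layer is exactly instances > 0
  expect_identical(five$binary, five$instances > 0L)
  expect_error(scene_spec(height = 16, width = 16, radius_px = c(10, 12)),
               "too small")
})

test_that("every painted nucleus pixel belongs to an instance (pre-noise)", {
  for (seed in 1:5) {
    s <- generate_scene(desk_spec(seed), keep_layers = TRUE)
    painted <- which(apply(abs(s$clean - s$field) > 1e-12, c(1, 2), any))
    expect_true(all(s$instances[painted] > 0L))
  }
})

test_that("mean nucleus count over 200 seeded scenes tracks the range midpoint", {
  sp <- scene_spec(height = 64, width = 64, n_nuclei = c(3L, 9L),
                   radius_px = c(4, 7), blur_sigma_px = 0,
                   texture_noise_sd = 0, seed = 1)
  counts <- vapply(1:200, function(i) {
    si <- sp; si$seed <- i
    generate_scene(si)$n_nuclei
  }, integer(1))
  mid <- mean(c(3, 9))
  expect_lt(abs(mean(counts) - mid), 0.1 * mid)
})

test_that("overlap control produces intersecting bounding boxes", {
  sp <- scene_spec(height = 64, width = 64, n_nuclei = c(4L, 6L),
                   radius_px = c(5, 9), overlap_fraction = 0.5,
                   blur_sigma_px = 0, texture_noise_sd = 0, seed = 1)
  bbox_hit <- vapply(1:40, function(i) {
    si <- sp; si$seed <- 1000L + i
    inst <- generate_scene(si)$instances
    ids <- setdiff(unique(as.vector(inst)), 0L)
    if (length(ids) < 2) return(FALSE)
    boxes <- t(vapply(ids, function(k) {
      w <- which(inst == k, arr.ind = TRUE)
      c(min(w[, 1]), max(w[, 1]), min(w[, 2]), max(w[, 2]))
    }, numeric(4)))
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1)) {
        if (boxes[a, 1] <= boxes[b, 2] && boxes[b, 1] <= boxes[a, 2] &&
            boxes[a, 3] <= boxes[b, 4] && boxes[b, 3] <= boxes[a, 4]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }, logical(1))
  expect_gte(mean(bbox_hit), 0.25)
})

test_that("generate_dataset writes rasters, manifest and round-trips exactly", {
  dir <- withr::local_tempdir()
  sp <- desk_spec(5)
  man <- generate_dataset(sp, 10, dir)
  files <- list.files(dir)
  expect_length(grep("^image_.*tiff$", files), 10)
  expect_length(grep("^inst_.*tiff$", files), 10)
  expect_true("manifest.json" %in% files)
  # manifest counts equal distinct ids on disk
  total_ids <- 0L
  for (i in 1:10) {
    inst <- read_tiff(file.path(dir, sprintf("inst_%04d.tiff", i)))
    total_ids <- total_ids + length(setdiff(unique(as.vector(inst)), 0L))
  }
  expect_equal(sum(man$nucleus_counts), total_ids)
  # round trip: arrays reproduce exactly (image up to 8-bit quantization)
  s3 <- sp; s3$seed <- sp$seed + 2L
  ref <- generate_scene(s3)
  img <- read_tiff(file.path(dir, "image_0003.tiff"))
  inst <- read_tiff(file.path(dir, "inst_0003.tiff"))
  expect_identical(inst, ref$instances)
  expect_equal(img, round(ref$image * 255) / 255, tolerance = 0)
})
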