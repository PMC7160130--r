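test_that("overlap_fraction matches pixel-count arithmetic", {
  a <- matrix(FALSE, 10, 10); a[1:10, 1:10] <- TRUE
  b <- matrix(FALSE, 10, 10)
  expect_equal(overlap_fraction(a, b), 0)
  expect_equal(overlap_fraction(a, a), 1)
  b[1:5, 1:10] <- TRUE  # covers exactly 50 of the 100 candidate pixels
  expect_equal(overlap_fraction(a, b), 0.5)
  empty <- matrix(FALSE, 10, 10)
  expect_error(overlap_fraction(empty, b), class = "undefined_fraction")
})

test_that("pasting onto an empty canvas reproduces the sprite away from the blur band", {
  pool <- small_pool(seed = 2)
  sp <- pool$sprites[[1]]
  state <- seedpheno:::new_scene_state(pool$backgrounds[[1]])
  rot <- seedpheno:::rotate_sprite(sp, 0)
  state <- paste_sprite(state, rot, x = 40L, y = 30L, blur_sigma = 1,
                        cultivar = sp$cultivar)
  h <- nrow(sp$alpha); w <- ncol(sp$alpha)
  # visible mask equals the sprite support up to the sub-pixel blur band:
  # it must contain the 1 px-eroded support and fit in the 1 px dilation
  supp <- sp$alpha > 0.5
  b3 <- EBImage::makeBrush(3, "box")
  er1 <- erode_pad(supp, b3)
  di1 <- t(as.matrix(EBImage::dilate(EBImage::Image(t(supp)), b3))) > 0.5
  win <- state$label_map[31:(30 + h), 41:(40 + w)] > 0
  expect_true(all(win[er1]))
  expect_true(all(!win[!di1]))
  expect_true(all(state$label_map[-(31:(30 + h)), ] == 0))
  # interior (>= 4 px from boundary in Chebyshev distance, beyond the
  # separable blur kernel's 3 px reach)
  interior <- erode_pad(sp$alpha > 0.5, EBImage::makeBrush(9, "box"))
  canvas_win <- state$canvas[31:(30 + h), 41:(40 + w), 1]
  expect_equal(canvas_win[interior], sp$pixels[, , 1][interior])
})

test_that("a later paste steals exactly the overlapped pixels (foreground replacement)", {
  bgsize <- 64L
  bg <- array(0.5, dim = c(bgsize, bgsize, 3))
  sq <- seed_sprite(array(0.9, dim = c(10, 10, 3)), matrix(1, 10, 10), "sq")
  state <- seedpheno:::new_scene_state(bg)
  rot <- list(pixels = sq$pixels, alpha = sq$alpha)
  state <- paste_sprite(state, rot, 10L, 10L, blur_sigma = 0)
  a_before <- sum(state$label_map == 1L)
  # overlap region: columns 18..20 x rows 11..20 => 3 * 10 = 30 px
  state <- paste_sprite(state, rot, 17L, 10L, blur_sigma = 0)
  expect_equal(a_before - sum(state$label_map == 1L), 30)
  expect_equal(sum(state$label_map == 2L), 100)
  expect_true(all(state$label_map[11:20, 18:20] == 2L))
})

test_that("blur_sigma = 0 gives a hard paste with pixels exactly sprite or background", {
  bg <- array(0.25, dim = c(40, 40, 3))
  sq <- seed_sprite(array(0.75, dim = c(7, 7, 3)), matrix(1, 7, 7), "sq")
  state <- seedpheno:::new_scene_state(bg)
  state <- paste_sprite(state, list(pixels = sq$pixels, alpha = sq$alpha),
                        5L, 5L, blur_sigma = 0)
  vals <- unique(as.vector(state$canvas))
  expect_setequal(vals, c(0.25, 0.75))
})

test_that("out-of-canvas placements violate the paste contract", {
  bg <- array(0, dim = c(32, 32, 3))
  sq <- seed_sprite(array(1, dim = c(8, 8, 3)), matrix(1, 8, 8), "sq")
  state <- seedpheno:::new_scene_state(bg)
  expect_error(paste_sprite(state, list(pixels = sq$pixels, alpha = sq$alpha),
                            28L, 0L, 0), class = "contract_violation")
})

test_that("max_trials = 0 yields the cropped background with zero instances", {
  pool <- small_pool(seed = 1)
  sc <- generate_scene(pool, small_config(max_trials = 0L), rng_seed = 5)
  expect_length(sc$instances, 0L)
  expect_true(all(sc$label_map == 0L))
  expect_equal(dim(sc$image), c(192L, 192L, 3L))
})

test_that("every accepted placement respected the overlap threshold at paste time", {
  pool <- small_pool(seed = 4)
  for (s in 1:3) {
    sc <- generate_scene(pool, small_config(), rng_seed = s)
    ins <- scene_instances(sc)
    expect_gt(nrow(ins), 0)
    expect_true(all(ins$overlap_at_paste <= 0.25 + 1e-12))
  }
})

test_that("the label map and instance masks are mutually consistent", {
  pool <- small_pool(seed = 4)
  sc <- generate_scene(pool, small_config(), rng_seed = 11)
  ins <- scene_instances(sc)
  rebuilt <- matrix(0L, nrow(sc$label_map), ncol(sc$label_map))
  for (i in seq_len(nrow(ins))) {
    rows <- (ins$y0[i] + 1):ins$y1[i]; cols <- (ins$x0[i] + 1):ins$x1[i]
    sub <- rebuilt[rows, cols]
    expect_true(all(sub[ins$mask[[i]]] == 0L))  # pairwise disjoint
    sub[ins$mask[[i]]] <- ins$instance_id[i]
    rebuilt[rows, cols] <- sub
    expect_equal(sum(ins$mask[[i]]), ins$area[i])
    # bbox tightness
    expect_true(any(ins$mask[[i]][1, ]) && any(ins$mask[[i]][nrow(ins$mask[[i]]), ]))
    expect_true(any(ins$mask[[i]][, 1]) && any(ins$mask[[i]][, ncol(ins$mask[[i]])]))
  }
  expect_equal(rebuilt, unname(sc$label_map))
})

test_that("occlusion is monotone: visible areas never grow as instances are added", {
  pool <- small_pool(seed = 9)
  bg <- pool$backgrounds[[1]]
  state <- seedpheno:::new_scene_state(bg)
  visible <- function(st, k) sum(st$label_map == k)
  set.seed(42)
  placed <- 0L
  history <- list()
  for (i in 1:8) {
    sp <- pool$sprites[[sample.int(length(pool$sprites), 1)]]
    rot <- seedpheno:::rotate_sprite(sp, runif(1, 0, 360))
    x <- sample.int(256 - ncol(rot$alpha), 1) - 1L
    y <- sample.int(256 - nrow(rot$alpha), 1) - 1L
    state <- paste_sprite(state, rot, x, y, blur_sigma = 1)
    placed <- placed + 1L
    now <- vapply(seq_len(placed), function(k) visible(state, k), 0)
    if (placed > 1L)
      expect_true(all(now[seq_len(placed - 1L)] <= history[[placed - 1L]]))
    history[[placed]] <- now
  }
})

test_that("scene generation is bit-exact under a fixed seed and differs across seeds", {
  pool <- small_pool(seed = 6)
  cfg <- small_config()
  s1 <- generate_scene(pool, cfg, rng_seed = 123)
  s2 <- generate_scene(pool, cfg, rng_seed = 123)
  s3 <- generate_scene(pool, cfg, rng_seed = 124)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$label_map, s2$label_map)
  expect_false(identical(s1$label_map, s3$label_map))
})

test_that("zero overlap threshold keeps even pasted supports pairwise disjoint", {
  pool <- small_pool(seed = 2)
  cfg <- small_config(canvas_size = 256L, out_size = 256L,
                      overlap_threshold = 0)
  sc <- generate_scene(pool, cfg, rng_seed = 3)
  ins <- scene_instances(sc)
  expect_gt(nrow(ins), 1)
  # no occlusion ever happened: visible area equals pasted area
  expect_equal(ins$area, ins$pasted_area_px)
})

test_that("border cropping recenters, drops margin-only instances and keeps cut ones", {
  pool <- small_pool(seed = 8)
  cfg_full <- small_config(canvas_size = 256L, out_size = 256L)
  sc_full <- generate_scene(pool, cfg_full, rng_seed = 17)
  cfg_crop <- small_config(canvas_size = 256L, out_size = 192L)
  sc_crop <- generate_scene(pool, cfg_crop, rng_seed = 17)
  # same RNG stream => same pastes; crop offset is 32 px per side
  expect_equal(sc_crop$image, sc_full$image[33:224, 33:224, , drop = FALSE])
  expect_equal(sc_crop$label_map, sc_full$label_map[33:224, 33:224])
  full_ins <- scene_instances(sc_full)
  crop_ins <- scene_instances(sc_crop)
  for (i in seq_len(nrow(full_ins))) {
    id <- full_ins$instance_id[i]
    inside <- sum(sc_full$label_map[33:224, 33:224] == id)
    if (inside == 0) {
      expect_false(id %in% crop_ins$instance_id)
    } else {
      expect_equal(crop_ins$area[crop_ins$instance_id == id], inside)
    }
  }
  # out_size == canvas_size is the identity
  expect_equal(dim(sc_full$image), c(256L, 256L, 3L))
})

test_that("dataset generation writes deterministic pairs with valid annotations", {
  pool <- small_pool(seed = 3)
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(pool, cfg, 3L, rng_seed = 99, d1)
  m2 <- generate_dataset(pool, cfg, 3L, rng_seed = 99, d2)
  for (f in m1$images$file_name)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  expect_identical(jsonlite::read_json(file.path(d1, "annotations.json")),
                   jsonlite::read_json(file.path(d2, "annotations.json")))
  # reload and check invariants per scene
  coco <- read_coco(file.path(d1, "annotations.json"))
  expect_equal(nrow(coco$images), 3L)
  for (id in coco$images$id) {
    rows <- annotation_masks(coco, id)
    lab <- tiff::readTIFF(file.path(d1, sprintf("lab_%05d.tif", id)))
    lab <- round(lab * 65535)
    union <- matrix(FALSE, 192, 192)
    for (j in seq_len(nrow(rows))) {
      expect_true(all(!(rows$mask[[j]] & union)))  # disjoint
      union <- union | rows$mask[[j]]
      expect_equal(sum(rows$mask[[j]]), rows$area[j])
    }
    expect_equal(union, lab > 0)  # label map agrees with mask union
  }
})
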