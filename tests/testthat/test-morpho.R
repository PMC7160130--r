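test_that("contour extraction is closed, sub-pixel, and picks the outer curve", {
  d <- disc_mask(50)
  cc <- extract_contour(d)
  expect_gt(length(cc$x), 8)
  # closed: endpoints adjacent after de-duplication
  expect_lt(sqrt((cc$x[1] - cc$x[length(cc$x)])^2 +
                 (cc$y[1] - cc$y[length(cc$y)])^2), 1.5)
  # counter-clockwise normalization: positive shoelace area near pi r^2
  ar <- seedpheno:::polygon_area_signed(cc$x, cc$y)
  expect_gt(ar, 0)
  expect_equal(ar, pi * 50^2, tolerance = 0.02)
  # border-touching mask still closes (padding)
  m <- matrix(TRUE, 12, 12)
  cb <- extract_contour(m)
  expect_equal(abs(seedpheno:::polygon_area_signed(cb$x, cb$y)), 144,
               tolerance = 0.02)
  # interior hole: outer contour wins, chosen by enclosed area
  holed <- disc_mask(30)
  ctr <- which(holed, arr.ind = TRUE)
  holed[40:41, 40:41] <- FALSE
  ch <- extract_contour(holed)
  expect_equal(abs(seedpheno:::polygon_area_signed(ch$x, ch$y)),
               pi * 30^2, tolerance = 0.03)
  expect_error(extract_contour(matrix(FALSE, 5, 5)), class = "empty_mask")
})

test_that("disc perimeter matches the marching-squares reference measurement", {
  # A binary disc's 0.5 iso-contour is a half-pixel staircase polygon; its
  # arc length is 1.0585x the smooth circumference.  Reference value from
  # an independent marching-squares implementation on the same raster.
  cc <- extract_contour(disc_mask(50))
  perim <- seedpheno:::polygon_perimeter(cc$x, cc$y)
  expect_equal(perim, 332.5341, tolerance = 1e-5)
})

test_that("descriptors recover analytic disc and ellipse geometry", {
  d <- compute_descriptors(disc_mask(100))
  expect_equal(d$area, pi * 100^2, tolerance = 0.01)
  expect_lt(d$eccentricity, 0.05)
  expect_gt(d$solidity, 0.98)
  expect_equal(d$lwr, 1, tolerance = 0.01)
  # circularity is depressed by the staircase perimeter (factor 1.0585^2)
  expect_equal(d$circularity, 1 / 1.0585^2, tolerance = 0.01)
  expect_lte(d$circularity, 1.02)

  e <- compute_descriptors(ellipse_mask(60, 30))
  expect_equal(e$length, 120, tolerance = 0.02)
  expect_equal(e$width, 60, tolerance = 0.02)
  expect_equal(e$lwr, 2, tolerance = 0.02)
  expect_equal(e$eccentricity, sqrt(1 - 0.25), tolerance = 0.02)

  sq <- compute_descriptors(square_mask(40))
  expect_equal(sq$solidity, 1.0)

  expect_error(compute_descriptors(matrix(FALSE, 4, 4)), class = "empty_mask")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[10:15, 10:15] <- TRUE
  expect_error(compute_descriptors(two), class = "multi_component")
})

test_that("descriptors scale correctly under mask magnification", {
  base <- ellipse_mask(50, 25)
  big <- ellipse_mask(100, 50)
  d1 <- compute_descriptors(base)
  d2 <- compute_descriptors(big)
  expect_equal(d2$area / d1$area, 4, tolerance = 0.02)
  expect_equal(d2$length / d1$length, 2, tolerance = 0.02)
  expect_equal(d2$perimeter / d1$perimeter, 2, tolerance = 0.02)
  for (f in c("lwr", "eccentricity", "solidity", "circularity"))
    expect_equal(d2[[f]], d1[[f]], tolerance = 0.02)
  # dpi conversion: 600 dpi scan -> mm
  dmm <- compute_descriptors(base, dpi = 600)
  expect_equal(dmm$length, d1$length * 25.4 / 600)
  expect_equal(dmm$area, d1$area * (25.4 / 600)^2)
})

test_that("raw EFD coefficients match direct numerical Fourier integration", {
  shapes <- list(circle_contour(50, 64), ellipse_contour(60, 30, 64))
  # an irregular 12-gon
  set.seed(3)
  th <- sort(runif(12, 0, 2 * pi))
  shapes$poly <- structure(list(x = 40 * (1 + 0.3 * runif(12)) * cos(th),
                                y = 40 * (1 + 0.3 * runif(12)) * sin(th)),
                           class = "seed_contour")
  for (sh in shapes) {
    got <- efd_coefficients(sh, harmonics = 8, normalize = FALSE)$coeffs
    want <- efd_oracle(sh, harmonics = 8)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("normalization pins (a1, b1, c1) to (1, 0, 0) and d1 to the harmonic axis ratio", {
  e <- efd_coefficients(circle_contour(50), 20)
  expect_equal(unname(e$coeffs[1, ]), c(1, 0, 0, 1), tolerance = 1e-6)
  expect_lt(max(abs(e$coeffs[-1, ])), 0.01)
  # 2:1 ellipse: first-harmonic minor/major ratio from the integration oracle
  raw <- efd_oracle(ellipse_contour(60, 30, 720), 1)
  want_d1 <- raw[1, "d"] / raw[1, "a"]
  e2 <- efd_coefficients(ellipse_contour(60, 30, 720), 20)
  expect_equal(unname(e2$coeffs[1, "d"]), unname(want_d1), tolerance = 1e-4)
})

test_that("normalized EFD are invariant to rotation, scale and starting point", {
  base <- ellipse_contour(60, 25, 360)
  # add mild asymmetry so the test is not on a degenerate symmetric shape
  base$x <- base$x + 6 * cos(2 * atan2(base$y, base$x))
  e0 <- efd_coefficients(base, 20)$coeffs
  ang <- 40 * pi / 180
  rot <- structure(list(
    x = 3 * (cos(ang) * base$x - sin(ang) * base$y) + 17,
    y = 3 * (sin(ang) * base$x + cos(ang) * base$y) - 4), class = "seed_contour")
  expect_equal(efd_coefficients(rot, 20)$coeffs, e0, tolerance = 1e-4)
  shift <- structure(list(x = c(base$x[101:360], base$x[1:100]),
                          y = c(base$y[101:360], base$y[1:100])),
                     class = "seed_contour")
  expect_equal(efd_coefficients(shift, 20)$coeffs, e0, tolerance = 1e-4)
})

test_that("the feature vector drops the three constants and keeps 77 values", {
  e <- efd_coefficients(ellipse_contour(50, 25), 20)
  f <- efd_features(e)
  expect_length(f, 77L)
  expect_equal(names(f)[1:3], c("d1", "a2", "b2"))
  raw <- efd_coefficients(ellipse_contour(50, 25), 20, normalize = FALSE)
  expect_error(efd_features(raw), class = "config_error")
  # circle: d1 ~ 1, everything else tiny
  fc <- efd_features(efd_coefficients(circle_contour(40), 20))
  expect_equal(unname(fc["d1"]), 1, tolerance = 1e-3)
  expect_lt(max(abs(fc[-1])), 0.01)
  # rotated congruent contour gives the same features
  base <- ellipse_contour(50, 25, 360)
  rot <- structure(list(x = cos(1.1) * base$x - sin(1.1) * base$y,
                        y = sin(1.1) * base$x + cos(1.1) * base$y),
                   class = "seed_contour")
  expect_equal(efd_features(efd_coefficients(rot, 20)),
               efd_features(efd_coefficients(base, 20)), tolerance = 1e-4)
})

test_that("reconstruction from 20 harmonics stays close to the source contour", {
  mask <- ellipse_mask(55, 25)
  cc <- extract_contour(mask)
  e <- efd_coefficients(cc, 20, normalize = FALSE)
  rec <- efd_reconstruct(e, n_points = 400)
  # mean distance from source vertices to the reconstructed polygon
  md <- mean(vapply(seq_along(cc$x), function(i)
    min(sqrt((rec$x - cc$x[i])^2 + (rec$y - cc$y[i])^2)), 0))
  expect_lt(md, 0.015 * 110)  # < 1.5% of the major axis
  # circle: radius coefficient of variation < 1%
  recc <- efd_reconstruct(efd_coefficients(circle_contour(50), 20,
                                           normalize = FALSE), 300)
  r <- sqrt(recc$x^2 + recc$y^2)
  expect_lt(stats::sd(r) / mean(r), 0.01)
  # truncation: reconstruction error non-increasing in harmonics
  errs <- vapply(c(2, 5, 10, 20), function(h) {
    rec_h <- efd_reconstruct(efd_coefficients(cc, h, normalize = FALSE),
                             n_points = 3 * 20)
    mean(vapply(seq_along(cc$x), function(i)
      min(sqrt((rec_h$x - cc$x[i])^2 + (rec_h$y - cc$y[i])^2)), 0))
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
  expect_error(efd_reconstruct(e, n_points = 10), class = "config_error")
})

test_that("mean contours average coefficient arrays", {
  base <- efd_coefficients(ellipse_contour(50, 25), 20)
  single <- mean_contour(list(base), n_points = 120)
  direct <- efd_reconstruct(base, 120)
  expect_equal(single$x, direct$x)
  expect_equal(single$y, direct$y)
  same <- mean_contour(list(base, base, base), n_points = 120)
  expect_equal(same$x, direct$x)
  # mirror-symmetric perturbations: mean lands nearer the base than members
  p1 <- base; p2 <- base
  p1$coeffs[3, "d"] <- base$coeffs[3, "d"] + 0.05
  p2$coeffs[3, "d"] <- base$coeffs[3, "d"] - 0.05
  mc <- mean_contour(list(p1, p2), n_points = 120)
  dist_to <- function(a, b) mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2))
  expect_lt(dist_to(mc, direct), dist_to(efd_reconstruct(p1, 120), direct))
  short <- efd_coefficients(ellipse_contour(50, 25), 10)
  expect_error(mean_contour(list(base, short)), class = "config_error")
})

test_that("PCA recovers known covariance structure and supports inversion", {
  # rank-1 data
  line <- cbind(1:50, 2 * (1:50))
  p1 <- pca_fit(line)
  expect_equal(p1$explained_ratio, c(1, 0), tolerance = 1e-12)
  # 2-D Gaussian with covariance diag(4, 1)
  set.seed(9)
  g <- cbind(rnorm(4000, sd = 2), rnorm(4000, sd = 1))
  p2 <- pca_fit(g)
  expect_equal(p2$explained_ratio, c(0.8, 0.2), tolerance = 0.03)
  expect_equal(sum(p2$explained_ratio), 1)
  # full reconstruction of the centered data
  sc <- as.matrix(p2$scores)
  rec <- sc %*% t(p2$loadings)
  expect_equal(rec + matrix(p2$center, 4000, 2, byrow = TRUE), g,
               tolerance = 1e-8, ignore_attr = TRUE)
  # zero-variance column under standardization errors by name
  bad <- data.frame(a = rnorm(10), b = rep(1, 10))
  expect_error(pca_fit(bad, standardize = TRUE), "b")
  # score -> feature -> score round trip
  x1 <- pca_invert(p2, c(1.3, -0.4))
  s1 <- (x1 - p2$center) %*% p2$loadings
  expect_equal(as.vector(s1), c(1.3, -0.4), tolerance = 1e-8)
})

test_that("PCA on descriptor tables carries metadata and fuels tidiers", {
  pool <- small_pool(seed = 25)
  sc <- generate_scene(pool, small_config(), rng_seed = 31)
  ins <- scene_instances(sc)
  rep <- apply_filters(ins, c(192, 192), filter_config())
  keep <- ins[rep$kept, ]
  tab <- morphometry_table(keep)
  expect_true(all(c("instance_id", "cultivar", "area", "circularity") %in%
                    names(tab)))
  fit <- pca_fit(dplyr::select(tab, -instance_id), standardize = TRUE)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true("cultivar" %in% names(tidy(fit)))
  expect_equal(glance(fit)$pc12_ratio,
               sum(fit$explained_ratio[1:2]))
  expect_s3_class(autoplot(fit, color = "cultivar"), "ggplot")
})

test_that("latent-axis reconstructions vary monotonically along an elongation axis", {
  # fixture set whose only variation is aspect ratio
  set.seed(41)
  masks <- lapply(seq(1.2, 3.2, length.out = 24), function(asp)
    ellipse_mask(round(20 * asp), 20))
  ins <- tibble::tibble(instance_id = seq_along(masks), mask = masks)
  feats <- efd_feature_table(ins, harmonics = 20)
  mat <- as.matrix(dplyr::select(feats, -instance_id, -cultivar))
  fit <- pca_fit(mat, standardize = FALSE)
  sdev1 <- fit$sdev[1]
  lat <- latent_axis_contours(fit, axis = 1,
                              positions = c(-2, -1, 0, 1, 2) * sdev1)
  aspect_of <- function(cc) {
    dx <- diff(range(cc$x)); dy <- diff(range(cc$y))
    max(dx, dy) / min(dx, dy)
  }
  aspects <- vapply(lat$contour, aspect_of, 0)
  expect_true(all(diff(aspects) > 0) || all(diff(aspects) < 0))
  # position 0 reconstructs the mean shape
  mean_feat <- colMeans(mat)
  co <- matrix(c(1, 0, 0, mean_feat), 20, 4, byrow = TRUE,
               dimnames = list(NULL, c("a", "b", "c", "d")))
  efd <- structure(list(coeffs = co, harmonics = 20L, normalized = TRUE,
                        A0 = 0, C0 = 0), class = "efd_coeffs")
  want <- efd_reconstruct(efd, 300)
  expect_equal(lat$contour[[3]]$x, want$x, tolerance = 1e-8)
  expect_error(latent_axis_contours(fit, axis = 999), class = "config_error")
  expect_s3_class(plot_contours(lat), "ggplot")
})
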