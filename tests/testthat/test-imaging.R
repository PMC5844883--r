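test_that("segmentation recovers well-separated synthetic nuclei exactly", {
  for (s in 1:3) {
    f <- gen_nuclei_image(image_scenario(n_nuclei = 12, seed = s))
    seg <- segment_nuclei(f$dapi)
    expect_equal(seg$n, 12)
    # centroids within 2 px of ground truth
    cent <- t(sapply(seq_len(seg$n), function(k) {
      w <- which(seg$labels == k, arr.ind = TRUE)
      colMeans(w)
    }))
    dd <- sapply(seq_len(12), function(k) {
      min(sqrt((cent[, 1] - f$nuclei$x[k])^2 + (cent[, 2] - f$nuclei$y[k])^2))
    })
    expect_lt(max(dd), 2)
  }
  blank <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(blank$n, 0)
})

test_that("watershed markers split touching nuclei with distinct maxima", {
  img <- matrix(0, 80, 80)
  xs <- seq_len(80)
  # two disks of radius 10 with centers 18 px apart: overlapping neck
  for (c0 in list(c(30, 40), c(48, 40))) {
    disk <- outer((xs - c0[1])^2, (xs - c0[2])^2, "+") <= 100
    img[disk] <- 1
  }
  expect_equal(max(EBImage::bwlabel(EBImage::Image(img > 0))), 1)  # touching
  seg <- segment_nuclei(img, sigma = 1, min_dist = 6, min_area = 30)
  expect_equal(seg$n, 2)
})

test_that("per-nucleus measurement is a masked mean", {
  lab <- matrix(0L, 10, 10)
  lab[2:3, 2] <- 1L
  ch <- matrix(0, 10, 10)
  ch[2, 2] <- 10; ch[3, 2] <- 20
  rec <- measure_nuclei(lab, ch)
  expect_equal(rec$mean_intensity, 15)
  expect_equal(rec$area, 2L)
  u <- matrix(7, 10, 10)
  expect_true(all(measure_nuclei(lab, u)$mean_intensity == 7))
  expect_equal(nrow(measure_nuclei(matrix(0L, 10, 10), u)), 0)
  expect_error(measure_nuclei(lab, matrix(0, 5, 5)), "shapes differ")
})

test_that("positivity threshold is control mean plus one sample sd", {
  th <- derive_threshold(c(8, 10, 12))
  expect_equal(th$control_mean, 10)
  expect_equal(th$control_sd, 2)
  expect_equal(th$threshold, 12)
  expect_equal(derive_threshold(c(10, 10, 10))$threshold, 10)
  expect_error(derive_threshold(10), ">= 2")
})

test_that("positivity uses a strict inequality and percent is invariant to affine rescaling", {
  rec <- tibble::tibble(mean_intensity = c(12, 12.0001, 5, 30))
  cls <- classify_positive(rec, derive_threshold(c(8, 10, 12)))
  expect_equal(cls$records$positive, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(cls$percent_positive, 50)
  expect_error(classify_positive(rec[0, ], derive_threshold(c(8, 10, 12))),
               "no cells")

  withr::with_seed(31, {
    ctrl <- rnorm(500, 100, 15)
    trt <- rnorm(500, 140, 15)
  })
  p1 <- classify_positive(tibble::tibble(mean_intensity = trt),
                          derive_threshold(ctrl))$percent_positive
  p2 <- classify_positive(tibble::tibble(mean_intensity = 3 * trt + 7),
                          derive_threshold(3 * ctrl + 7))$percent_positive
  expect_equal(p1, p2)
})

test_that("a Gaussian null population scores about 1 - pnorm(1) positive", {
  withr::with_seed(32, v <- rnorm(10000, 50, 8))
  p <- classify_positive(tibble::tibble(mean_intensity = v),
                         derive_threshold(v))$percent_positive
  expect_lt(abs(p - 100 * (1 - pnorm(1))), 1.5)
})

test_that("foci detection finds isolated spots and is monotone in prominence", {
  lab <- matrix(0L, 60, 60); lab[10:50, 10:50] <- 1L
  u <- matrix(5, 60, 60)
  expect_equal(detect_foci(u, lab)$per_nucleus$foci_count, 0L)
  one <- cddpflux:::add_gaussian(u, 30, 30, 50, 1.5)
  expect_equal(detect_foci(one, lab)$per_nucleus$foci_count, 1L)
  f <- gen_nuclei_image(image_scenario(n_nuclei = 15, seed = 9,
                                       foci = list(type = "poisson",
                                                   lambda = 3)))
  fc0 <- detect_foci(f$gh2ax, f$labels, prominence = 1e-6)
  fc1 <- detect_foci(f$gh2ax, f$labels, prominence = 20)
  expect_true(all(fc1$per_nucleus$foci_count <= fc0$per_nucleus$foci_count))
  expect_true(all(fc0$per_nucleus$foci_count >= 0))
})

test_that("max projection is the per-pixel maximum", {
  a <- matrix(0, 8, 8); a[2, 2] <- 5
  b <- matrix(0, 8, 8); b[6, 6] <- 3
  st <- array(c(a, b), dim = c(8, 8, 2))
  mp <- max_project(st)
  expect_equal(mp[2, 2], 5)
  expect_equal(mp[6, 6], 3)
  expect_equal(max_project(array(a, dim = c(8, 8, 1))), a)
  expect_equal(max_project(a), a)
  expect_equal(max_project(array(0, dim = c(4, 4, 3))), matrix(0, 4, 4))
  expect_error(max_project(1:5), "matrix")
})
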