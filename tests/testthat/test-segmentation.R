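# Three-class adaptive labelling, region validation and compartment
# extraction, cross-checked against per-pixel and flood-fill oracles.

test_that("local_stats matches the per-pixel loop on integer images", {
  # constant image: mean = c, sd = 0
  img <- nucleus_image(matrix(300, 20, 20), matrix(TRUE, 20, 20))
  ls <- local_stats(img)
  expect_true(all(ls$mean[img$mask] == 300))
  expect_true(all(ls$sd[img$mask] == 0))

  # single in-mask pixel: count 1, sd 0
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  img1 <- structure(list(pixels = matrix(7, 9, 9), mask = m), class = "nucleus_image")
  ls1 <- local_stats(img1)
  expect_equal(ls1$count[5, 5], 1)
  expect_equal(ls1$sd[5, 5], 0)

  # random 16x16: bit-exact against the double loop
  set.seed(5)
  for (i in 1:5) {
    rm_ <- random_masked_image(16, 16)
    img2 <- structure(list(pixels = rm_$pixels, mask = rm_$mask),
                      class = "nucleus_image")
    p <- seg_params(window_radius = sample(2:4, 1))
    got <- local_stats(img2, p)
    want <- brute_local_stats(rm_$pixels, rm_$mask, p$window_radius)
    expect_identical(got$mean[rm_$mask], want$mean[rm_$mask])
    expect_identical(got$sd[rm_$mask], want$sd[rm_$mask])
    expect_identical(got$count, want$count)
    expect_identical(got$window_area * 1.0, want$window_area)
  }
})

test_that("label_pixels implements the two-sided adaptive rule", {
  # flat image: everything grey
  img <- nucleus_image(matrix(400, 24, 24), matrix(TRUE, 24, 24))
  lbl <- label_pixels(img)
  expect_true(all(lbl[img$mask] == 2L))
  expect_true(all(lbl[!img$mask] == 0L))

  # planted high-OD square -> dark; mirrored low-OD square -> bright
  nuc <- planted_nucleus(40, 40, dark_centres = list(c(12, 12)),
                         bright_centres = list(c(28, 28)))
  lbl2 <- label_pixels(nuc)
  expect_true(all(lbl2[12 + (-2:2), 12 + (-2:2)] == 1L))
  expect_true(all(lbl2[28 + (-2:2), 28 + (-2:2)] == 3L))
  # far field stays grey
  expect_true(all(lbl2[1:5, 1:5] == 2L))

  # label partition: dark + grey + bright = mask area
  expect_equal(sum(lbl2 %in% c(1L, 2L, 3L)), sum(nuc$mask))
})

test_that("label_pixels matches the brute-force oracle on random images", {
  set.seed(17)
  for (i in 1:10) {
    rm_ <- random_masked_image(32, 32)
    img <- structure(list(pixels = rm_$pixels, mask = rm_$mask),
                     class = "nucleus_image")
    p <- seg_params()
    expect_identical(label_pixels(img, p), brute_label(rm_$pixels, rm_$mask, p))
  }
})

test_that("labelling is invariant to affine OD shifts", {
  set.seed(23)
  rm_ <- random_masked_image(32, 32)
  px <- matrix(sample(100:900, 32 * 32, TRUE), 32, 32)
  img <- structure(list(pixels = px, mask = rm_$mask), class = "nucleus_image")
  shifted <- structure(list(pixels = px + 37, mask = rm_$mask),
                       class = "nucleus_image")
  expect_identical(label_pixels(img), label_pixels(shifted))
})

test_that("contrast scaling about the local mean never demotes labels when sigma_min = 0", {
  # on a 5x5 image with window radius 4 every truncated window is the whole
  # image, so the local mean/sd fields are constant and scaling deviations
  # about the mean multiplies both the margin and the threshold by exactly c
  set.seed(31)
  p0 <- seg_params(window_radius = 4, sigma_min = 0)
  for (i in 1:10) {
    px <- matrix(sample(0:1023, 25, TRUE), 5, 5)
    img <- structure(list(pixels = px, mask = matrix(TRUE, 5, 5)),
                     class = "nucleus_image")
    l1 <- label_pixels(img, p0)
    for (cmul in c(1, 2, 5)) {
      px2 <- mean(px) + cmul * (px - mean(px))
      img2 <- structure(list(pixels = px2, mask = matrix(TRUE, 5, 5)),
                        class = "nucleus_image")
      l2 <- label_pixels(img2, p0)
      expect_true(all(l2[l1 == 1L] == 1L))
      expect_true(all(l2[l1 == 3L] == 3L))
    }
  }
})

test_that("validate_regions drops speckles and edgeless regions only", {
  nuc <- planted_nucleus(40, 40, dark_centres = list(c(20, 20)), delta = 80)
  # add a single-pixel speckle strong enough to be labelled dark
  nuc$pixels[5, 5] <- 480
  lbl <- label_pixels(nuc)
  expect_equal(lbl[5, 5], 1L)
  val <- validate_regions(lbl, nuc)
  expect_equal(val[5, 5], 2L)                       # speckle removed
  expect_true(all(val[20 + (-2:2), 20 + (-2:2)] == 1L))  # sharp square survives

  # vacuous thresholds: validation is the identity
  p0 <- seg_params(g_min = 0, min_region_size = 1)
  expect_identical(validate_regions(lbl, nuc, p0), lbl)

  # validation never creates dark/bright pixels
  set.seed(41)
  rm_ <- random_masked_image(32, 32)
  img <- structure(list(pixels = rm_$pixels, mask = rm_$mask),
                   class = "nucleus_image")
  l1 <- label_pixels(img)
  v1 <- validate_regions(l1, img)
  expect_true(all(v1[l1 == 2L] == 2L))
  expect_true(all(v1 %in% c(l1, 2L)))
  changed <- v1 != l1
  expect_true(all(v1[changed] == 2L))
})

test_that("extract_compartments agrees with the BFS flood-fill oracle", {
  img <- structure(list(pixels = matrix(0, 32, 32), mask = matrix(TRUE, 32, 32)),
                   class = "nucleus_image")
  # all grey -> empty
  expect_length(extract_compartments(matrix(2L, 32, 32), img), 0)

  # two disjoint 3-pixel dark blobs
  lbl <- matrix(2L, 32, 32)
  lbl[3, 3:5] <- 1L
  lbl[10, 10:12] <- 1L
  comps <- extract_compartments(lbl, img)
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, 0, "size_px"), c(3, 3))

  # diagonal touch merges under 8-connectivity
  lbl2 <- matrix(2L, 32, 32)
  lbl2[5, 5] <- 1L; lbl2[6, 6] <- 1L
  comps2 <- extract_compartments(lbl2, img)
  expect_length(comps2, 1)
  expect_equal(comps2[[1]]$size_px, 2)

  # random label maps vs oracle (counts, sizes, memberships, ordering)
  set.seed(53)
  for (i in 1:20) {
    lblr <- matrix(sample(c(1L, 2L, 3L), 32 * 32, TRUE, c(.2, .6, .2)), 32, 32)
    comps <- extract_compartments(lblr, img)
    for (cls in c(1L, 3L)) {
      cname <- if (cls == 1L) "dark" else "bright"
      want <- bfs_label(lblr == cls, 8)
      got <- Filter(function(x) x$region_class == cname, comps)
      expect_equal(length(got), max(want))
      for (id in seq_len(max(want))) {
        expect_identical(sort(got[[id]]$pixels), which(want == id))
      }
    }
  }
})

test_that("segment_nucleus composes the stages deterministically", {
  # flat nucleus: all grey, no compartments
  img <- nucleus_image(matrix(500, 30, 30), matrix(TRUE, 30, 30))
  seg <- segment_nucleus(img)
  expect_true(all(seg$labels[img$mask] == 2L))
  expect_length(seg$compartments, 0)

  # 4 planted dark + 3 planted bright well-separated 3x3 blobs (small
  # relative to the 9x9 window, so no contrast halo forms around them)
  nuc <- planted_nucleus(60, 60,
    dark_centres = list(c(10, 10), c(10, 40), c(30, 10), c(50, 50)),
    bright_centres = list(c(30, 40), c(50, 10), c(10, 52)),
    half = 1, delta = 80)
  seg2 <- segment_nucleus(nuc)
  cls <- vapply(seg2$compartments, `[[`, "", "region_class")
  expect_equal(sum(cls == "dark"), 4)
  expect_equal(sum(cls == "bright"), 3)

  # fused path is identical to composing the stage functions
  g <- generate_nucleus(nucleus_preset("separated_poor"), seed = 9)
  s1 <- segment_nucleus(g$image)
  l2 <- validate_regions(label_pixels(g$image), g$image)
  expect_identical(s1$labels, l2)
  expect_identical(s1$compartments, extract_compartments(l2, g$image))

  # translation equivariance inside a uniform interior
  big <- matrix(400, 50, 50)
  big[20 + (-2:2), 20 + (-2:2)] <- 470
  imgA <- nucleus_image(big, matrix(TRUE, 50, 50))
  imgB <- nucleus_image(rbind(big[50, , drop = FALSE], big[-50, ]),
                        matrix(TRUE, 50, 50))
  segA <- segment_nucleus(imgA)
  segB <- segment_nucleus(imgB)
  expect_equal(segA$compartments[[1]]$size_px, segB$compartments[[1]]$size_px)
  expect_equal(segA$compartments[[1]]$centroid + c(1, 0),
               segB$compartments[[1]]$centroid)
})

test_that("label maps round-trip through PNG", {
  set.seed(3)
  lbl <- matrix(sample(0:3, 20 * 20, TRUE), 20, 20)
  p <- tempfile(fileext = ".png")
  write_label_map(lbl, p)
  expect_identical(read_label_map(p), lbl)
})
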