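# Adaptive DESH features and the Gaussian common-covariance classifier.

mkdesh <- function(probs, cls = "dark") {
  structure(list(region_class = cls, edges = c(-Inf, seq_along(probs)[-1] - 1, Inf),
                 probs = probs), class = "desh")
}

test_that("fit_bin_weights scores bins by outcome contrast", {
  dp <- list(mkdesh(c(0.3, 0.7)), mkdesh(c(0.3, 0.7)))
  dg <- list(mkdesh(c(0.1, 0.9)), mkdesh(c(0.1, 0.9)))
  w <- fit_bin_weights(c(dp, dg), c("poor", "poor", "good", "good"))
  expect_equal(w$w[1], (0.3 - 0.1) / (0.3 + 0.1 + 1e-12))  # 0.5
  expect_equal(w$w[1], 0.5, tolerance = 1e-10)

  # identical class means: all weights zero
  w0 <- fit_bin_weights(c(dp, dp), c("poor", "poor", "good", "good"))
  expect_true(all(w0$w == 0))

  # disjoint supports: +1 on poor-only bins, -1 on good-only bins
  wd <- fit_bin_weights(list(mkdesh(c(1, 0)), mkdesh(c(0, 1))),
                        c("poor", "good"))
  expect_equal(wd$w, c(1, -1), tolerance = 1e-10)

  # a missing class is a training error
  expect_error(fit_bin_weights(dp, c("poor", "poor")),
               class = "chromdiv_training_error")

  # swapping outcome labels negates the weights
  set.seed(6)
  ds <- lapply(1:8, function(i) { p <- stats::runif(5); mkdesh(p / sum(p)) })
  oc <- rep(c("poor", "good"), 4)
  w1 <- fit_bin_weights(ds, oc)
  w2 <- fit_bin_weights(ds, ifelse(oc == "poor", "good", "poor"))
  expect_equal(w1$w, -w2$w)
})

test_that("desh_feature is the bounded weighted sum", {
  expect_equal(desh_feature(mkdesh(c(0, 1)), list(w = c(-1, 1))), 1)
  expect_equal(desh_feature(mkdesh(rep(0.25, 4)),
                            list(w = c(0.5, -0.5, 0.2, -0.2))), 0)
  expect_equal(desh_feature(mkdesh(c(0.5, 0.5)), list(w = c(0.5, -0.1))), 0.2)
  expect_error(desh_feature(mkdesh(c(0.5, 0.5)), list(w = c(1, 1, 1))),
               class = "chromdiv_value_error")
})

test_that("fit_gaussian_classifier recovers moments and stays invertible", {
  # identical classes: equal means, any point scores 0
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  cls <- fit_gaussian_classifier(rbind(x, x),
                                 rep(c("poor", "good"), each = 4))
  expect_equal(cls$mu_poor, cls$mu_good)
  r <- classify_features(c(5, -3), cls)
  expect_equal(r$score, 0)
  expect_equal(r$call, "DCC")   # boundary tie goes to DCC

  # moment recovery at n = 1e4
  set.seed(1)
  n <- 10000
  xp <- cbind(stats::rnorm(n, 1), stats::rnorm(n, 0))
  xg <- cbind(stats::rnorm(n, -1), stats::rnorm(n, 0))
  fit <- fit_gaussian_classifier(rbind(xp, xg),
                                 rep(c("poor", "good"), each = n))
  expect_equal(fit$mu_poor, c(1, 0), tolerance = 0.05)
  expect_equal(fit$mu_good, c(-1, 0), tolerance = 0.05)
  expect_equal(fit$sigma_pooled, diag(2), tolerance = 0.05)

  # degenerate input: a single repeated point per class stays solvable
  deg <- fit_gaussian_classifier(matrix(c(1, 1, 0, 0, 1, 1, 0, 0), 4, 2),
                                 c("poor", "poor", "good", "good"))
  expect_no_error(solve(deg$sigma_pooled))
  expect_error(fit_gaussian_classifier(x[1:3, ], c("poor", "good", "good")),
               class = "chromdiv_training_error")
})

test_that("classify_features draws the equal-prior linear boundary", {
  marker <- list(mu_poor = c(1, 1), mu_good = c(-1, -1),
                 sigma_pooled = diag(2))
  expect_equal(classify_features(c(1, 1), marker)$call, "DCC")
  expect_equal(classify_features(c(-1, -1), marker)$call, "SCC")
  mid <- classify_features(c(0, 0), marker)
  expect_equal(mid$score, 0)
  expect_equal(mid$call, "DCC")
  # empirical error approaches the Bayes error of the generating model
  set.seed(2)
  n <- 10000
  xp <- cbind(stats::rnorm(n, 1), stats::rnorm(n, 1))
  xg <- cbind(stats::rnorm(n, -1), stats::rnorm(n, -1))
  calls <- classify_features(rbind(xp, xg), marker)$call
  err <- mean(calls != rep(c("DCC", "SCC"), each = n))
  bayes <- stats::pnorm(-sqrt(sum((c(1, 1) - c(-1, -1))^2)) / 2)
  expect_lt(abs(err - bayes), 0.02)
})

test_that("train_marker / apply_marker are deterministic, consistent and label-symmetric", {
  set.seed(77)
  gp <- nucleus_preset("separated_poor"); gg <- nucleus_preset("separated_good")
  mk_imgs <- function(p, n) lapply(seq_len(n), function(i) generate_nucleus(p)$image)
  co <- make_cohort(
    c(lapply(1:4, function(i) mk_imgs(gp, 4)),
      lapply(1:4, function(i) mk_imgs(gg, 4))),
    rep(c("poor", "good"), each = 4))

  m1 <- train_marker(co, Q = 10)
  m2 <- train_marker(co, Q = 10)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_marker(m1, f1); write_marker(m2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical retrain

  # scoring a training patient reproduces its training-time features
  r <- apply_marker(co$patients[[1]]$images, m1)
  expect_equal(r$feature_dark, m1$train_features$feature_dark[1])
  expect_equal(r$feature_bright, m1$train_features$feature_bright[1])
  expect_equal(r$call, m1$train_features$call[1])

  # duplicating every nucleus leaves DESH and call unchanged
  rdup <- apply_marker(c(co$patients[[1]]$images, co$patients[[1]]$images), m1)
  expect_equal(rdup$desh_dark$probs, r$desh_dark$probs)
  expect_equal(rdup$call, r$call)

  # features are bounded
  expect_true(all(abs(m1$train_features$feature_dark) <= 1))
  expect_true(all(abs(m1$train_features$feature_bright) <= 1))

  # swapping outcome labels negates weights and flips every non-boundary call
  co_sw <- co
  for (i in seq_along(co_sw$patients))
    co_sw$patients[[i]]$outcome <-
      ifelse(co_sw$patients[[i]]$outcome == "poor", "good", "poor")
  msw <- train_marker(co_sw, Q = 10)
  expect_equal(msw$w_dark$w, -m1$w_dark$w)
  expect_equal(msw$w_bright$w, -m1$w_bright$w)
  sc1 <- vapply(co$patients, function(p) apply_marker(p$images, m1)$score, 0)
  sc2 <- vapply(co$patients, function(p) apply_marker(p$images, msw)$score, 0)
  nb <- abs(sc1) > 1e-9
  expect_true(all(sign(sc1[nb]) == -sign(sc2[nb])))

  # high-diversity patient -> DCC; low-diversity -> SCC (planted, seed 7)
  set.seed(7)
  expect_equal(apply_marker(mk_imgs(gp, 6), m1)$call, "DCC")
  expect_equal(apply_marker(mk_imgs(gg, 6), m1)$call, "SCC")

  # marker JSON round trip preserves the decision function
  mback <- read_marker(f1)
  rb <- apply_marker(co$patients[[2]]$images, mback)
  r2 <- apply_marker(co$patients[[2]]$images, m1)
  expect_equal(rb$score, r2$score, tolerance = 1e-12)
  expect_error(read_marker({
    p <- tempfile(fileext = ".json")
    jsonlite::write_json(list(version = "9.9"), p, auto_unbox = TRUE)
    p
  }), class = "chromdiv_format_error")
})

test_that("training errors on unusable cohorts", {
  img <- nucleus_image(matrix(400, 24, 24), matrix(TRUE, 24, 24))
  co <- make_cohort(list(list(img), list(img), list(img)),
                    c("poor", "poor", "poor"))
  expect_error(train_marker(co), class = "chromdiv_training_error")
  co2 <- make_cohort(rep(list(list(img)), 5),
                     c("poor", "poor", "good", "good", "unknown"))
  co2$patients[[1]]$images <- list()
  expect_error(train_marker(co2), class = "chromdiv_value_error")
})
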