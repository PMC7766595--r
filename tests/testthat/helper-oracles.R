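# Independent brute-force oracles used to cross-check the vectorised
# implementation, plus small fixture builders. The oracles deliberately use
# the most naive algorithm available (queue-based flood fill, per-pixel
# double loops, direct O-E tabulation).

# Queue-based BFS connected-component labelling.
bfs_label <- function(bin, connectivity = 8) {
  nr <- nrow(bin); nc <- ncol(bin)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  lab <- matrix(0L, nr, nc)
  k <- 0L
  # scan row-major so labels come out in first-pixel row-major order
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!bin[r, cc] || lab[r, cc] > 0L) next
    k <- k + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(offs))) {
        rr <- p[1] + offs[i, 1]; c2 <- p[2] + offs[i, 2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
            bin[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- k
          queue[[length(queue) + 1]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# Flood-fill hole removal oracle: flood the background from the border
# (4-connectivity); anything not reached is a hole.
bfs_fill_holes <- function(mask) {
  bg <- !mask
  lab <- bfs_label(bg, connectivity = 4)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- border_ids[border_ids > 0]
  mask | (bg & !(lab %in% border_ids))
}

# Per-pixel double-loop local statistics (population sd), same algebraic
# form as the implementation so integer input gives bit-identical doubles.
brute_local_stats <- function(pixels, mask, r) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  mu <- sdv <- cnt <- war <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - r):min(nr, i + r)
    cj <- max(1, j - r):min(nc, j + r)
    w <- pixels[ri, cj, drop = FALSE]
    m <- mask[ri, cj, drop = FALSE]
    war[i, j] <- length(w)
    n <- sum(m)
    cnt[i, j] <- n
    if (n > 0) {
      v <- w[m]
      mu[i, j] <- sum(v) / n
      sdv[i, j] <- sqrt(max(sum(v * v) / n - (sum(v) / n)^2, 0))
    }
  }
  list(mean = mu, sd = sdv, count = cnt, window_area = war)
}

# Per-pixel three-class labelling oracle on top of brute_local_stats.
brute_label <- function(pixels, mask, params) {
  ls <- brute_local_stats(pixels, mask, params$window_radius)
  nr <- nrow(pixels); nc <- ncol(pixels)
  lbl <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    if (ls$count[i, j] / ls$window_area[i, j] < params$min_mask_fraction) {
      lbl[i, j] <- 2L
      next
    }
    thr <- params$k * max(ls$sd[i, j], params$sigma_min)
    lbl[i, j] <- if (pixels[i, j] > ls$mean[i, j] + thr) 1L
                 else if (pixels[i, j] < ls$mean[i, j] - thr) 3L else 2L
  }
  lbl
}

# Two-group log-rank oracle: direct observed-minus-expected tabulation with
# hypergeometric variance at each distinct event time.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(max(g) == 2)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Random integer-valued nucleus image over a random blobby mask.
random_masked_image <- function(nr = 64, nc = 64) {
  cy <- nr / 2 + stats::runif(1, -4, 4); cx <- nc / 2 + stats::runif(1, -4, 4)
  ry <- stats::runif(1, 0.3, 0.48) * nr; rx <- stats::runif(1, 0.3, 0.48) * nc
  mask <- ((row(matrix(0, nr, nc)) - cy) / ry)^2 +
          ((col(matrix(0, nr, nc)) - cx) / rx)^2 <= 1
  pixels <- matrix(sample(0:1023, nr * nc, replace = TRUE), nr, nc)
  list(pixels = pixels, mask = mask)
}

# Minimal in-memory cohort from per-patient image lists and outcomes.
make_cohort <- function(image_lists, outcomes, times = NULL, events = NULL) {
  patients <- lapply(seq_along(image_lists), function(i) list(
    patient_id = sprintf("P%03d", i), outcome = outcomes[i],
    time_years = if (is.null(times)) 1 else times[i],
    event = if (is.null(events)) 0L else events[i],
    figo_substage = 0L, grade_class = 0L, path_risk = "LPR", age = 60,
    chromatin_value = NA_real_, images = image_lists[[i]]))
  structure(list(patients = patients, dir = NULL), class = "cohort")
}

# A flat nucleus with planted square compartments at given centres.
planted_nucleus <- function(nr = 40, nc = 40, base = 400,
                            dark_centres = list(), bright_centres = list(),
                            half = 2, delta = 60) {
  pixels <- matrix(base, nr, nc)
  mask <- matrix(TRUE, nr, nc)
  for (ct in dark_centres)
    pixels[ct[1] + (-half:half), ct[2] + (-half:half)] <- base + delta
  for (ct in bright_centres)
    pixels[ct[1] + (-half:half), ct[2] + (-half:half)] <- base - delta
  nucleus_image(pixels, mask)
}
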