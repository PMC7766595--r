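# Low-level raster utilities shared by the segmentation and synthesis code.
# All grids are plain R matrices indexed [row, col].

# Condition helpers: errors carry a class so callers (and the CLI) can map
# them to exit codes without string matching.
chromdiv_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "chromdiv_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
stop_format    <- function(msg) chromdiv_stop(msg, "chromdiv_format_error")
stop_value     <- function(msg) chromdiv_stop(msg, "chromdiv_value_error")
stop_training  <- function(msg) chromdiv_stop(msg, "chromdiv_training_error")
stop_numerical <- function(msg) chromdiv_stop(msg, "chromdiv_numerical_error")

# Shift a matrix by (dr, dc); vacated cells are filled with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(sr) < 1 || length(sc) < 1) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

.NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
.NB4 <- cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))

# Sliding-window sum with the window truncated at the image edge, via
# cumulative sums. Exact for integer-valued input (all partial sums are
# integers representable in doubles), which is what makes the segmentation
# statistics bit-identical to a direct per-pixel loop.
box_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(m, 2, cumsum)
  hi <- pmin(seq_len(nr) + r, nr)
  lo <- pmax(seq_len(nr) - r, 1)
  cs0 <- rbind(0, cs)                        # cs0[i + 1, ] = sum of rows 1..i
  rs <- cs0[hi + 1, , drop = FALSE] - cs0[lo, , drop = FALSE]
  cs2 <- t(apply(rs, 1, cumsum))
  chi <- pmin(seq_len(nc) + r, nc)
  clo <- pmax(seq_len(nc) - r, 1)
  cs20 <- cbind(0, cs2)
  cs20[, chi + 1, drop = FALSE] - cs20[, clo, drop = FALSE]
}

# Number of in-image pixels of the (2r+1)^2 window centred at each pixel.
window_area <- function(nr, nc, r) {
  wr <- pmin(seq_len(nr) + r, nr) - pmax(seq_len(nr) - r, 1) + 1
  wc <- pmin(seq_len(nc) + r, nc) - pmax(seq_len(nc) - r, 1) + 1
  outer(wr, wc)
}

# Connected-component labelling of a logical matrix. The 4-connected pass
# delegates to EBImage's C implementation; 8-connectivity is obtained by
# merging components that touch diagonally with a union-find over the
# (small) component adjacency list. Components are numbered 1..K in
# row-major order of their first (top-most, then left-most) pixel, which
# fixes a deterministic compartment ordering.
label_components <- function(bin, connectivity = 8) {
  nr <- nrow(bin); nc <- ncol(bin)
  if (!any(bin)) return(matrix(0L, nr, nc))
  L <- EBImage::bwlabel(bin * 1L)
  L <- matrix(as.integer(round(L)), nr, nc)
  if (connectivity == 8 && max(L) > 1L) {
    prs <- rbind(
      cbind(as.vector(L[-nr, -nc]), as.vector(L[-1, -1])),   # \ diagonals
      cbind(as.vector(L[-nr, -1]), as.vector(L[-1, -nc])))   # / diagonals
    prs <- prs[prs[, 1] > 0L & prs[, 2] > 0L & prs[, 1] != prs[, 2], ,
               drop = FALSE]
    if (nrow(prs)) {
      parent <- seq_len(max(L))
      find <- function(x) {
        while (parent[x] != x) {
          parent[x] <<- parent[parent[x]]
          x <- parent[x]
        }
        x
      }
      for (i in seq_len(nrow(prs))) {
        a <- find(prs[i, 1]); b <- find(prs[i, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      L[L > 0L] <- roots[L[L > 0L]]
    }
  }
  out <- matrix(0L, nr, nc)
  fg <- which(bin)
  roots <- L[fg]
  rowmaj <- (row(bin) - 1L) * nc + col(bin)  # row-major position
  first <- tapply(rowmaj[fg], roots, min)
  ord <- names(sort(first))
  out[fg] <- match(as.character(roots), ord)
  out
}

# Logical dilation by `r` steps of the 8-neighbourhood (Chebyshev radius r).
dilate_mask <- function(bin, r) {
  out <- bin
  for (step in seq_len(r)) {
    acc <- out
    for (i in seq_len(nrow(.NB8))) {
      acc <- acc | shift_mat(out, .NB8[i, 1], .NB8[i, 2], fill = FALSE)
    }
    out <- acc
  }
  out
}

# 3x3 Sobel gradient magnitude with replicate padding at the image border.
sobel_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  p <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  at <- function(dr, dc) p[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  gx <- (at(-1, 1) + 2 * at(0, 1) + at(1, 1)) -
        (at(-1, -1) + 2 * at(0, -1) + at(1, -1))
  gy <- (at(1, -1) + 2 * at(1, 0) + at(1, 1)) -
        (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1))
  sqrt(gx^2 + gy^2)
}

# Pixels of a labelled region map that touch a different label (or the image
# border) through the 8-neighbourhood; returns a logical matrix.
region_boundary <- function(lab) {
  interior <- lab > 0
  for (i in seq_len(nrow(.NB8))) {
    interior <- interior & (shift_mat(lab, .NB8[i, 1], .NB8[i, 2], fill = -1) == lab)
  }
  (lab > 0) & !interior
}
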