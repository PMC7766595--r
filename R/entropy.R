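# Per-nucleus entropy sums of compartment size and optical-density
# distributions, and their aggregation into per-patient dual entropy sum
# histograms (DESH).

#' Histogram specification for compartment size and OD distributions
#'
#' Compartment sizes are binned on a logarithmic axis because they span
#' orders of magnitude within a nucleus of a few thousand pixels; OD values
#' use linear bins over the 10-bit range.
#'
#' @param size_bins number of log-spaced size bins over `[1, size_max]`
#'   (default 32).
#' @param od_bins number of linear OD bins over `od_range` (default 64).
#' @param size_max upper end of the size axis in pixels (default 2048).
#' @param od_range OD axis limits (default `c(0, 1023)`).
#' @return An object of class `hist_spec` carrying the bin edges.
#' @export
hist_spec <- function(size_bins = 32, od_bins = 64, size_max = 2048,
                      od_range = c(0, 1023)) {
  if (size_bins < 2 || od_bins < 2) stop_value("bin counts must be >= 2")
  structure(list(
    size_bins = as.integer(size_bins), od_bins = as.integer(od_bins),
    size_max = size_max, od_range = od_range,
    size_edges = exp(seq(log(1), log(size_max), length.out = size_bins + 1)),
    od_edges = seq(od_range[1], od_range[2], length.out = od_bins + 1)),
    class = "hist_spec")
}

#' Shannon entropy of a count histogram, in bits
#'
#' `H = -sum(p_b * log2(p_b))` over occupied bins, with `p = counts / sum`.
#' Histograms with total count 0 or 1 carry no diversity and return 0.
#'
#' @param counts nonnegative numeric vector of bin counts.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  if (any(counts < 0)) stop_value("negative histogram counts")
  n <- sum(counts)
  if (n <= 1) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

# Bin values with clipping into the end bins.
.bin_clip <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(b, 1L), length(edges) - 1L)
}

#' Size and OD histograms of one compartment class
#'
#' The size histogram counts one entry per compartment of the class; the OD
#' histogram counts one entry per member pixel of those compartments (pixel
#' densities, not per-compartment means). Values outside the axis limits are
#' clipped into the end bins.
#'
#' @param comps compartment list from [extract_compartments()].
#' @param region_class `"dark"` or `"bright"`.
#' @param spec a [hist_spec()].
#' @return List of numeric vectors `size_counts`, `od_counts`.
#' @export
compartment_histograms <- function(comps, region_class, spec = hist_spec()) {
  sel <- Filter(function(cc) cc$region_class == region_class, comps)
  sizes <- vapply(sel, function(cc) cc$size_px, numeric(1))
  ods <- unlist(lapply(sel, function(cc) cc$od_values))
  size_counts <- tabulate(.bin_clip(sizes, spec$size_edges), spec$size_bins)
  od_counts <- if (length(ods)) {
    tabulate(.bin_clip(ods, spec$od_edges), spec$od_bins)
  } else rep(0L, spec$od_bins)
  list(size_counts = size_counts, od_counts = od_counts)
}

#' Entropy sums of one nucleus
#'
#' For each compartment class, the Shannon entropy of the compartment size
#' histogram plus the Shannon entropy of the within-compartment OD
#' histogram: a single continuous value describing the diversity of highly
#' (dark) or weakly (bright) condensed chromatin compartments in the
#' nucleus. Zero when the nucleus has no compartment of the class.
#'
#' @param comps compartment list of one nucleus.
#' @param spec a [hist_spec()].
#' @return List with `e_dark` and `e_bright`, both in bits.
#' @export
nucleus_entropy_sums <- function(comps, spec = hist_spec()) {
  e <- function(cls) {
    h <- compartment_histograms(comps, cls, spec)
    shannon_entropy(h$size_counts) + shannon_entropy(h$od_counts)
  }
  list(e_dark = e("dark"), e_bright = e("bright"))
}

#' Fit an adaptive (equal-frequency) quantisation of entropy sums
#'
#' Bin edges are placed at the percentiles of the pooled training values, so
#' every DESH bin is populated on the training material. Duplicate or
#' degenerate edges are collapsed, which can shrink the effective bin count.
#' The outer edges are at minus/plus infinity: test values outside the
#' training range are clipped into the end bins.
#'
#' @param train_sums pooled entropy-sum values of the training nuclei.
#' @param Q requested bin count (default 40).
#' @return Numeric edge vector of length `effective_Q + 1`, starting with
#'   `-Inf` and ending with `Inf`.
#' @export
fit_quantization <- function(train_sums, Q = 40) {
  if (length(train_sums) < 1) stop_value("no entropy sums to quantise")
  if (Q < 2) stop_value("Q must be >= 2")
  qs <- unname(stats::quantile(train_sums, probs = seq(0, 1, length.out = Q + 1),
                               type = 7, names = FALSE))
  interior <- unique(qs[-c(1, Q + 1)])
  interior <- interior[interior > qs[1] & interior < qs[Q + 1]]
  c(-Inf, interior, Inf)
}

#' Build the DESH of one patient
#'
#' The normalised histogram, over the patient's nuclei, of one compartment
#' class's entropy sums, quantised with training-derived edges (test
#' patients reuse the training edges; no refitting).
#'
#' @param patient_sums entropy-sum values of the patient's nuclei.
#' @param edges edge vector from [fit_quantization()].
#' @param region_class `"dark"` or `"bright"` (metadata only).
#' @return An object of class `desh`: list of `region_class`, `edges`,
#'   `probs` (sums to 1).
#' @export
build_desh <- function(patient_sums, edges, region_class = NA_character_) {
  if (length(patient_sums) < 1) stop_value("patient has zero nuclei")
  interior <- edges[is.finite(edges)]
  bins <- findInterval(patient_sums, interior) + 1L
  counts <- tabulate(bins, nbins = length(interior) + 1L)
  structure(list(region_class = region_class, edges = edges,
                 probs = counts / sum(counts)),
            class = "desh")
}

# Entropy-sum table of one patient's nuclei.
#' Per-nucleus entropy sums for a list of nucleus images
#' @param images list of [nucleus_image()] objects.
#' @param params a [seg_params()].
#' @param spec a [hist_spec()].
#' @return Data frame with columns `nucleus_id`, `e_dark`, `e_bright`.
#' @export
patient_entropy_sums <- function(images, params = seg_params(),
                                 spec = hist_spec()) {
  rows <- lapply(seq_along(images), function(i) {
    seg <- segment_nucleus(images[[i]], params)
    es <- nucleus_entropy_sums(seg$compartments, spec)
    data.frame(nucleus_id = if (is.na(images[[i]]$nucleus_id))
                 as.character(i) else images[[i]]$nucleus_id,
               e_dark = es$e_dark, e_bright = es$e_bright,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
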