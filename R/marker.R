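# Adaptive DESH features and the equal-prior common-covariance Gaussian
# classifier that turns them into the DCC/SCC patient call.

#' Fit outcome-contrast bin weights for one DESH class
#'
#' Each DESH bin is scored by the bounded contrast ratio between the mean
#' training DESH of poor-outcome and good-outcome patients,
#' `w_b = (p_poor(b) - p_good(b)) / (p_poor(b) + p_good(b) + eps)`, so that
#' `w_b` is close to +1 for bins populated (almost) only by poor-outcome
#' patients, -1 for good-only bins, and 0 where the classes agree. Positive
#' weight is evidence of poor outcome. Swapping the outcome labels negates
#' every weight.
#'
#' @param train_deshs list of [build_desh()] objects, one per training
#'   patient, all sharing the same edges.
#' @param outcomes character vector, `"good"` or `"poor"`, parallel to
#'   `train_deshs`.
#' @param eps stabiliser of the ratio (default 1e-12).
#' @return List with `region_class` and weight vector `w` in `[-1, 1]`.
#' @export
fit_bin_weights <- function(train_deshs, outcomes, eps = 1e-12) {
  if (!any(outcomes == "poor") || !any(outcomes == "good"))
    stop_training("both outcome classes are required to fit bin weights")
  P <- do.call(rbind, lapply(train_deshs, function(d) d$probs))
  mp <- colMeans(P[outcomes == "poor", , drop = FALSE])
  mg <- colMeans(P[outcomes == "good", , drop = FALSE])
  structure(list(region_class = train_deshs[[1]]$region_class,
                 w = (mp - mg) / (mp + mg + eps)),
            class = "bin_weights")
}

#' Adaptive feature value of a DESH
#'
#' The weighted sum `F = sum(probs * w)`, a single continuous value in
#' `[-1, 1]`; positive values indicate a poor-outcome-like distribution of
#' entropy sums.
#'
#' @param desh a [build_desh()] object.
#' @param w a [fit_bin_weights()] object (matching bin count).
#' @return Numeric scalar feature value.
#' @export
desh_feature <- function(desh, w) {
  if (length(desh$probs) != length(w$w))
    stop_value("DESH and bin-weight lengths differ")
  sum(desh$probs * w$w)
}

#' Fit the equal-prior common-covariance Gaussian classifier
#'
#' Class means and the Bessel-weighted pooled covariance
#' `S = ((nP-1) SP + (nG-1) SG) / (nP + nG - 2)`. If the pooled matrix is
#' ill-conditioned (condition number above 1e8) a trace-scaled ridge
#' `lambda = 1e-6 * trace(S) / 2` (with an absolute floor for the fully
#' degenerate case) is added so the 2x2 solve stays well-posed on small
#' cohorts.
#'
#' @param features numeric matrix (patients x 2) of the dark and bright
#'   DESH features.
#' @param outcomes `"good"`/`"poor"` per row; at least 2 patients per class.
#' @return List with `mu_poor`, `mu_good`, `sigma_pooled`.
#' @export
fit_gaussian_classifier <- function(features, outcomes) {
  features <- as.matrix(features)
  xp <- features[outcomes == "poor", , drop = FALSE]
  xg <- features[outcomes == "good", , drop = FALSE]
  if (nrow(xp) < 2 || nrow(xg) < 2)
    stop_training("need at least 2 patients per outcome class")
  np <- nrow(xp); ng <- nrow(xg)
  S <- ((np - 1) * stats::cov(xp) + (ng - 1) * stats::cov(xg)) / (np + ng - 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > 1e8) {
    lambda <- max(1e-6 * sum(diag(S)) / 2, 1e-10)
    S <- S + diag(lambda, ncol(S))
  }
  list(mu_poor = colMeans(xp), mu_good = colMeans(xg), sigma_pooled = S)
}

#' Classify a patient's feature point
#'
#' The linear discriminant score
#' `g(x) = (muP - muG)' S^-1 x - 0.5 (muP - muG)' S^-1 (muP + muG)`
#' (equal priors, common covariance). The call is DCC (diverse chromatin
#' compartments, poor-prognosis indication) when `g >= 0` and SCC otherwise;
#' the boundary tie goes to DCC, the clinically conservative side.
#'
#' @param x numeric length-2 vector, or an n x 2 matrix of points.
#' @param marker a [train_marker()] object, or any list with `mu_poor`,
#'   `mu_good`, `sigma_pooled`.
#' @return For a single point, a `marker_result` list with `feature_dark`,
#'   `feature_bright`, `score`, `call`; for a matrix, a data frame with one
#'   row per point.
#' @export
classify_features <- function(x, marker) {
  d <- marker$mu_poor - marker$mu_good
  a <- tryCatch(solve(marker$sigma_pooled, d),
                error = function(e) stop_numerical(
                  "singular pooled covariance; classifier was not regularised"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  score <- as.numeric(X %*% a) - 0.5 * sum(a * (marker$mu_poor + marker$mu_good))
  call <- ifelse(score >= 0, "DCC", "SCC")
  if (single) {
    structure(list(feature_dark = X[1, 1], feature_bright = X[1, 2],
                   score = score, call = call), class = "marker_result")
  } else {
    data.frame(feature_dark = X[, 1], feature_bright = X[, 2],
               score = score, call = call, stringsAsFactors = FALSE)
  }
}

#' Train the marker of diversity of chromatin compartments
#'
#' Runs the full training pipeline on a labelled cohort: segment every
#' nucleus, compute per-nucleus entropy sums, fit the adaptive quantisation
#' on the pooled training sums (separately for dark and bright), build the
#' per-patient DESHs, fit the outcome-contrast bin weights, reduce each
#' patient to the two DESH features, and fit the Gaussian common-covariance
#' classifier. Deterministic for fixed inputs and parameters.
#'
#' @param cohort a `cohort` object (see [read_cohort()] /
#'   [generate_cohort()]) whose patients carry `outcome` labels
#'   (`"good"`/`"poor"`; `"unknown"` patients are excluded from training).
#' @param params a [seg_params()].
#' @param spec a [hist_spec()].
#' @param Q requested DESH bin count (default 40).
#' @return An object of class `trained_marker`: quantisation edges, bin
#'   weights, classifier parameters, the segmentation/histogram settings and
#'   the per-patient training features.
#' @export
train_marker <- function(cohort, params = seg_params(), spec = hist_spec(),
                         Q = 40) {
  pts <- Filter(function(p) p$outcome %in% c("good", "poor"), cohort$patients)
  if (length(pts) < 4)
    stop_training("too few labelled patients to train")
  outcomes <- vapply(pts, function(p) p$outcome, character(1))
  if (sum(outcomes == "poor") < 2 || sum(outcomes == "good") < 2)
    stop_training("need at least 2 patients per outcome class")
  sums <- lapply(pts, function(p) {
    if (length(p$images) == 0) stop_value(
      sprintf("patient %s has zero readable nuclei", p$patient_id))
    patient_entropy_sums(p$images, params, spec)
  })
  edges_dark <- fit_quantization(unlist(lapply(sums, `[[`, "e_dark")), Q)
  edges_bright <- fit_quantization(unlist(lapply(sums, `[[`, "e_bright")), Q)
  desh_dark <- lapply(sums, function(s) build_desh(s$e_dark, edges_dark, "dark"))
  desh_bright <- lapply(sums, function(s) build_desh(s$e_bright, edges_bright, "bright"))
  w_dark <- fit_bin_weights(desh_dark, outcomes)
  w_bright <- fit_bin_weights(desh_bright, outcomes)
  feats <- cbind(
    feature_dark = vapply(desh_dark, desh_feature, numeric(1), w = w_dark),
    feature_bright = vapply(desh_bright, desh_feature, numeric(1), w = w_bright))
  cls <- fit_gaussian_classifier(feats, outcomes)
  train_features <- data.frame(
    patient_id = vapply(pts, function(p) p$patient_id, character(1)),
    outcome = outcomes, feats,
    call = classify_features(feats, cls)$call,
    stringsAsFactors = FALSE)
  structure(list(
    version = "1.0", Q = Q, seg_params = params, hist_spec = spec,
    edges_dark = edges_dark, edges_bright = edges_bright,
    w_dark = w_dark, w_bright = w_bright,
    mu_poor = cls$mu_poor, mu_good = cls$mu_good,
    sigma_pooled = cls$sigma_pooled,
    train_features = train_features), class = "trained_marker")
}

#' Apply a trained marker to one patient's nucleus images
#'
#' Uses the marker's stored quantisation edges, bin weights and classifier
#' parameters; nothing is refitted on test data, and no outcome labels are
#' consumed. Duplicating every nucleus leaves the (normalised) DESH, the
#' features and the call unchanged.
#'
#' @param images list of [nucleus_image()] objects of one patient.
#' @param marker a [train_marker()] object.
#' @return A `marker_result` list: `feature_dark`, `feature_bright`,
#'   `score`, `call`, plus the patient's two DESHs and `n_nuclei`.
#' @export
apply_marker <- function(images, marker) {
  if (length(images) == 0) stop_value("patient has zero readable nuclei")
  sums <- patient_entropy_sums(images, marker$seg_params, marker$hist_spec)
  dd <- build_desh(sums$e_dark, marker$edges_dark, "dark")
  db <- build_desh(sums$e_bright, marker$edges_bright, "bright")
  x <- c(desh_feature(dd, marker$w_dark), desh_feature(db, marker$w_bright))
  res <- classify_features(x, marker)
  res$desh_dark <- dd
  res$desh_bright <- db
  res$n_nuclei <- length(images)
  res
}

#' Score every patient of a cohort with a trained marker
#'
#' @param cohort a `cohort` object.
#' @param marker a [train_marker()] object.
#' @return Data frame with one row per patient: identifiers, features,
#'   score, call, and the cohort's outcome/survival columns for downstream
#'   evaluation.
#' @export
score_cohort <- function(cohort, marker) {
  rows <- lapply(cohort$patients, function(p) {
    r <- apply_marker(p$images, marker)
    data.frame(patient_id = p$patient_id,
               feature_dark = r$feature_dark, feature_bright = r$feature_bright,
               score = r$score, call = r$call, stringsAsFactors = FALSE)
  })
  cbind(do.call(rbind, rows),
        cohort_records(cohort)[, c("outcome", "time_years", "event",
                                   "figo_substage", "grade_class",
                                   "path_risk", "age", "chromatin_value")])
}

#' Serialise a trained marker to JSON
#'
#' Writes the auditable `marker.json` schema: version, settings,
#' quantisation edges (interior, finite), bin weights, class means and
#' pooled covariance. Training-feature tables are not serialised.
#'
#' @param marker a [train_marker()] object.
#' @param path output path.
#' @export
write_marker <- function(marker, path) {
  doc <- list(
    version = marker$version, Q = marker$Q,
    seg_params = unclass(marker$seg_params),
    hist_spec = unclass(marker$hist_spec)[c("size_bins", "od_bins",
                                            "size_max", "od_range")],
    edges_dark = marker$edges_dark[is.finite(marker$edges_dark)],
    edges_bright = marker$edges_bright[is.finite(marker$edges_bright)],
    w_dark = marker$w_dark$w, w_bright = marker$w_bright$w,
    mu_poor = unname(marker$mu_poor), mu_good = unname(marker$mu_good),
    sigma = unname(marker$sigma_pooled))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a marker serialised by [write_marker()]
#' @param path path to `marker.json`.
#' @return A `trained_marker` object.
#' @export
read_marker <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || doc$version != "1.0")
    stop_format("incompatible marker version")
  hs <- doc$hist_spec
  structure(list(
    version = doc$version, Q = doc$Q,
    seg_params = do.call(seg_params, as.list(doc$seg_params)),
    hist_spec = hist_spec(hs$size_bins, hs$od_bins, hs$size_max, hs$od_range),
    edges_dark = c(-Inf, doc$edges_dark, Inf),
    edges_bright = c(-Inf, doc$edges_bright, Inf),
    w_dark = structure(list(region_class = "dark", w = doc$w_dark),
                       class = "bin_weights"),
    w_bright = structure(list(region_class = "bright", w = doc$w_bright),
                         class = "bin_weights"),
    mu_poor = doc$mu_poor, mu_good = doc$mu_good,
    sigma_pooled = matrix(unlist(doc$sigma), 2, 2),
    train_features = NULL), class = "trained_marker")
}
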