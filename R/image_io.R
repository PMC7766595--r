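#' Nucleus image container
#'
#' Bundles a 2-D grid of optical-density (OD) values on the 10-bit scale
#' 0--1023 with a same-shape binary nuclear mask. The mask is hole-filled on
#' construction and pixel values are clamped to the valid range, so every
#' `nucleus_image` satisfies the class invariants: no interior mask holes,
#' all values in `[0, 1023]`.
#'
#' @param pixels numeric matrix of OD values (10-bit scale).
#' @param mask logical or 0/1 matrix of the same shape; `TRUE`/1 marks
#'   nuclear pixels.
#' @param pixel_size_nm physical pixel size in nanometres (default 165).
#' @param patient_id,nucleus_id optional identifiers.
#' @return An object of class `nucleus_image` with elements `pixels`,
#'   `mask`, `pixel_size_nm`, `patient_id`, `nucleus_id`.
#' @export
nucleus_image <- function(pixels, mask, pixel_size_nm = 165,
                          patient_id = NA_character_,
                          nucleus_id = NA_character_) {
  if (!is.matrix(pixels)) stop_format("pixels must be a matrix")
  if (!identical(dim(pixels), dim(mask)))
    stop_format("image and mask shapes differ")
  mask <- matrix(as.logical(mask), nrow(pixels), ncol(pixels))
  if (anyNA(mask) || anyNA(pixels))
    stop_format("NA values in image or mask")
  if (!any(mask)) stop_value("empty nuclear mask")
  mask <- fill_mask_holes(mask)
  pixels <- pmin(pmax(pixels, 0), 1023)
  structure(
    list(pixels = pixels, mask = mask, pixel_size_nm = pixel_size_nm,
         patient_id = patient_id, nucleus_id = nucleus_id),
    class = "nucleus_image"
  )
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf("<nucleus_image %s/%s: %d x %d px, %d in mask, OD %.0f-%.0f>\n",
              x$patient_id, x$nucleus_id, nrow(x$pixels), ncol(x$pixels),
              sum(x$mask), min(x$pixels[x$mask]), max(x$pixels[x$mask])))
  invisible(x)
}

#' Fill interior holes of a binary mask
#'
#' A hole is a background connected component (4-connectivity) that does not
#' reach the image border. Holes are set to foreground; foreground pixels are
#' never removed, so the operation is idempotent and monotone. Background
#' 4-connectivity is the standard dual of the 8-connectivity used for
#' compartments.
#'
#' @param mask logical or 0/1 matrix.
#' @return Logical matrix with all interior holes filled.
#' @export
fill_mask_holes <- function(mask) {
  mask <- if (is.logical(mask)) mask else matrix(as.logical(mask), nrow(mask), ncol(mask))
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(mask)] <- bg[, ncol(mask)]
  repeat {
    nxt <- reach
    for (i in seq_len(nrow(.NB4))) {
      nxt <- nxt | shift_mat(reach, .NB4[i, 1], .NB4[i, 2], fill = FALSE)
    }
    nxt <- nxt & bg
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mask | (bg & !reach)
}

#' Optical-density transform of raw transmittance intensities
#'
#' Converts background-corrected raw intensities to optical density
#' `OD = log10(background / max(raw, 1))`, then rescales linearly so that
#' `OD = 0` maps to 0 and `OD = od_ceiling` maps to 1023 (the 10-bit scale).
#' Raw values of 0 are clamped to 1 so the OD stays finite; the transform is
#' strictly decreasing in `raw` on `[1, background]`.
#'
#' @param raw nonnegative numeric matrix (or vector) of raw intensities.
#' @param background scalar or same-shape grid of blank-field intensities.
#' @param od_ceiling OD value mapped to 1023; default 2.0, a typical maximal
#'   absorbance for Feulgen preparations.
#' @return Numeric grid of OD values clamped to `[0, 1023]` (not rounded).
#' @export
od_transform <- function(raw, background, od_ceiling = 2.0) {
  if (any(background <= 0)) stop_value("background intensity must be positive")
  if (any(raw < 0)) stop_value("raw intensities must be nonnegative")
  od <- log10(background / pmax(raw, 1))
  pmin(pmax(od / od_ceiling * 1023, 0), 1023)
}

# Read a grayscale image as integer values on the 0..65535 scale. 16-bit
# PNGs are stored as two 8-bit channels (high byte, low byte) because the
# png package writes 8 bits per channel.
.read_gray <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = round(tiff::readTIFF(path) * 65535),
    png = {
      x <- png::readPNG(path)
      if (length(dim(x)) == 3 && dim(x)[3] >= 2) {
        round(x[, , 1] * 255) * 256 + round(x[, , 2] * 255)
      } else {
        if (length(dim(x)) == 3) x <- x[, , 1]
        round(x * 65535)
      }
    },
    stop_format(sprintf("unsupported image format: .%s", ext)))
}

#' Read a nucleus image and its mask from disk
#'
#' Images are 16-bit grayscale TIFF (preferred) or PNG containers holding
#' 10-bit values: a stored intensity `x in [0, 1]` decodes to
#' `round(x * 65535)` OD units. Masks use any nonzero value as foreground
#' and are hole-filled on load. If `values = "raw"` the stored values are
#' treated as raw transmittance intensities and passed through
#' [od_transform()] with the given `background`.
#'
#' @param path image file path (.tif/.tiff/.png).
#' @param mask_path mask file path of the same shape.
#' @param values `"od"` (default; values are already OD) or `"raw"`.
#' @param background blank-field intensity, required when `values = "raw"`.
#' @param od_ceiling see [od_transform()].
#' @param patient_id,nucleus_id identifiers recorded on the object.
#' @return A [nucleus_image()].
#' @export
read_nucleus_image <- function(path, mask_path, values = c("od", "raw"),
                               background = NULL, od_ceiling = 2.0,
                               patient_id = NA_character_,
                               nucleus_id = NA_character_) {
  values <- match.arg(values)
  img <- .read_gray(path)
  msk <- .read_gray(mask_path) > 32767
  if (!identical(dim(img), dim(msk)))
    stop_format(sprintf("image %s and mask %s shapes differ", path, mask_path))
  if (values == "raw") {
    if (is.null(background)) stop_value("values='raw' requires a background intensity")
    img <- round(od_transform(img, background, od_ceiling))
  }
  nucleus_image(img, msk, patient_id = patient_id, nucleus_id = nucleus_id)
}

#' Write a nucleus image and mask to disk
#'
#' Stores OD values in a 16-bit grayscale TIFF or PNG (value `v` encoded as
#' `v / 65535`) and the mask as an 8-bit binary image. The round trip through
#' [read_nucleus_image()] reproduces integer-valued pixels and the mask
#' bit-exactly.
#'
#' @param img a [nucleus_image()].
#' @param path,mask_path output paths; format chosen by extension.
#' @export
write_nucleus_image <- function(img, path, mask_path) {
  stopifnot(inherits(img, "nucleus_image"))
  wr <- function(v, p, bits) {
    ext <- tolower(tools::file_ext(p))
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(v / 65535, p, bits.per.sample = bits)
    } else if (ext == "png") {
      if (bits == 16L) {
        png::writePNG(array(c(v %/% 256, v %% 256) / 255,
                            c(nrow(v), ncol(v), 2)), p)
      } else {
        png::writePNG(v / 65535, p)
      }
    } else stop_format(sprintf("unsupported image format: .%s", ext))
  }
  wr(round(img$pixels), path, 16L)
  wr(img$mask * 65535, mask_path, 8L)
  invisible(c(path, mask_path))
}

#' Read and validate a cohort from manifest files
#'
#' A cohort directory holds `images.csv` (`patient_id,nucleus_path,mask_path`;
#' paths relative to the directory), `patients.csv`
#' (`patient_id,outcome,time_years,event,figo_substage,grade_class,path_risk,age,chromatin_value`)
#' and the referenced image files.
#'
#' @param dir cohort directory.
#' @param load_images if `FALSE`, only manifests are read and validated.
#' @param values,background,od_ceiling forwarded to [read_nucleus_image()].
#' @return A `cohort` object: a list with one element per patient, each a
#'   list of `patient_id`, `outcome`, `time_years`, `event`, covariates,
#'   `chromatin_value` and `images` (list of [nucleus_image()]).
#' @export
read_cohort <- function(dir, load_images = TRUE, values = "od",
                        background = NULL, od_ceiling = 2.0) {
  for (f in c("images.csv", "patients.csv")) {
    if (!file.exists(file.path(dir, f)))
      stop_format(sprintf("manifest not found: %s", file.path(dir, f)))
  }
  ims <- utils::read.csv(file.path(dir, "images.csv"), stringsAsFactors = FALSE)
  pts <- utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  validate_manifest(ims, pts, dir)
  for (opt in c("figo_substage", "grade_class", "path_risk", "age",
                "chromatin_value")) {
    if (is.null(pts[[opt]])) pts[[opt]] <- NA
  }
  patients <- lapply(seq_len(nrow(pts)), function(i) {
    p <- as.list(pts[i, ])
    rows <- ims[ims$patient_id == p$patient_id, , drop = FALSE]
    imgs <- if (load_images) {
      lapply(seq_len(nrow(rows)), function(j)
        read_nucleus_image(file.path(dir, rows$nucleus_path[j]),
                           file.path(dir, rows$mask_path[j]),
                           values = values, background = background,
                           od_ceiling = od_ceiling,
                           patient_id = p$patient_id,
                           nucleus_id = basename(rows$nucleus_path[j])))
    } else list()
    c(p, list(images = imgs))
  })
  structure(list(patients = patients, dir = dir), class = "cohort")
}

#' Validate cohort manifests
#'
#' Checks the manifest invariants: unique patient ids, events in `{0, 1}`,
#' nonnegative times, outcomes in `{good, poor, unknown}`, and that every
#' referenced image path resolves.
#'
#' @param images_df,patients_df manifest data frames.
#' @param dir base directory for relative paths (`NULL` skips existence checks).
#' @return Invisibly `TRUE`; signals a format error otherwise.
#' @export
validate_manifest <- function(images_df, patients_df, dir = NULL) {
  need_i <- c("patient_id", "nucleus_path", "mask_path")
  need_p <- c("patient_id", "outcome", "time_years", "event")
  if (!all(need_i %in% names(images_df)))
    stop_format("images manifest lacks required columns")
  if (!all(need_p %in% names(patients_df)))
    stop_format("patients manifest lacks required columns")
  if (anyDuplicated(patients_df$patient_id))
    stop_format("duplicate patient_id in patients manifest")
  if (!all(patients_df$event %in% c(0, 1)))
    stop_format("event must be 0 or 1")
  if (any(patients_df$time_years < 0))
    stop_format("time_years must be nonnegative")
  if (!all(patients_df$outcome %in% c("good", "poor", "unknown")))
    stop_format("outcome must be good, poor or unknown")
  if (!all(images_df$patient_id %in% patients_df$patient_id))
    stop_format("images manifest references unknown patient_id")
  if (!is.null(dir)) {
    paths <- file.path(dir, c(images_df$nucleus_path, images_df$mask_path))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop_format(sprintf("unresolvable image paths (e.g. %s)", missing[1]))
  }
  invisible(TRUE)
}

#' Write a cohort to a directory in the manifest layout
#'
#' @param cohort a `cohort` object whose patients carry in-memory images.
#' @param dir output directory (created if needed).
#' @param format `"tiff"` or `"png"` for the nucleus images.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  irows <- list(); prows <- list()
  for (p in cohort$patients) {
    pdir <- file.path(dir, p$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    for (j in seq_along(p$images)) {
      np <- file.path(p$patient_id, sprintf("nucleus_%04d.%s", j, ext))
      mp <- file.path(p$patient_id, sprintf("mask_%04d.%s", j, ext))
      write_nucleus_image(p$images[[j]], file.path(dir, np), file.path(dir, mp))
      irows[[length(irows) + 1L]] <- data.frame(
        patient_id = p$patient_id, nucleus_path = np, mask_path = mp,
        stringsAsFactors = FALSE)
    }
    prows[[length(prows) + 1L]] <- data.frame(
      patient_id = p$patient_id, outcome = p$outcome,
      time_years = p$time_years, event = p$event,
      figo_substage = p$figo_substage, grade_class = p$grade_class,
      path_risk = p$path_risk, age = p$age,
      chromatin_value = p$chromatin_value, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, irows), file.path(dir, "images.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, prows), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# Survival/covariate table of a cohort (one row per patient), used by the
# evaluation functions.
#' Extract the per-patient survival and covariate table of a cohort
#' @param cohort a `cohort` object.
#' @return A data frame with one row per patient.
#' @export
cohort_records <- function(cohort) {
  do.call(rbind, lapply(cohort$patients, function(p) data.frame(
    patient_id = p$patient_id, outcome = p$outcome,
    time_years = p$time_years, event = p$event,
    figo_substage = p$figo_substage, grade_class = p$grade_class,
    path_risk = p$path_risk, age = p$age,
    chromatin_value = p$chromatin_value, stringsAsFactors = FALSE)))
}
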