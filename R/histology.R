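## Histology quantification: Lab colour-space stain segmentation,
## field-based microvessel density, and the ellipsoid tumour-volume helper.

#' Segment stain-positive tissue in Lab colour space
#'
#' Converts the slide to CIE Lab, excludes background (near-white pixels:
#' `L* > 95`, or `L* > 90` with chroma below 8 so the rule is robust to
#' modest brightness changes), partitions the remaining tissue pixels into
#' two classes by seeded k-means on the `(a*, b*)` chroma plane, and labels
#' as stain-positive the class whose centroid lies nearer the reference
#' colour of the requested stain. Percent positivity is reported over
#' tissue pixels, not the whole canvas.
#'
#' @param image rows x cols x 3 sRGB array in \[0, 1\] (as returned by
#'   [renderHistologySlide()] or [png::readPNG()]).
#' @param stain `"picrosirius_red"` (collagen) or `"dab"`
#'   (immunohistochemistry).
#' @param seed integer seed for the k-means initialisation.
#' @return A list: logical `stainMask` and `tissueMask`,
#'   `percentPositive` (0-100, share of tissue pixels), and the
#'   `stainReference` Lab colour used.
#' @examples
#' slide <- renderHistologySlide(0.25, seed = 3, size = c(96, 96))
#' segmentStain(slide$image, "picrosirius_red")$percentPositive
#' @export
segmentStain <- function(image, stain = c("picrosirius_red", "dab"),
                         seed = 1L) {
  stain <- match.arg(stain)
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be a rows x cols x 3 RGB array", call. = FALSE)
  dims <- dim(image)[1:2]
  lab <- grDevices::convertColor(matrix(image, ncol = 3L),
                                 from = "sRGB", to = "Lab")
  chroma <- sqrt(lab[, 2]^2 + lab[, 3]^2)
  background <- lab[, 1] > 95 | (lab[, 1] > 90 & chroma < 8)
  tissue <- !background
  if (!any(tissue))
    stop("image is entirely background", call. = FALSE)

  ab <- lab[tissue, 2:3, drop = FALSE]
  km <- withSeed(seed, stats::kmeans(ab, centers = 2L, nstart = 5L))
  ref <- stainReferenceLab(stain)[c("a", "b")]
  d <- sqrt(rowSums((km$centers - matrix(ref, 2, 2, byrow = TRUE))^2))
  stainClass <- which.min(d)
  ## on a stain-free slide k-means still splits the counterstain jitter in
  ## two; accept the nearer class as stain only if its centroid actually
  ## sits at the stain colour
  pos <- if (min(d) > 12) rep(FALSE, nrow(ab))
         else km$cluster == stainClass

  stainMask <- matrix(FALSE, dims[1], dims[2])
  stainMask[which(tissue)[pos]] <- TRUE
  list(stainMask = stainMask,
       tissueMask = matrix(tissue, dims[1], dims[2]),
       percentPositive = 100 * mean(pos),
       stainReference = stainReferenceLab(stain))
}

#' Microvessel density from randomly sampled fields
#'
#' Places `nFields` non-overlapping square fields of `fieldArea` mm^2
#' across the section (seeded placement, or explicit `origins`), counts the
#' immunostain-positive vessels whose connected-component centroid falls
#' inside a field, and converts to vessels per mm^2:
#' `mvd = vessels / (nFields * fieldArea)`.
#'
#' @param vesselImage either a logical vessel mask or an RGB slide (in
#'   which case the DAB class is segmented first via [segmentStain()]).
#' @param nFields number of fields, at least 1.
#' @param fieldArea field area in mm^2 (default 0.25, a x200 field).
#' @param pixelsPerMm image scale.
#' @param seed integer seed for field placement.
#' @param origins optional integer matrix of field top-left `(row, col)`
#'   corners, one row per field, overriding random placement (use to tile
#'   the section exactly).
#' @return A list: `mvd` (vessels/mm^2), `vesselsCounted`, `fieldsSampled`
#'   (corner matrix), `fieldSidePx` and `fieldArea`.
#' @export
countMvd <- function(vesselImage, nFields = 6L, fieldArea = 0.25,
                     pixelsPerMm = 100, seed = 1L, origins = NULL) {
  if (nFields < 1L) stop("nFields must be at least 1", call. = FALSE)
  stopifnotPositive(fieldArea, "fieldArea")
  mask <- if (length(dim(vesselImage)) == 3L)
    segmentStain(vesselImage, "dab", seed = seed)$stainMask
  else vesselImage != 0
  dims <- dim(mask)
  side <- round(sqrt(fieldArea) * pixelsPerMm)
  if (side > min(dims))
    stop("tissue is smaller than one field", call. = FALSE)

  if (is.null(origins)) {
    origins <- withSeed(seed, {
      placed <- matrix(integer(0), ncol = 2L)
      guard <- 0L
      while (nrow(placed) < nFields) {
        guard <- guard + 1L
        if (guard > 10000L)
          stop("could not place ", nFields, " non-overlapping fields",
               call. = FALSE)
        cand <- c(sample.int(dims[1] - side + 1L, 1L),
                  sample.int(dims[2] - side + 1L, 1L))
        if (!nrow(placed) ||
            all(abs(placed[, 1] - cand[1]) >= side |
                abs(placed[, 2] - cand[2]) >= side))
          placed <- rbind(placed, cand)
      }
      placed
    })
  } else {
    origins <- matrix(as.integer(origins), ncol = 2L)
    if (nrow(origins) != nFields)
      stop("origins must supply one corner per field", call. = FALSE)
  }

  labels <- EBImage::bwlabel(mask * 1)
  nComp <- max(labels)
  counted <- 0L
  if (nComp > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lv <- labels[labels > 0]
    cr <- tapply(idx[, 1], lv, mean)
    cc <- tapply(idx[, 2], lv, mean)
    inField <- rep(FALSE, nComp)
    for (i in seq_len(nrow(origins))) {
      o <- origins[i, ]
      inField <- inField |
        (cr >= o[1] & cr < o[1] + side & cc >= o[2] & cc < o[2] + side)
    }
    counted <- sum(inField)
  }
  list(mvd = counted / (nFields * fieldArea), vesselsCounted = counted,
       fieldsSampled = origins, fieldSidePx = side, fieldArea = fieldArea)
}

#' Ellipsoid tumour volume from calliper measurements
#'
#' `(pi / 6) * L * W * D`, symmetric in its arguments.
#'
#' @param l,w,d the three orthogonal lengths (any consistent unit).
#' @return Volume in the cubed unit.
#' @examples
#' ellipsoidVolume(3, 2, 1)  # = pi
#' @export
ellipsoidVolume <- function(l, w, d) {
  stopifnotPositive(c(l, w, d), "lengths")
  pi / 6 * l * w * d
}
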