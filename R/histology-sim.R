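## Synthetic histology slide renderer. Fixed reference Lab colours for the
## stains, per-pixel jitter, and exact-by-construction ground-truth masks.

stainReferenceLab <- function(stain = c("picrosirius_red", "dab",
                                        "counterstain", "background")) {
  switch(match.arg(stain),
    picrosirius_red = c(L = 45, a = 65, b = 35),
    dab             = c(L = 40, a = 20, b = 35),
    counterstain    = c(L = 75, a = 15, b = 8),
    background      = c(L = 98, a = 0, b = 0))
}

## Grow random discs inside `allowed` until `target` pixels are set, then
## trim the surplus so the mask hits the target exactly.
growBlobMask <- function(dims, allowed, target, radiusRange = c(4, 12)) {
  mask <- matrix(FALSE, dims[1], dims[2])
  if (target <= 0) return(mask)
  rows <- row(mask); cols <- col(mask)
  allowedIdx <- which(allowed)
  guard <- 0L
  while (sum(mask) < target) {
    guard <- guard + 1L
    if (guard > 10000L) stop("blob growth failed to reach target fraction",
                             call. = FALSE)
    ctr <- allowedIdx[sample.int(length(allowedIdx), 1L)]
    r <- stats::runif(1, radiusRange[1], radiusRange[2])
    disc <- (rows - rows[ctr])^2 + (cols - cols[ctr])^2 <= r^2
    mask <- mask | (disc & allowed)
  }
  excess <- sum(mask) - target
  if (excess > 0) {
    drop <- sample(which(mask), excess)
    mask[drop] <- FALSE
  }
  mask
}

#' Render a synthetic stained histology slide
#'
#' Draws a tissue section (canvas minus a white background margin) in a
#' counterstain colour, stain-positive blobs whose pixel share of the
#' tissue equals the requested fractions exactly by construction, and
#' optionally a set of disjoint vessel blobs (an immunostained endothelium
#' proxy for microvessel counting). Colours are fixed reference Lab values
#' for picrosirius red, DAB brown and the counterstain, jittered per pixel,
#' then converted to sRGB. Ground-truth masks are returned so segmentation
#' can be validated against the exact truth.
#'
#' @param collagenFraction target picrosirius-red-positive fraction of the
#'   tissue pixels, in \[0, 1\].
#' @param hypoxiaFraction target DAB-positive fraction, in \[0, 1\]
#'   (disjoint from the collagen blobs).
#' @param nVessels number of disjoint vessel components to place.
#' @param size canvas `c(rows, cols)` in pixels.
#' @param seed integer RNG seed.
#' @param labJitter per-pixel Gaussian jitter SD on each Lab channel.
#' @return A list: `image` (rows x cols x 3 sRGB array in \[0, 1\]),
#'   logical matrices `collagenMask`, `hypoxiaMask`, `vesselMask`,
#'   `tissueMask`, and `collagenFraction`/`hypoxiaFraction` actually laid
#'   down.
#' @examples
#' slide <- renderHistologySlide(0.25, seed = 3, size = c(96, 96))
#' mean(slide$collagenMask[slide$tissueMask])
#' @export
renderHistologySlide <- function(collagenFraction, hypoxiaFraction = 0,
                                 nVessels = 0L, size = c(256, 256),
                                 seed = 1L, labJitter = 1.5) {
  if (collagenFraction < 0 || collagenFraction > 1 ||
      hypoxiaFraction < 0 || hypoxiaFraction > 1)
    stop("stain fractions must lie in [0, 1]", call. = FALSE)
  if (collagenFraction + hypoxiaFraction > 0.95)
    stop("requested stain fractions exceed the canvas capacity",
         call. = FALSE)
  dims <- as.integer(size)
  margin <- max(4L, round(min(dims) * 0.03))
  tissue <- matrix(FALSE, dims[1], dims[2])
  tissue[(margin + 1):(dims[1] - margin), (margin + 1):(dims[2] - margin)] <- TRUE
  nTissue <- sum(tissue)

  withSeed(seed, {
    collagen <- growBlobMask(dims, tissue,
                             round(collagenFraction * nTissue))
    hypoxia <- growBlobMask(dims, tissue & !collagen,
                            round(hypoxiaFraction * nTissue))
    vessels <- matrix(FALSE, dims[1], dims[2])
    if (nVessels > 0) {
      rows <- row(vessels); cols <- col(vessels)
      centres <- matrix(numeric(0), ncol = 2)
      inner <- which(tissue & rows > margin + 4 & rows < dims[1] - margin - 4 &
                     cols > margin + 4 & cols < dims[2] - margin - 4)
      guard <- 0L
      while (nrow(centres) < nVessels) {
        guard <- guard + 1L
        if (guard > 20000L)
          stop("could not place ", nVessels, " disjoint vessels",
               call. = FALSE)
        v <- inner[sample.int(length(inner), 1L)]
        cand <- c(rows[v], cols[v])
        if (!nrow(centres) ||
            min((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) > 49)
          centres <- rbind(centres, cand)
      }
      for (i in seq_len(nrow(centres)))
        vessels <- vessels |
          ((rows - centres[i, 1])^2 + (cols - centres[i, 2])^2 <= 4)
    }

    lab <- matrix(rep(stainReferenceLab("background"), each = prod(dims)),
                  ncol = 3)
    assignLab <- function(maskIdx, ref) {
      lab[maskIdx, ] <<- matrix(rep(ref, each = length(maskIdx)), ncol = 3)
    }
    assignLab(which(tissue), stainReferenceLab("counterstain"))
    assignLab(which(collagen), stainReferenceLab("picrosirius_red"))
    assignLab(which(hypoxia), stainReferenceLab("dab"))
    if (any(vessels)) assignLab(which(vessels), stainReferenceLab("dab"))
    jitterIdx <- which(tissue)
    lab[jitterIdx, ] <- lab[jitterIdx, ] +
      matrix(stats::rnorm(length(jitterIdx) * 3, 0, labJitter), ncol = 3)
    rgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB",
                                   clip = TRUE)
    img <- array(rgb, dim = c(dims, 3L))

    list(image = img, collagenMask = collagen, hypoxiaMask = hypoxia,
         vesselMask = vessels, tissueMask = tissue,
         collagenFraction = sum(collagen) / nTissue,
         hypoxiaFraction = sum(hypoxia) / nTissue)
  })
}
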