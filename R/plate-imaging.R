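# Idealized plate scans of sectored colonies and the threshold ->
# binary image -> connected-component counter used for the half-sector
# denominator. Sectors are drawn as ideal wedges (a half sector is a
# 180-degree wedge); half-sector *scoring* from images is deliberately
# not automated - plates are scored for totals by thresholding, while
# half and fully green colonies are counted by eye.

#' Render an idealized plate scan
#'
#' Colonies are placed as non-overlapping disks by bounded rejection
#' sampling. In the GFP channel, red colonies sit at the background
#' level, fully green colonies are bright disks, and half / partial
#' sectors are bright wedges of the corresponding angular fraction
#' (180 degrees for a half sector; partial sectors draw a random wedge
#' between 18 and 162 degrees). The composite channel renders every
#' colony bright and is the input for total-colony counting.
#'
#' @param classes character vector of colony classes (`"red"`,
#'   `"half_sector"`, `"partial_sector"`, `"full_green"`), e.g. the
#'   `class` column of [simulateColonyTable()].
#' @param geometry list of rendering parameters: `imageSize` (pixels,
#'   square), `radiusRange` (colony radius range, pixels), `background`
#'   and `level` (intensities of background and GFP-bright pixels).
#' @param seed explicit RNG seed.
#' @return A [PlateRender-class] object.
#' @examples
#' pr <- renderPlate(c("red", "half_sector", "full_green"), seed = 1)
#' countColonies(pr@composite, threshold = 0.5)
#' @export
renderPlate <- function(classes,
                        geometry = list(imageSize = 512L,
                                        radiusRange = c(8, 14),
                                        background = 0.05, level = 1),
                        seed) {
  stopifnot(all(classes %in% c("red", "half_sector", "partial_sector",
                               "full_green")))
  n <- length(classes)
  size <- as.integer(geometry$imageSize)
  withSeed(seed, {
    radius <- stats::runif(n, geometry$radiusRange[1L],
                           geometry$radiusRange[2L])
    xs <- numeric(0)
    ys <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        x <- stats::runif(1, radius[i] + 2, size - radius[i] - 1)
        y <- stats::runif(1, radius[i] + 2, size - radius[i] - 1)
        if (i == 1L ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >
                radius[seq_len(i - 1L)] + radius[i] + 2)) {
          xs <- c(xs, x)
          ys <- c(ys, y)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", n, " non-overlapping colonies on a ",
             size, " px plate")
    }
    wedge <- vapply(classes, function(cl) switch(cl,
      red = 0, full_green = 2 * pi, half_sector = pi,
      partial_sector = stats::runif(1, 0.05, 0.45) * 2 * pi),
      numeric(1))
    start <- stats::runif(n, 0, 2 * pi)
    gfp <- matrix(geometry$background, nrow = size, ncol = size)
    composite <- matrix(geometry$background, nrow = size, ncol = size)
    for (i in seq_len(n)) {
      px <- max(1L, floor(xs[i] - radius[i])):min(size,
                                                  ceiling(xs[i] + radius[i]))
      py <- max(1L, floor(ys[i] - radius[i])):min(size,
                                                  ceiling(ys[i] + radius[i]))
      dy <- outer(py - ys[i], rep(1, length(px)))
      dx <- outer(rep(1, length(py)), px - xs[i])
      inside <- dx^2 + dy^2 <= radius[i]^2
      sub <- composite[py, px]
      sub[inside] <- geometry$level
      composite[py, px] <- sub
      if (wedge[i] > 0) {
        ang <- (atan2(dy, dx) - start[i]) %% (2 * pi)
        green <- inside & ang <= wedge[i]
        sub <- gfp[py, px]
        sub[green] <- geometry$level
        gfp[py, px] <- sub
      }
    }
    new("PlateRender", gfp = gfp, composite = composite,
        colonies = data.frame(x = xs, y = ys, radius = radius,
                              class = classes, wedgeAngle = wedge,
                              wedgeStart = start,
                              stringsAsFactors = FALSE))
  })
}

#' Count colonies on a scanned plate image
#'
#' Binarizes the image at the given intensity threshold, labels
#' connected components (8-connectivity), discards components below the
#' minimum area, and returns the component count. Note this counts
#' bright objects in whatever channel is supplied: counting totals
#' requires a channel or composite in which all colonies exceed the
#' threshold. Touching colonies merge into one component - a documented
#' limitation of component counting.
#'
#' @param image 2D numeric matrix (a plate scan or [PlateRender-class]
#'   channel).
#' @param threshold intensity threshold within the image range.
#' @param minArea minimum component area in pixels (suppresses
#'   single-pixel noise).
#' @return Integer colony count.
#' @export
countColonies <- function(image, threshold, minArea = 20L) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  if (threshold < min(image) || threshold > max(image))
    warning("threshold lies outside the image intensity range")
  fg <- which(image > threshold)
  if (length(fg) == 0L) return(0L)
  ij <- arrayInd(fg, dim(image))
  coords <- cbind(1L, ij)  # singleton z: 26-connectivity becomes 8 in 2D
  comp <- labelComponents(coords, c(1L, dim(image)))
  sum(tabulate(comp) >= minArea)
}
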