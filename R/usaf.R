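#' Three-bar resolution-chart specification
#'
#' Standard 1951-style chart elements: the spatial frequency of group `g`,
#' element `e` is `2^(g + (e - 1) / 6)` line pairs per mm.
#'
#' @param groups Integer groups to include.
#' @param elements Elements per group (default 1:6).
#' @return Tibble `group`, `element`, `lp_mm`, `period_um` (full line-pair
#'   period, `1000 / lp_mm`).
#' @export
usaf_elements <- function(groups = 2:4, elements = 1:6) {
  gr <- rep(groups, each = length(elements))
  el <- rep(elements, times = length(groups))
  lp <- 2^(gr + (el - 1) / 6)
  tibble::tibble(group = gr, element = el, lp_mm = lp,
                 period_um = 1000 / lp)
}

#' Render a synthetic three-bar resolution chart
#'
#' Draws each element twice — three horizontal bars and three vertical bars
#' (bright bars on dark background) — on a regular grid, and records the bar
#' positions so the scorer can extract profiles without localisation.
#'
#' @param spec Element table from [usaf_elements()].
#' @param pixel_pitch Image pixel pitch, mm.
#' @param cell Cell size allotted to each element pattern, mm (default 2).
#' @return A list of class `usaf_chart`: `image` (matrix, x by y),
#'   `pixel_pitch`, and `layout` (the spec with pattern centres `cx`, `cy`
#'   per orientation).
#' @export
usaf_chart_image <- function(spec = usaf_elements(), pixel_pitch = 40 / 2048,
                             cell = 2) {
  n_el <- nrow(spec)
  ncell <- ceiling(sqrt(n_el))
  # two patterns (orientations) per element, side by side in each cell
  width <- ncell * 2 * cell
  height <- ncell * cell
  nx <- ceiling(width / pixel_pitch)
  ny <- ceiling(height / pixel_pitch)
  img <- matrix(0, nx, ny)
  xc <- (seq_len(nx) - 0.5) * pixel_pitch
  yc <- (seq_len(ny) - 0.5) * pixel_pitch
  layout <- spec
  layout$cx_h <- layout$cy_h <- layout$cx_v <- layout$cy_v <- NA_real_
  for (i in seq_len(n_el)) {
    row <- (i - 1) %/% ncell
    col <- (i - 1) %% ncell
    w <- 1 / (2 * spec$lp_mm[i])           # bar width = half period
    len <- 5 * w
    draw <- function(cx, cy, horizontal) {
      # three bars, centre-to-centre spacing 2w
      for (off in c(-2, 0, 2) * w) {
        if (horizontal) {
          xi <- which(abs(xc - cx) <= len / 2)
          yi <- which(abs(yc - (cy + off)) <= w / 2)
        } else {
          xi <- which(abs(xc - (cx + off)) <= w / 2)
          yi <- which(abs(yc - cy) <= len / 2)
        }
        img[xi, yi] <<- 1
      }
    }
    cxh <- col * 2 * cell + cell / 2
    cxv <- col * 2 * cell + 3 * cell / 2
    cy <- row * cell + cell / 2
    draw(cxh, cy, TRUE)
    draw(cxv, cy, FALSE)
    layout$cx_h[i] <- cxh; layout$cy_h[i] <- cy
    layout$cx_v[i] <- cxv; layout$cy_v[i] <- cy
  }
  structure(list(image = img, pixel_pitch = pixel_pitch, layout = layout),
            class = "usaf_chart")
}

#' Blur a chart image with a Gaussian optical point-spread function
#'
#' @param chart A [usaf_chart_image()].
#' @param fwhm_um Optical blur FWHM in micrometres.
#' @return The chart with a blurred image.
#' @export
blur_chart <- function(chart, fwhm_um) {
  sigma_px <- (fwhm_um / 1000) / (2 * sqrt(2 * log(2))) / chart$pixel_pitch
  if (sigma_px <= 0) return(chart)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  img <- chart$image
  pad <- function(m) m  # zero boundary via convolve edges
  img <- apply(img, 2, function(colv)
    stats::filter(c(rep(0, half), colv, rep(0, half)), k,
                  sides = 2)[(half + 1):(half + length(colv))])
  img <- t(apply(img, 1, function(rowv)
    stats::filter(c(rep(0, half), rowv, rep(0, half)), k,
                  sides = 2)[(half + 1):(half + length(rowv))]))
  chart$image <- img
  chart
}

# count local maxima with sufficient peak-to-valley modulation
.three_peaks <- function(profile, contrast_threshold) {
  n <- length(profile)
  if (n < 5) return(FALSE)
  is_peak <- c(FALSE, profile[2:(n - 1)] > profile[1:(n - 2)] &
                 profile[2:(n - 1)] >= profile[3:n], FALSE)
  peaks <- which(is_peak)
  # merge flat-top plateaus
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) != 3) return(FALSE)
  v1 <- min(profile[peaks[1]:peaks[2]])
  v2 <- min(profile[peaks[2]:peaks[3]])
  pk <- min(profile[peaks])
  if (pk <= 0) return(FALSE)
  (pk - max(v1, v2)) / pk >= contrast_threshold
}

#' Score the resolvability of a resolution chart image
#'
#' For every element and orientation, extracts the line profile normal to the
#' bars through the known pattern centre; the element counts as resolvable
#' when the profile shows three distinct local maxima whose peak-to-valley
#' modulation is at least `contrast_threshold` in *both* orientations.  The
#' finest resolvable element determines the reported optical resolution,
#' converted to micrometres as the full line-pair period `1000 / lp_mm`.
#'
#' @param chart A (possibly blurred) [usaf_chart_image()], or an image matrix
#'   plus `layout`/`pixel_pitch` in the same shape.
#' @param contrast_threshold Minimum peak-to-valley modulation (default 0.1).
#' @return A list of class `usaf_score`: `table` (per element: resolvable per
#'   orientation), `finest_lp_mm`, `resolution_um` (`NA` when nothing
#'   resolves).
#' @export
usaf_resolvability <- function(chart, contrast_threshold = 0.1) {
  stopifnot(inherits(chart, "usaf_chart"))
  img <- chart$image; pitch <- chart$pixel_pitch
  lay <- chart$layout
  xc <- (seq_len(nrow(img)) - 0.5) * pitch
  yc <- (seq_len(ncol(img)) - 0.5) * pitch
  res_h <- res_v <- logical(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    w <- 1 / (2 * lay$lp_mm[i])
    span <- 3.2 * w
    # horizontal bars: profile along y at x = cx_h
    xi <- which.min(abs(xc - lay$cx_h[i]))
    yi <- which(abs(yc - lay$cy_h[i]) <= span)
    res_h[i] <- .three_peaks(img[xi, yi], contrast_threshold)
    # vertical bars: profile along x at y = cy_v
    yi2 <- which.min(abs(yc - lay$cy_v[i]))
    xi2 <- which(abs(xc - lay$cx_v[i]) <= span)
    res_v[i] <- .three_peaks(img[xi2, yi2], contrast_threshold)
  }
  tab <- lay[, c("group", "element", "lp_mm", "period_um")]
  tab$resolvable_h <- res_h
  tab$resolvable_v <- res_v
  tab$resolvable <- res_h & res_v
  finest <- if (any(tab$resolvable)) max(tab$lp_mm[tab$resolvable]) else NA_real_
  structure(list(table = tab, finest_lp_mm = finest,
                 resolution_um = if (is.na(finest)) NA_real_ else 1000 / finest),
            class = "usaf_score")
}

#' @export
print.usaf_score <- function(x, ...) {
  cat(sprintf("<usaf_score> finest resolvable: %s lp/mm (%s um)\n",
              signif(x$finest_lp_mm, 4), signif(x$resolution_um, 4)))
  invisible(x)
}
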