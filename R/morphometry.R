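#' Nuclear/cytosolic intensity ratio and nuclear-filling class
#'
#' The N/C ratio is the ratio of mean fluorescence intensity inside the
#' nuclear mask to that inside the cytosolic mask. Neurons with
#' N/C ratio strictly greater than the cutoff (default 0.8) are classified
#' \code{"nucleus_filled"} (the chronic-toxicity hallmark), otherwise
#' \code{"nucleus_excluded"}.
#'
#' @param image 2-D numeric intensity matrix.
#' @param nucleus_mask,cytosol_mask logical matrices, same dimensions as
#'   \code{image}, non-empty and disjoint.
#' @param cutoff classification cutoff (default 0.8).
#' @return list with \code{nc_ratio} and \code{nuclear_class}.
#' @export
nc_ratio_and_class <- function(image, nucleus_mask, cytosol_mask,
                               cutoff = 0.8) {
  stopifnot(is.matrix(image),
            identical(dim(image), dim(nucleus_mask)),
            identical(dim(image), dim(cytosol_mask)))
  if (!any(nucleus_mask) || !any(cytosol_mask)) stop("empty mask")
  if (any(nucleus_mask & cytosol_mask)) stop("masks overlap")
  cyt <- mean(image[cytosol_mask])
  if (cyt == 0) stop("zero cytosolic mean intensity")
  ratio <- mean(image[nucleus_mask]) / cyt
  list(nc_ratio = ratio,
       nuclear_class = if (ratio > cutoff) "nucleus_filled" else "nucleus_excluded")
}

#' Soma area from a mask
#'
#' @param soma_mask logical matrix.
#' @param pixel_size um per pixel (> 0).
#' @return area in um^2 (pixel count times pixel_size^2).
#' @export
soma_area <- function(soma_mask, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!any(soma_mask)) stop("empty soma mask")
  sum(soma_mask) * pixel_size^2
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until only 1-px-wide centerlines
#' remain. Used by \code{\link{total_neurite_length}}; exported because
#' Sholl profiles are computed on the skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      del <- .zs_step(pad, step)
      if (any(del)) { pad[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  out <- pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] > 0
  out
}

# one Zhang-Suen subiteration on the padded image; returns deletion mask
.zs_step <- function(pad, step) {
  nr <- nrow(pad); nc <- ncol(pad)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  p  <- pad[ri, ci]
  # neighbours clockwise from north: p2..p9
  p2 <- pad[ri - 1, ci];     p3 <- pad[ri - 1, ci + 1]
  p4 <- pad[ri, ci + 1];     p5 <- pad[ri + 1, ci + 1]
  p6 <- pad[ri + 1, ci];     p7 <- pad[ri + 1, ci - 1]
  p8 <- pad[ri, ci - 1];     p9 <- pad[ri - 1, ci - 1]
  bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
  a <- 0
  for (i in 1:8) a <- a + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
  if (step == 0) {
    c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
  } else {
    c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
  }
  del <- p == 1 & bsum >= 2 & bsum <= 6 & a == 1 & c1 == 0 & c2 == 0
  full <- matrix(FALSE, nr, nc)
  full[ri, ci] <- del
  full
}

#' Total neurite length from a mask
#'
#' The mask is skeletonized to 1-px centerlines and the length summed over
#' adjacent skeleton-pixel steps: 1 pixel for axial neighbours, sqrt(2)
#' for diagonal neighbours (diagonal steps that shortcut an axial corner
#' are not double-counted), scaled by \code{pixel_size}.
#'
#' @param neurite_mask logical matrix.
#' @param pixel_size um per pixel.
#' @param skeletonized set TRUE if the mask already is a skeleton.
#' @return total length in um (0 with a warning for an empty mask).
#' @export
total_neurite_length <- function(neurite_mask, pixel_size,
                                 skeletonized = FALSE) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (!any(neurite_mask)) {
    warning("empty neurite mask")
    return(0)
  }
  sk <- if (skeletonized) neurite_mask else skeletonize(neurite_mask)
  nr <- nrow(sk); nc <- ncol(sk)
  z <- matrix(FALSE, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- sk
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  axial <- sum(z[ri, ci] & z[ri, ci + 1]) + sum(z[ri, ci] & z[ri + 1, ci])
  # diagonal edge counts only when the two shared axial neighbours are off
  d1 <- z[ri, ci] & z[ri + 1, ci + 1] & !(z[ri + 1, ci] & z[ri, ci + 1])
  d2 <- z[ri, ci] & z[ri + 1, ci - 1] & !(z[ri + 1, ci] & z[ri, ci - 1])
  (axial + (sum(d1) + sum(d2)) * sqrt(2)) * pixel_size
}

#' Sholl profile
#'
#' Counts neurite crossings of concentric circles around the soma centre:
#' at each radius, the skeleton pixels lying in a thin annulus (half-width
#' sqrt(2)/2 px, so no 8-connected path can step across unseen) are grouped
#' into 8-connected runs and each run counts as one intersection.
#'
#' @param skeleton logical matrix (1-px skeleton, e.g. from
#'   \code{\link{skeletonize}}).
#' @param soma_center numeric length-2, (row, col) pixel coordinates of the
#'   soma centre.
#' @param step radius step in um.
#' @param max_radius largest radius in um.
#' @param pixel_size um per pixel.
#' @return data.frame with columns \code{radius} (um) and
#'   \code{intersections}.
#' @export
sholl_profile <- function(skeleton, soma_center, step, max_radius,
                          pixel_size = 1) {
  if (step <= 0) stop("step must be positive")
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  if (soma_center[1] < 1 || soma_center[1] > nr ||
      soma_center[2] < 1 || soma_center[2] > nc) {
    stop("soma centre outside the image")
  }
  idx <- which(skeleton, arr.ind = TRUE)
  d_px <- sqrt((idx[, 1] - soma_center[1])^2 + (idx[, 2] - soma_center[2])^2)
  radii <- seq(step, max_radius, by = step)
  counts <- vapply(radii, function(r) {
    r_px <- r / pixel_size
    sel <- abs(d_px - r_px) <= sqrt(2) / 2  # guarantees any 8-connected
                                            # path through the circle is hit
    if (!any(sel)) return(0L)
    .count_components(idx[sel, , drop = FALSE])
  }, integer(1))
  data.frame(radius = radii, intersections = counts)
}

# 8-connected components among a small set of pixel coordinates
.count_components <- function(coords) {
  m <- nrow(coords)
  if (m == 0) return(0L)
  comp <- integer(m); nc <- 0L
  for (i in seq_len(m)) {
    if (comp[i] > 0) next
    nc <- nc + 1L
    queue <- i; comp[i] <- nc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      adj <- which(comp == 0 &
                   abs(coords[, 1] - coords[cur, 1]) <= 1 &
                   abs(coords[, 2] - coords[cur, 2]) <= 1)
      if (length(adj)) { comp[adj] <- nc; queue <- c(queue, adj) }
    }
  }
  nc
}

#' Image contrast index
#'
#' \deqn{C = 1 - \frac{2}{F/F_{background} + 1}.}
#' Zero when the signal equals the background, approaching 1 as
#' \eqn{F/F_{background} \to \infty}, bounded in (-1, 1).
#'
#' @param F mean signal intensity.
#' @param F_background mean background intensity (> 0).
#' @return contrast, dimensionless.
#' @export
image_contrast <- function(F, F_background) {
  if (F_background <= 0) stop("background intensity must be positive")
  1 - 2 / (F / F_background + 1)
}
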