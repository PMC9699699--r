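#' Render a synthetic neuron image with known ground truth
#'
#' Draws, on a square canvas: a soma disk of sampled area, a concentric
#' nucleus disk whose mean intensity over the cytosolic mean equals the
#' sampled N/C ratio (up to rasterization and additive noise), and a
#' random tree of straight polyline neurites whose summed Euclidean length
#' is recorded exactly as \code{truth_length}. Each primary neurite starts
#' on the soma boundary and wanders with bounded turning angles; with
#' probability 0.4 it spawns one child branch at an interior vertex.
#' Masks for nucleus, cytosol (soma minus nucleus), soma, neurites and
#' background are returned along with the truth values.
#'
#' @param morph a \code{\link{morph_preset}}.
#' @param seed integer seed (deterministic output).
#' @param canvas_px canvas side in pixels (default 512).
#' @return object of class \code{synthetic_image}: list with \code{pixels},
#'   \code{masks} (named list of logical matrices), \code{polylines}
#'   (list of n x 2 matrices, pixel coordinates), \code{truth_length} (um),
#'   \code{truth_soma_area} (um^2), \code{truth_nc_ratio},
#'   \code{soma_center} (row, col), \code{pixel_size}.
#' @export
render_neuron_image <- function(morph, seed, canvas_px = 512) {
  stopifnot(inherits(morph, "morph_preset"))
  set.seed(seed %% .Machine$integer.max)
  ps <- morph$pixel_size
  area <- max(20, stats::rnorm(1, morph$soma_area_mean, morph$soma_area_sd))
  r_soma_px <- sqrt(area / pi) / ps
  nc <- max(0.05, stats::rnorm(1, morph$nc_ratio_mean, morph$nc_ratio_sd))
  total_len <- max(20, stats::rnorm(1, morph$total_length_mean,
                                    morph$total_length_sd))
  cx <- canvas_px / 2; cy <- canvas_px / 2
  margin <- 6
  if (r_soma_px + margin > canvas_px / 2) stop("soma exceeds canvas")

  xg <- matrix(rep(seq_len(canvas_px), each = canvas_px), canvas_px)
  yg <- matrix(rep(seq_len(canvas_px), times = canvas_px), canvas_px)
  d2 <- (yg - cy)^2 + (xg - cx)^2
  soma <- d2 <= r_soma_px^2
  nucleus <- d2 <= (0.55 * r_soma_px)^2
  cytosol <- soma & !nucleus

  n_br <- sample(morph$branch_count_range[1]:morph$branch_count_range[2], 1)
  wts <- stats::rgamma(n_br, shape = 4, rate = 1)
  budgets <- total_len * wts / sum(wts)
  # primary neurites leave the soma at evenly spread, jittered angles so
  # branches rarely collide (overlapping pixels would shorten the skeleton)
  theta0 <- 2 * pi * (seq_len(n_br) - 1) / n_br + stats::runif(n_br, -0.3, 0.3)
  polylines <- list()
  truth_len <- 0
  for (b in seq_len(n_br)) {
    child_frac <- if (stats::runif(1) < 0.4) stats::runif(1, 0.25, 0.45) else 0
    main_budget <- budgets[b] * (1 - child_frac)
    start <- c(cy + r_soma_px * sin(theta0[b]), cx + r_soma_px * cos(theta0[b]))
    pl <- .wander_polyline(start, theta0[b], main_budget / ps, canvas_px, margin)
    polylines[[length(polylines) + 1]] <- pl$coords
    truth_len <- truth_len + pl$len_px * ps
    if (child_frac > 0 && nrow(pl$coords) > 2) {
      v <- sample(2:(nrow(pl$coords) - 1), 1)
      # child leaves at 45-90 degrees off the parent's local heading so it
      # cannot retrace the parent
      seg_dir <- atan2(pl$coords[v, 1] - pl$coords[v - 1, 1],
                       pl$coords[v, 2] - pl$coords[v - 1, 2])
      child_theta <- seg_dir + sample(c(-2, -1, 1, 2), 1) * pi / 4
      cpl <- .wander_polyline(pl$coords[v, ], child_theta,
                              budgets[b] * child_frac / ps, canvas_px, margin)
      polylines[[length(polylines) + 1]] <- cpl$coords
      truth_len <- truth_len + cpl$len_px * ps
    }
  }

  neurites <- matrix(FALSE, canvas_px, canvas_px)
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1)) {
      px <- .bresenham(pl[s, ], pl[s + 1, ])
      neurites[px] <- TRUE
    }
  }
  neurites <- neurites & !soma

  cyt_int <- 200
  pixels <- matrix(10, canvas_px, canvas_px)
  pixels[neurites] <- 160
  pixels[cytosol] <- cyt_int
  pixels[nucleus] <- cyt_int * nc
  pixels <- pixels + stats::rnorm(canvas_px^2, 0, 1)

  structure(list(
    pixels = pixels,
    masks = list(nucleus = nucleus, cytosol = cytosol, soma = soma,
                 neurites = neurites,
                 background = !(soma | neurites)),
    polylines = polylines,
    truth_length = truth_len,
    truth_soma_area = area,
    truth_nc_ratio = nc,
    soma_center = c(cy, cx),
    pixel_size = ps,
    seed = seed
  ), class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image>  %dx%d px @ %g um/px; soma %.0f um^2, neurites %.0f um, N/C %.2f\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$truth_soma_area, x$truth_length, x$truth_nc_ratio))
  invisible(x)
}

# Random polyline of ~len_px total length starting at `start` (row, col).
# Headings are quantized to multiples of 45 degrees and vertices to the
# pixel lattice, so the Bresenham raster of every segment has Euclidean
# length exactly equal to the recorded segment length (axial steps of 1,
# diagonal steps of sqrt(2)); the summed ground-truth length is then exact
# for the drawn skeleton. Walks are steered back toward the canvas centre
# near the border.
.wander_polyline <- function(start, theta, len_px, canvas_px, margin,
                             segment_px = 40) {
  dirs <- seq(0, 2 * pi - pi / 4, by = pi / 4)
  oct <- function(a) {  # nearest 45-degree direction index
    (round(a / (pi / 4)) %% 8) + 1
  }
  step_of <- function(k) c(sin(dirs[k]), cos(dirs[k]))
  pos <- round(start)
  coords <- matrix(pos, nrow = 1)
  k <- oct(theta)
  remaining <- len_px
  len_total <- 0
  while (remaining > 1) {
    u <- round(step_of(k))  # integer step: axial or diagonal
    unit <- if (all(u != 0)) sqrt(2) else 1
    n_steps <- max(1, min(round(segment_px / unit), floor(remaining / unit)))
    cand <- pos + n_steps * u
    if (any(cand < margin) || any(cand > canvas_px - margin)) {
      # steer back toward the centre, but never turn more than 90 degrees:
      # sharper turns let the walk run back adjacent to itself, which the
      # skeletonizer would fuse and shorten
      k_ctr <- oct(atan2(canvas_px / 2 - pos[1], canvas_px / 2 - pos[2]))
      dk <- ((k_ctr - k + 4) %% 8) - 4       # signed turn in 45-degree units
      dk <- max(-2, min(2, dk))
      k <- ((k - 1 + dk) %% 8) + 1
      u <- round(step_of(k))
      unit <- if (all(u != 0)) sqrt(2) else 1
      n_steps <- max(1, min(round(segment_px / unit), floor(remaining / unit)))
      cand <- pos + n_steps * u
      if (any(cand < margin) || any(cand > canvas_px - margin)) break
    }
    seg <- n_steps * unit
    coords <- rbind(coords, cand)
    len_total <- len_total + seg
    remaining <- remaining - seg
    pos <- cand
    k <- ((k - 1 + sample(c(-1L, 0L, 1L), 1)) %% 8) + 1
  }
  list(coords = coords, len_px = len_total)
}

# integer pixel indices (n x 2, row/col) along a segment, inclusive
.bresenham <- function(p0, p1) {
  x0 <- round(p0[2]); y0 <- round(p0[1])
  x1 <- round(p1[2]); y1 <- round(p1[1])
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  if (sx == 0) sx <- 1L
  if (sy == 0) sy <- 1L
  err <- dx - dy
  out <- matrix(0L, dx + dy + 1, 2)
  i <- 0L; x <- x0; y <- y0
  repeat {
    i <- i + 1L
    out[i, ] <- c(y, x)
    if (x == x1 && y == y1) break
    e2 <- 2 * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx)  { err <- err + dx; y <- y + sy }
  }
  out[seq_len(i), , drop = FALSE]
}
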