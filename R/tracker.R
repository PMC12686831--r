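## Classical pyramidal optic-flow (Lucas-Kanade) tracker. The SLAM core is
## tracker-agnostic: any function returning per-frame pixel positions and
## visibility for window query points satisfies the interface. This
## implementation works on lists of grayscale matrices (rows = image y,
## values in [0, 1]) and exists so the pipeline can run on real image
## sequences; synthetic scenes use the oracle tracker.

bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  if (x0 < 0 || y0 < 0 || x0 >= w - 1 || y0 >= h - 1) return(NA_real_)
  fx <- x - x0; fy <- y - y0
  (img[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
     img[y0 + 1, x0 + 2] * fx * (1 - fy) +
     img[y0 + 2, x0 + 1] * (1 - fx) * fy +
     img[y0 + 2, x0 + 2] * fx * fy)
}

halve_image <- function(img) {
  h <- 2 * (nrow(img) %/% 2); w <- 2 * (ncol(img) %/% 2)
  img <- img[1:h, 1:w]
  (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
     img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)]) / 4
}

# Track one point from image a to image b at a single pyramid level.
lk_step <- function(a, b, pt, guess, half_win = 3, iters = 12) {
  # anchor the template on the integer grid; the flow d applies to the
  # anchor and, by local constancy, to pt itself
  ax <- round(pt[1]); ay <- round(pt[2])
  xs <- ax + (-half_win:half_win)
  ys <- ay + (-half_win:half_win)
  h <- nrow(a); w <- ncol(a)
  if (min(xs) < 1 || min(ys) < 1 || max(xs) > w - 2 || max(ys) > h - 2)
    return(NULL)
  patch <- a[ys + 1, xs + 1]
  gx <- (a[ys + 1, xs + 2] - a[ys + 1, xs]) / 2
  gy <- (a[ys + 2, xs + 1] - a[ys, xs + 1]) / 2
  G <- matrix(c(sum(gx^2), sum(gx * gy), sum(gx * gy), sum(gy^2)), 2, 2)
  if (abs(det(G)) < 1e-12) return(NULL)
  Ginv <- solve(G)
  d <- guess
  # dy varies fastest so the sampled patch matrix is [row = y, col = x],
  # matching the template layout
  grid <- expand.grid(dy = -half_win:half_win, dx = -half_win:half_win)
  for (it in seq_len(iters)) {
    vals <- mapply(function(dx, dy)
      bilinear_sample(b, ax + d[1] + dx, ay + d[2] + dy),
      grid$dx, grid$dy)
    if (anyNA(vals)) return(NULL)
    diffm <- matrix(vals, 2 * half_win + 1, 2 * half_win + 1) - patch
    bvec <- c(sum(gx * diffm), sum(gy * diffm))
    step <- -as.numeric(Ginv %*% bvec)
    d <- d + step
    if (sqrt(sum(step^2)) < 0.01) break
  }
  d
}

#' Track a point between two grayscale images (pyramidal Lucas-Kanade)
#'
#' @param a,b Grayscale matrices (same size, values in `[0, 1]`).
#' @param pt Length-2 point `(x, y)` in 0-based pixel coordinates in `a`.
#' @param levels Pyramid levels (default 3).
#' @param half_win Half window size (default 3, i.e. 7 x 7 patches).
#' @return Length-2 tracked point in `b`, or `NULL` when tracking fails.
#' @export
lk_track_point <- function(a, b, pt, levels = 3, half_win = 3) {
  pyr_a <- list(a); pyr_b <- list(b)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_a[[l]])) < 4 * half_win) break
    pyr_a[[l + 1]] <- halve_image(pyr_a[[l]])
    pyr_b[[l + 1]] <- halve_image(pyr_b[[l]])
  }
  L <- length(pyr_a)
  d <- c(0, 0)
  for (l in L:1) {
    d <- d * 2
    res <- lk_step(pyr_a[[l]], pyr_b[[l]], pt / 2^(l - 1), d,
                   half_win = half_win)
    if (is.null(res)) return(NULL)
    d <- res
  }
  pt + d
}

# Gradient-magnitude corner score maxima on a coarse grid.
detect_queries <- function(img, n_points, margin = 8) {
  h <- nrow(img); w <- ncol(img)
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]
  score <- gx^2 + gy^2
  score[1:margin, ] <- 0; score[(h - margin):h, ] <- 0
  score[, 1:margin] <- 0; score[, (w - margin):w] <- 0
  cell <- max(8, floor(min(h, w) / ceiling(sqrt(n_points) * 1.5)))
  pts <- NULL
  for (cy in seq(1, h - cell, by = cell))
    for (cx in seq(1, w - cell, by = cell)) {
      block <- score[cy:(cy + cell - 1), cx:(cx + cell - 1)]
      if (max(block) <= 0) next
      ij <- which(block == max(block), arr.ind = TRUE)[1, ]
      pts <- rbind(pts, c(cx + ij[2] - 2, cy + ij[1] - 2, max(block)))
    }
  if (is.null(pts)) return(NULL)
  pts <- pts[order(-pts[, 3]), , drop = FALSE]
  pts[seq_len(min(nrow(pts), n_points)), 1:2, drop = FALSE]
}

#' Classical optic-flow tracker for image sequences
#'
#' Builds a tracker for [track_section()] over a list of grayscale
#' matrices: each window detects query points in its first frame
#' (gradient-based corner scores on a grid) and tracks them frame to
#' frame with pyramidal Lucas-Kanade; lost points are marked invisible
#' from the frame of loss onward.
#'
#' @param frames List of grayscale matrices (rows = image y).
#' @param points_per_window Queries per window.
#' @return A tracker function `tracker(frame_indices)` returning a track
#'   table; track ids are unique per (window, query).
#' @export
make_klt_tracker <- function(frames, points_per_window = 25) {
  counter <- new.env()
  counter$next_id <- 1L
  function(win) {
    img0 <- frames[[win[1] + 1]]
    q <- detect_queries(img0, points_per_window)
    if (is.null(q)) return(data.frame(track_id = integer(0),
                                      frame = integer(0), x = numeric(0),
                                      y = numeric(0), visible = logical(0)))
    ids <- counter$next_id + seq_len(nrow(q)) - 1L
    counter$next_id <- counter$next_id + nrow(q)
    rows <- data.frame(track_id = ids, frame = win[1],
                       x = q[, 1], y = q[, 2], visible = TRUE)
    cur <- lapply(seq_len(nrow(q)), function(i) q[i, ])
    alive <- rep(TRUE, nrow(q))
    for (j in seq_along(win)[-1]) {
      fa <- win[j - 1]; fb <- win[j]
      for (i in seq_len(nrow(q))) {
        if (alive[i]) {
          nxt <- lk_track_point(frames[[fa + 1]], frames[[fb + 1]],
                                cur[[i]])
          if (is.null(nxt)) alive[i] <- FALSE else cur[[i]] <- nxt
        }
        rows <- rbind(rows, data.frame(track_id = ids[i], frame = fb,
                                       x = cur[[i]][1], y = cur[[i]][2],
                                       visible = alive[i]))
      }
    }
    rows
  }
}
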