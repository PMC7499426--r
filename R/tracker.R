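# Silhouette tracking: segmentation, midline extraction (skeleton-based),
# heading and tail-angle computation.

#' Segment the larva in one frame
#'
#' Background subtraction followed by a fixed threshold at a configured
#' fraction of the frame's larva/background contrast, then connected-
#' component labelling. Exactly one component with a plausible area must
#' remain, otherwise the frame is flagged as a tracking failure.
#'
#' @param frame,background numeric image matrices of identical size.
#' @param thresh_frac threshold as a fraction of the maximal difference.
#' @param min_area,max_area plausible component area in pixels.
#' @param min_contrast minimal larva/background contrast; below it the frame
#'   is considered empty.
#' @return list with \code{mask} (logical matrix or NULL) and \code{ok}.
#' @export
segmentLarva <- function(frame, background, thresh_frac = 0.5,
                         min_area = 40, max_area = 5000,
                         min_contrast = 0.2) {
  stopifnot(all(dim(frame) == dim(background)))
  d <- frame - background
  contrast <- max(d)
  if (!is.finite(contrast) || contrast < min_contrast)
    return(list(mask = NULL, ok = FALSE))
  bw <- d > thresh_frac * contrast
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab))
  plausible <- which(tab >= min_area & tab <= max_area)
  if (length(plausible) != 1) return(list(mask = NULL, ok = FALSE))
  list(mask = matrix(as.integer(lab) == plausible, nrow(frame), ncol(frame)),
       ok = TRUE)
}

# Zhang-Suen morphological thinning; mask is a logical matrix.
# No installed package provides 2-D skeletonization, so it is implemented
# here; operates on the bounding box only.
thinMask <- function(mask) {
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  m <- pad
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nrow(x), ncol(x))
    rs <- (1 + max(0, dr)):(nrow(x) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(x) + min(0, dc))
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1); p4 <- shift(m, 0, -1)
      p5 <- shift(m, -1, -1); p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqn <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9))
      a <- rowSums(seqn[, c(1:7, 8)] == 0 & seqn[, c(2:8, 1)] == 1)
      A <- matrix(a, nrow(m), ncol(m))
      if (step == 1) {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & bsum >= 2 & bsum <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nr + 1), 2:(nc + 1)] == 1
}

# longest path through the skeleton (8-connected): double BFS
skeletonPath <- function(skel) {
  pix <- which(skel, arr.ind = TRUE)
  if (nrow(pix) < 3) return(NULL)
  key <- paste(pix[, 1], pix[, 2])
  idx <- seq_len(nrow(pix))
  names(idx) <- key
  nbr <- function(i) {
    r <- pix[i, 1]; c <- pix[i, 2]
    cand <- expand.grid(r = r + (-1):1, c = c + (-1):1)
    k <- paste(cand$r, cand$c)
    out <- idx[k]
    out <- out[!is.na(out)]
    out[out != i]
  }
  bfs <- function(start) {
    dist <- rep(NA_integer_, nrow(pix))
    parent <- rep(NA_integer_, nrow(pix))
    dist[start] <- 0L
    q <- c(start)
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in nbr(u)) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          parent[v] <- u
          q <- c(q, v)
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  b1 <- bfs(1L)
  a <- which.max(b1$dist)
  b2 <- bfs(a)
  b <- which.max(b2$dist)
  path <- b
  while (!is.na(b2$parent[path[1]])) path <- c(b2$parent[path[1]], path)
  pix[path, , drop = FALSE]
}

# resample an ordered pixel path to n points equally spaced in arc length
resamplePath <- function(path, n) {
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  tgt <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, path[, 1], xout = tgt)$y,
        stats::approx(s, path[, 2], xout = tgt)$y)
}

#' Extract the midline from a larva mask
#'
#' Skeletonizes the mask (Zhang-Suen thinning), takes the longest skeleton
#' path, identifies the head end as the end with the larger local mask width
#' (distance-transform value), resamples the path to 11 equally spaced
#' points (head plus 10 tail points to the tip) and estimates the heading as
#' the direction of the head-end segment. Pixel row/col coordinates are
#' converted to mm with the y axis flipped to mathematical convention.
#'
#' @param mask logical matrix from [segmentLarva()].
#' @param intensity optional background-subtracted intensity image; when
#'   given, head/neck/tip centroids are intensity-weighted (sub-pixel
#'   accuracy from the optical blur of the silhouette boundary).
#' @param px_per_mm pixel scale.
#' @param origin mm coordinates of the pixel grid: \code{c(x, y_top)} of
#'   pixel (1,1) (as returned by [renderFrames()]); default puts pixel (1,1)
#'   at (0, nrow/px_per_mm).
#' @param min_path_px minimal skeleton path length in pixels.
#' @return a [Midline-class], or NULL when no usable skeleton exists.
#' @export
extractMidline <- function(mask, px_per_mm, origin = NULL,
                           intensity = NULL, min_path_px = 15) {
  if (is.null(origin))
    origin <- c(x = 0, y_top = nrow(mask) / px_per_mm)
  # work on the bounding box only (thinning cost scales with image area)
  rows_in <- range(which(rowSums(mask) > 0))
  cols_in <- range(which(colSums(mask) > 0))
  r0 <- max(1, rows_in[1] - 2); c0 <- max(1, cols_in[1] - 2)
  sub <- mask[r0:min(nrow(mask), rows_in[2] + 2),
              c0:min(ncol(mask), cols_in[2] + 2), drop = FALSE]
  path <- skeletonPath(thinMask(sub))
  if (is.null(path) || nrow(path) < min_path_px) return(NULL)
  path <- cbind(path[, 1] + r0 - 1L, path[, 2] + c0 - 1L)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dmm <- matrix(as.numeric(dm), nrow(mask), ncol(mask))
  khead <- min(5, nrow(path))
  w_start <- mean(dmm[path[seq_len(khead), , drop = FALSE]])
  w_end <- mean(dmm[path[nrow(path) - seq_len(khead) + 1, , drop = FALSE]])
  if (w_end > w_start) path <- path[nrow(path):1, , drop = FALSE]
  tomm <- function(rc) cbind(origin[["x"]] + (rc[, 2] - 1) / px_per_mm,
                             origin[["y_top"]] - (rc[, 1] - 1) / px_per_mm)
  # pixel pool for sub-pixel centroids: intensity-weighted when the
  # background-subtracted image is available (optical blur carries
  # sub-pixel boundary information), otherwise the binary mask
  if (is.null(intensity)) {
    pool <- which(mask, arr.ind = TRUE)
    w <- rep(1, nrow(pool))
  } else {
    soft <- intensity > 0.05 * max(intensity)
    pool <- which(soft, arr.ind = TRUE)
    w <- intensity[pool]
  }
  poolmm <- tomm(pool)
  wcent <- function(sel) c(sum(poolmm[sel, 1] * w[sel]),
                           sum(poolmm[sel, 2] * w[sel])) / sum(w[sel])
  # head centre: weighted centroid around the mask core (widest region);
  # more stable than the skeleton end, which carries thinning artifacts
  head_xy <- colMeans(tomm(which(dmm >= 0.75 * max(dmm), arr.ind = TRUE)))
  for (it in 1:2)  # iterate: a quantized seed clips the cut asymmetrically
    head_xy <- wcent(sqrt((poolmm[, 1] - head_xy[1])^2 +
                          (poolmm[, 2] - head_xy[2])^2) < 0.34)
  # heading: rough estimate from the midline point ~0.7 mm down the neck,
  # then refined as the direction from the sub-pixel centroid of the neck
  # annulus (0.35-0.75 mm from the head centre, gated to +-55 deg around
  # the rough direction so a curled tail tip cannot contaminate it)
  allmm <- tomm(path)
  s <- c(0, cumsum(sqrt(rowSums(diff(allmm)^2))))
  neck_pt <- c(stats::approx(s, allmm[, 1], xout = min(0.9, max(s) / 3))$y,
               stats::approx(s, allmm[, 2], xout = min(0.9, max(s) / 3))$y)
  hv <- head_xy - neck_pt
  heading <- atan2(hv[2], hv[1]) * 180 / pi
  rel <- sweep(poolmm, 2, head_xy)
  rad <- sqrt(rowSums(rel^2))
  ang <- atan2(rel[, 2], rel[, 1]) * 180 / pi
  in_ann <- rad > 0.35 & rad < 1.05 &
    abs(wrapAngle(ang - (heading + 180))) < 55
  if (sum(in_ann) >= 5) {
    neck_c <- wcent(in_ann)
    hv <- head_xy - neck_c
    heading <- atan2(hv[2], hv[1]) * 180 / pi
  }
  rp <- tomm(resamplePath(path, 11))
  # sub-pixel tail tip: project the skeleton tip laterally onto a weighted
  # total-least-squares line through the distal midline pixels. Only the
  # lateral coordinate is corrected: an along-tail shift would rotate the
  # (short) head-tip chord at large bends.
  base_pt <- allmm[which.min(abs(s - (max(s) - 0.6))), ]
  seg_v <- rp[11, ] - base_pt
  seg_l <- sqrt(sum(seg_v^2))
  if (seg_l > 0.3) {
    seg_u <- seg_v / seg_l
    relb <- sweep(poolmm, 2, base_pt)
    tpar <- relb %*% seg_u
    latd <- abs(relb[, 1] * (-seg_u[2]) + relb[, 2] * seg_u[1])
    in_band <- tpar > 0 & tpar < seg_l + 0.1 & latd < 0.25
    if (sum(in_band) >= 6) {
      bw2 <- w[in_band]
      bp <- poolmm[in_band, , drop = FALSE]
      anchor <- c(sum(bp[, 1] * bw2), sum(bp[, 2] * bw2)) / sum(bw2)
      cc <- stats::cov.wt(bp, wt = bw2)$cov
      dirv <- eigen(cc, symmetric = TRUE)$vectors[, 1]
      if (sum(dirv * seg_u) < 0) dirv <- -dirv
      rp[11, ] <- anchor + dirv * sum((rp[11, ] - anchor) * dirv)
    }
  }
  new("Midline", headXY = as.numeric(head_xy), headingDeg = heading,
      tailPoints = rp[2:11, , drop = FALSE], quality = "ok")
}

#' Tail angle of a midline
#'
#' Signed angle between the straight-behind body axis (heading + 180
#' degrees) and the vector from the head to the tail tip (10th tail point):
#' 0 for a straight body, positive for bends towards the fish's left,
#' range (-180, 180].
#'
#' @param midline a [Midline-class].
#' @return angle in degrees, or NA (degenerate geometry: tip at the head).
#' @export
computeTailAngle <- function(midline) {
  tip <- midline@tailPoints[10, ]
  v <- tip - midline@headXY
  if (sqrt(sum(v^2)) < 0.1) return(NA_real_)
  back <- midline@headingDeg + 180
  wrapAngle(back - atan2(v[2], v[1]) * 180 / pi)
}

#' Track a rendered image stack
#'
#' Runs segmentation, midline extraction and the tail-angle computation on
#' every frame of a stack and assembles a trace in the generator's format,
#' with failed frames flagged. The background defaults to the pixelwise
#' median of (up to) 50 evenly spaced frames.
#'
#' @param stack a list as returned by [renderFrames()] (images, geom,
#'   origin, frames, rate), or a plain list of image matrices plus the
#'   \code{rate}, \code{px_per_mm} and \code{origin} arguments.
#' @param background optional background image.
#' @param rate,px_per_mm,origin overrides when \code{stack} is a plain list.
#' @return a [TailTrace-class] with per-frame \code{flagged} column and a
#'   \code{failure_rate} entry in its metadata.
#' @export
trackStack <- function(stack, background = NULL, rate = NULL,
                       px_per_mm = NULL, origin = NULL) {
  if (!is.null(stack$images)) {
    imgs <- stack$images
    rate <- rate %||% stack$rate
    px_per_mm <- px_per_mm %||% stack$geom$px_per_mm
    origin <- origin %||% stack$origin
    background <- background %||% stack$background
  } else imgs <- stack
  n <- length(imgs)
  if (is.null(background)) {
    sel <- unique(round(seq(1, n, length.out = min(50, n))))
    arr <- simplify2array(imgs[sel])
    background <- apply(arr, c(1, 2), stats::median)
  }
  res <- data.frame(frame = 0:(n - 1), time_s = (0:(n - 1)) / rate,
                    x_mm = NA_real_, y_mm = NA_real_,
                    heading_deg = NA_real_, tail_angle_deg = NA_real_,
                    flagged = FALSE)
  prev_head <- NULL
  for (i in seq_len(n)) {
    seg <- segmentLarva(imgs[[i]], background)
    ml <- if (seg$ok)
      extractMidline(seg$mask, px_per_mm, origin,
                     intensity = imgs[[i]] - background) else NULL
    ang <- if (!is.null(ml)) computeTailAngle(ml) else NA_real_
    if (is.null(ml) || is.na(ang)) {
      res$flagged[i] <- TRUE
      next
    }
    # temporal-continuity fallback for head/tail disambiguation
    if (!is.null(prev_head)) {
      d_head <- sqrt(sum((ml@headXY - prev_head)^2))
      d_tip <- sqrt(sum((ml@tailPoints[10, ] - prev_head)^2))
      if (d_tip < d_head - 0.5) res$flagged[i] <- TRUE
    }
    res$x_mm[i] <- ml@headXY[1]; res$y_mm[i] <- ml@headXY[2]
    res$heading_deg[i] <- ml@headingDeg
    res$tail_angle_deg[i] <- ang
    prev_head <- ml@headXY
  }
  newTailTrace(res, rate,
               meta = list(kind = "tracked",
                           failure_rate = mean(res$flagged)))
}
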