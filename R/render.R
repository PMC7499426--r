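# Rendering of larva silhouettes from a TailTrace: a bright elongated body
# on a dark background inside a circular well, with geometry chosen so the
# tracker can invert it (head disc + straight neck + constant-curvature tail
# arc whose chord reproduces the trace's tail angle).

#' Well and body geometry for rendering
#'
#' @param diameter_mm well diameter.
#' @param px_per_mm pixel scale.
#' @param head_radius_mm radius of the head blob.
#' @param neck_len_mm straight body section behind the head (keeps the local
#'   body axis at the head aligned with the heading).
#' @param tail_len_mm arc length of the bending tail section.
#' @return named list of geometry settings.
#' @export
wellGeometry <- function(diameter_mm = 15, px_per_mm = 16,
                         head_radius_mm = 0.30, neck_len_mm = 0.8,
                         bend_len_mm = 1.4, distal_len_mm = 1.1) {
  list(diameter_mm = diameter_mm, px_per_mm = px_per_mm,
       head_radius_mm = head_radius_mm, neck_len_mm = neck_len_mm,
       bend_len_mm = bend_len_mm, distal_len_mm = distal_len_mm)
}

# solve the arc turn angle phi (radians) so that the chord from the head to
# the tail tip makes the requested tail angle with the body axis.
# positive tail angle = bend to the fish's left = tip rotated clockwise
# (in math convention) from straight-behind.
solveArcTurn <- function(alpha_deg, neck, bendlen, distlen) {
  alpha <- alpha_deg * pi / 180
  tipOf <- function(phi) {
    if (abs(phi) < 1e-9) {
      c(neck + bendlen + distlen, 0)
    } else {
      R <- bendlen / phi
      c(neck + R * sin(phi), R * (1 - cos(phi))) +
        distlen * c(cos(phi), sin(phi))
    }
  }
  # local frame: body axis u along +x; model angle of the chord
  amod <- function(phi) {
    v <- tipOf(phi)
    -atan2(v[2], v[1])  # positive alpha corresponds to clockwise tip offset
  }
  if (abs(alpha) < 1e-9) return(0)
  # amod is monotone decreasing on (-lim, lim); clamp the requested angle
  # into the achievable chord range (~ +-175 deg for the default geometry)
  lim <- 3.55
  amax <- amod(-lim); amin <- amod(lim)
  alpha <- min(max(alpha, amin + 1e-6), amax - 1e-6)
  stats::uniroot(function(phi) amod(phi) - alpha,
                 lower = -lim, upper = lim, tol = 1e-8)$root
}

# body sample points (mm) for one frame: head disc centre, straight neck,
# curved tail; returns positions and half-width per sample
larvaBody <- function(x, y, heading_deg, tail_angle_deg, geom, n_samples = 160) {
  h <- heading_deg * pi / 180
  u <- c(cos(h + pi), sin(h + pi))  # straight-behind direction
  nk <- geom$neck_len_mm; bl <- geom$bend_len_mm; dl <- geom$distal_len_mm
  phi <- solveArcTurn(tail_angle_deg, nk, bl, dl)
  total <- nk + bl + dl
  s <- seq(0, total, length.out = n_samples)
  if (abs(phi) < 1e-9) {
    local_pts <- cbind(s, 0)
  } else {
    R <- bl / phi
    sb <- pmin(pmax(s - nk, 0), bl)        # arc-section arc length
    sd2 <- pmax(s - nk - bl, 0)            # distal straight section
    a <- sb / bl * phi
    local_pts <- cbind(pmin(s, nk) + R * sin(a) + sd2 * cos(a),
                       R * (1 - cos(a)) + sd2 * sin(a))
  }
  # rotate local frame (+x = u) into world coordinates
  ca <- u[1]; sa <- u[2]
  wx <- x + local_pts[, 1] * ca - local_pts[, 2] * sa
  wy <- y + local_pts[, 1] * sa + local_pts[, 2] * ca
  frac <- pmax(0, (s - nk) / (bl + dl))
  hw <- ifelse(s <= nk, 0.20, 0.20 - 0.12 * frac)
  list(x = wx, y = wy, halfwidth = hw)
}

#' Render silhouette frames from a trace
#'
#' Produces one 8-bit-style grayscale image (matrix in [0, 1], row 1 = top)
#' per trace frame: dark background, circular well boundary, bright larva.
#' The well is centred on the trace's starting position. Errors if any body
#' point leaves the well.
#'
#' @param trace a [TailTrace-class].
#' @param geom geometry from [wellGeometry()].
#' @param frames which frame indices (1-based rows of the trace) to render;
#'   default all.
#' @param noise_sd pixel noise SD (0 disables).
#' @return list with \code{images} (list of matrices), \code{geom}, and the
#'   mm coordinates of pixel (1,1) (\code{origin}) needed to invert the
#'   geometry.
#' @export
renderFrames <- function(trace, geom = wellGeometry(), frames = NULL,
                         noise_sd = 0.02) {
  fr <- traceFrames(trace)
  if (is.null(frames)) frames <- seq_len(nrow(fr))
  ppm <- geom$px_per_mm
  npx <- ceiling(geom$diameter_mm * ppm)
  cx <- fr$x_mm[1]; cy <- fr$y_mm[1]  # well centre at start position
  x0 <- cx - geom$diameter_mm / 2
  ytop <- cy + geom$diameter_mm / 2
  rwell <- geom$diameter_mm / 2
  imgs <- vector("list", length(frames))
  for (j in seq_along(frames)) {
    i <- frames[j]
    body <- larvaBody(fr$x_mm[i], fr$y_mm[i], fr$heading_deg[i],
                      fr$tail_angle_deg[i], geom)
    rr <- sqrt((body$x - cx)^2 + (body$y - cy)^2)
    if (any(rr > rwell - 0.2))
      stop("fish outside the well at frame ", fr$frame[i], call. = FALSE)
    img <- matrix(0.08, npx, npx)
    # paint the head disc plus the tapering body
    px <- c(fr$x_mm[i], body$x)
    py <- c(fr$y_mm[i], body$y)
    pr <- c(geom$head_radius_mm, body$halfwidth)
    for (b in seq_along(px)) {
      c0 <- (px[b] - x0) * ppm + 1
      r0 <- (ytop - py[b]) * ppm + 1
      rad <- pr[b] * ppm
      cols <- max(1, floor(c0 - rad)):min(npx, ceiling(c0 + rad))
      rows <- max(1, floor(r0 - rad)):min(npx, ceiling(r0 + rad))
      dd <- outer((rows - r0)^2, (cols - c0)^2, "+")
      img[rows, cols][dd <= rad^2] <- 0.90
    }
    # optical point-spread blur: gives boundary pixels partial intensity,
    # which the tracker exploits for sub-pixel localization
    img <- matrix(as.numeric(EBImage::gblur(EBImage::Image(img), sigma = 0.08 * ppm)),
                  npx, npx)
    if (noise_sd > 0)
      img <- pmin(pmax(img + matrix(stats::rnorm(npx * npx, 0, noise_sd),
                                    npx, npx), 0), 1)
    imgs[[j]] <- img
  }
  list(images = imgs, geom = geom, origin = c(x = x0, y_top = ytop),
       frames = fr$frame[frames], rate = traceRate(trace),
       background = matrix(0.08, npx, npx))
}
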