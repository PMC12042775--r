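#' Generate a synthetic filament scene
#'
#' Builds a ground-truth scene of fibrous filaments emulating immunostained
#' extracellular-matrix fibrils (fibronectin, laminin, collagen) on a cell
#' surface. Each filament is a random-walk polyline centerline with a fixed
#' half-width; the filament body is the set of points within `half_width` nm
#' of the centerline. The scene is the ground truth against which the
#' reconstruction, segmentation and colocalization stages are validated.
#'
#' @param n_filaments Number of filaments (>= 0).
#' @param field Field size in nm, `c(width, height)`. Default 25,600 nm
#'   square, the 25.6 x 25.6 um field of a 512 x 512 camera frame.
#' @param half_width Filament half-width in nm (> 0).
#' @param curvature Standard deviation (radians) of the per-step turning
#'   angle of the centerline random walk; 0 gives straight filaments.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#' @param length Centerline length per filament in nm; defaults to
#'   `0.8 * min(field)`. Long filaments (>~ the field size) bounce off the
#'   field margin and emulate fibrils spanning the whole field of view.
#' @param n_segments Number of centerline segments per filament.
#' @return An object of class `filament_scene`: a list with `field`,
#'   `filaments` (each a list with `vertices` (n x 2 matrix, nm) and
#'   `half_width`), `total_length` (nm of centerline) and `seed`.
#' @export
filament_scene <- function(n_filaments, field = c(25600, 25600),
                           half_width = 100, curvature = 0.15, seed = 1,
                           length = 0.8 * min(field), n_segments = 16) {
  if (!is_count(n_filaments)) stop_validation("n_filaments must be a nonnegative integer")
  if (length(field) != 2 || any(!is.finite(field)) || any(field <= 0))
    stop_validation("field must be two positive lengths in nm")
  if (!is.numeric(half_width) || half_width <= 0)
    stop_validation("half_width must be positive")
  if (curvature < 0) stop_validation("curvature must be >= 0")
  filaments <- with_seed(seed, {
    lapply(seq_len(n_filaments), function(i) {
      step <- length / n_segments
      margin <- half_width + 1
      v <- matrix(NA_real_, n_segments + 1L, 2L)
      v[1L, ] <- c(stats::runif(1, margin, field[1] - margin),
                   stats::runif(1, margin, field[2] - margin))
      theta <- stats::runif(1, 0, 2 * pi)
      for (k in seq_len(n_segments)) {
        theta <- theta + stats::rnorm(1, 0, curvature)
        prop <- v[k, ] + step * c(cos(theta), sin(theta))
        ## bounce off the field margin so every vertex stays inside
        tries <- 0L
        while ((prop[1] < margin || prop[1] > field[1] - margin ||
                prop[2] < margin || prop[2] > field[2] - margin) &&
               tries < 50L) {
          theta <- theta + pi / 2 + stats::rnorm(1, 0, 0.5)
          prop <- v[k, ] + step * c(cos(theta), sin(theta))
          tries <- tries + 1L
        }
        prop[1] <- min(max(prop[1], margin), field[1] - margin)
        prop[2] <- min(max(prop[2], margin), field[2] - margin)
        v[k + 1L, ] <- prop
      }
      list(vertices = v, half_width = half_width)
    })
  })
  total_length <- sum(vapply(filaments, function(f) {
    d <- diff(f$vertices)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1)))
  structure(list(field = as.numeric(field), filaments = filaments,
                 total_length = total_length, seed = seed),
            class = "filament_scene")
}

#' @export
print.filament_scene <- function(x, ...) {
  cat(sprintf("filament_scene: %d filament(s), field %.0f x %.0f nm, total centerline %.0f nm\n",
              length(x$filaments), x$field[1], x$field[2], x$total_length))
  invisible(x)
}

## Centerline segments of every filament: matrix x1,y1,x2,y2 plus per-segment
## filament index, half-width and cumulative arclength for uniform sampling.
scene_segments <- function(scene) {
  segs <- lapply(seq_along(scene$filaments), function(i) {
    v <- scene$filaments[[i]]$vertices
    if (nrow(v) < 2L) return(NULL)
    cbind(v[-nrow(v), , drop = FALSE], v[-1L, , drop = FALSE],
          i, scene$filaments[[i]]$half_width)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs)) {
    return(list(segs = NULL, length = numeric(0), cum = numeric(0)))
  }
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  list(segs = segs, length = len, cum = cumsum(len))
}

#' Exact signed distance to the true filament boundary
#'
#' Signed Euclidean distance (nm) from each query point to the edge of the
#' filament body, computed analytically from the scene geometry: distance to
#' the nearest centerline minus that filament's half-width. Negative inside a
#' filament. Exact for non-overlapping filaments; used as ground truth for
#' the segmentation-based distances.
#'
#' @param scene A `filament_scene`.
#' @param points n x 2 matrix of nm coordinates.
#' @return Numeric vector of signed distances (nm); `Inf` for an empty scene.
#' @export
scene_signed_distance <- function(scene, points) {
  points <- rbind(points)
  if (length(scene$filaments) == 0L) return(rep(Inf, nrow(points)))
  d <- rep(Inf, nrow(points))
  for (f in scene$filaments) {
    v <- f$vertices
    segs <- cbind(v[-nrow(v), , drop = FALSE], v[-1L, , drop = FALSE])
    d <- pmin(d, point_segment_distance(points, segs) - f$half_width)
  }
  d
}

#' Ground-truth binary mask of a scene
#'
#' Rasterizes the true filament body (pixels whose centers lie within the
#' half-width band of a centerline) on the reconstruction grid.
#'
#' @param scene A `filament_scene`.
#' @param pixel Pixel size in nm.
#' @return A `binary_mask` (see [binarize()]).
#' @export
scene_mask <- function(scene, pixel = 10) {
  nc <- ceiling(scene$field[1] / pixel)
  nr <- ceiling(scene$field[2] / pixel)
  xc <- (seq_len(nc) - 0.5) * pixel
  yc <- (seq_len(nr) - 0.5) * pixel
  pts <- cbind(rep(xc, each = nr), rep(yc, times = nc))
  d <- scene_signed_distance(scene, pts)
  values <- matrix(as.integer(d <= 0), nr, nc)
  new_binary_mask(values, pixel, origin = c(0, 0), threshold = NA_real_)
}

#' Blinking / localization-error model for structure fluorophores
#'
#' Describes how single-molecule localizations arise from the filament
#' scene: a per-length Poisson blinking rate, a distribution of per-spot
#' localization uncertainties, and a uniform false-localization rate.
#'
#' @param per_frame_density Expected localizations per um of filament per
#'   frame. Default 0.03.
#' @param uncertainty_law List describing the uncertainty distribution:
#'   `list(name = "lognormal", median, gsd)` (median in nm, geometric SD) or
#'   `list(name = "constant", value)`. Default lognormal, median 20 nm,
#'   geometric SD 1.4 — a typical SMLM precision scale.
#' @param false_rate False localizations per um^2 per frame. Default 5e-4.
#' @return Object of class `blink_model`.
#' @export
blink_model <- function(per_frame_density = 0.03,
                        uncertainty_law = list(name = "lognormal",
                                               median = 20, gsd = 1.4),
                        false_rate = 5e-4) {
  if (per_frame_density < 0 || false_rate < 0)
    stop_validation("rates must be >= 0")
  if (!uncertainty_law$name %in% c("lognormal", "constant"))
    stop_validation("unknown uncertainty law: %s", uncertainty_law$name)
  structure(list(per_frame_density = per_frame_density,
                 uncertainty_law = uncertainty_law,
                 false_rate = false_rate),
            class = "blink_model")
}

sample_uncertainty <- function(law, n) {
  u <- switch(law$name,
    lognormal = stats::rlnorm(n, meanlog = log(law$median), sdlog = log(law$gsd)),
    constant = rep(law$value, n))
  stopifnot(all(u > 0))
  u
}

#' Sample a localization table from a filament scene
#'
#' Emulates a dSTORM acquisition: in each frame, blinking events occur on the
#' filaments as a Poisson process uniform in arclength (transverse position
#' uniform across the filament width), each displaced by isotropic Gaussian
#' localization error with SD equal to its per-spot uncertainty; false
#' localizations occur uniformly over the field. Ground-truth labels are
#' kept in the `truth` attribute (columns `structure`, `true_x`, `true_y`).
#'
#' @param scene A `filament_scene`.
#' @param blink A `blink_model`.
#' @param n_frames Number of acquisition frames (>= 1).
#' @param seed Integer seed.
#' @param frame_rate Frames per second recorded in the table metadata.
#' @return A `loc_table` (see [loc_table()]) with a `truth` attribute.
#' @export
sample_localizations <- function(scene, blink, n_frames, seed = 1,
                                 frame_rate = 200) {
  if (!is_count(n_frames, min = 1)) stop_validation("n_frames must be >= 1")
  length_um <- scene$total_length / 1000
  area_um2 <- prod(scene$field) / 1e6
  sg <- scene_segments(scene)
  with_seed(seed, {
    n_true <- stats::rpois(n_frames, blink$per_frame_density * length_um)
    n_false <- stats::rpois(n_frames, blink$false_rate * area_um2)
    nt <- sum(n_true)
    nf <- sum(n_false)
    if (nt > 0L && !is.null(sg$segs)) {
      s <- stats::runif(nt, 0, sg$cum[length(sg$cum)])
      si <- findInterval(s, c(0, sg$cum), rightmost.closed = TRUE)
      si[si > nrow(sg$segs)] <- nrow(sg$segs)
      t0 <- (s - c(0, sg$cum)[si]) / sg$length[si]
      px <- sg$segs[si, 1] + t0 * (sg$segs[si, 3] - sg$segs[si, 1])
      py <- sg$segs[si, 2] + t0 * (sg$segs[si, 4] - sg$segs[si, 2])
      ## transverse offset uniform across the filament width
      nx <- -(sg$segs[si, 4] - sg$segs[si, 2]) / sg$length[si]
      ny <- (sg$segs[si, 3] - sg$segs[si, 1]) / sg$length[si]
      hw <- sg$segs[si, 6]
      off <- stats::runif(nt, -hw, hw)
      tx <- px + off * nx
      ty <- py + off * ny
      u_t <- sample_uncertainty(blink$uncertainty_law, nt)
      x_t <- tx + stats::rnorm(nt, 0, u_t)
      y_t <- ty + stats::rnorm(nt, 0, u_t)
      fr_t <- rep(seq_len(n_frames), n_true)
    } else {
      nt <- 0L
      x_t <- y_t <- u_t <- tx <- ty <- numeric(0)
      fr_t <- integer(0)
    }
    if (nf > 0L) {
      fx <- stats::runif(nf, 0, scene$field[1])
      fy <- stats::runif(nf, 0, scene$field[2])
      u_f <- sample_uncertainty(blink$uncertainty_law, nf)
      fr_f <- rep(seq_len(n_frames), n_false)
    } else {
      fx <- fy <- u_f <- numeric(0)
      fr_f <- integer(0)
    }
    records <- data.frame(
      frame = c(fr_t, fr_f),
      x = c(x_t, fx), y = c(y_t, fy),
      uncertainty = c(u_t, u_f),
      intensity = rep(NA_real_, nt + nf))
    ord <- order(records$frame)
    records <- records[ord, , drop = FALSE]
    truth <- data.frame(
      structure = c(rep(TRUE, nt), rep(FALSE, nf)),
      true_x = c(tx, fx), true_y = c(ty, fy))[ord, , drop = FALSE]
    rownames(records) <- rownames(truth) <- NULL
    tab <- loc_table(records,
                     meta = list(frame_rate = frame_rate,
                                 field = scene$field,
                                 source = "synthetic"))
    attr(tab, "truth") <- truth
    tab
  })
}

#' Simulate extracellular-vesicle tracks
#'
#' Generates ground-truth EV trajectories over the scene: a fraction of
#' particles is bound, constrained to stay within +/- 50 nm of a filament
#' boundary (slow diffusion with rejection of excursions out of the band);
#' the remainder diffuse freely with reflecting field edges.
#'
#' @param scene A `filament_scene`; must contain at least one filament if
#'   `fraction_bound > 0`.
#' @param n_particles Number of particles.
#' @param fraction_bound Fraction in [0, 1] of bound particles
#'   (`round(n_particles * fraction_bound)` of them).
#' @param D_free,D_bound Diffusion coefficients, um^2/s. Defaults 0.2 and
#'   0.002, the scales of free and matrix-bound membrane-proximal particles.
#' @param n_frames Frames per track.
#' @param dt Frame interval in seconds (> 0).
#' @param seed Integer seed.
#' @param bind_band Half-width (nm) of the band around the filament boundary
#'   within which bound particles stay. Default 50.
#' @return A data.frame of class `ev_tracks` with columns `track_id`,
#'   `frame`, `x`, `y` (nm), `intensity` (NA) and `bound`; attributes record
#'   the simulation parameters.
#' @export
simulate_tracks <- function(scene, n_particles, fraction_bound,
                            D_free = 0.2, D_bound = 0.002,
                            n_frames = 100, dt = 0.03, seed = 1,
                            bind_band = 50) {
  if (fraction_bound < 0 || fraction_bound > 1)
    stop_validation("fraction_bound must be in [0, 1]")
  if (dt <= 0) stop_validation("dt must be > 0")
  n_bound <- round(n_particles * fraction_bound)
  if (n_bound > 0 && length(scene$filaments) == 0L)
    stop_validation("bound particles require at least one filament")
  n_free <- n_particles - n_bound
  sd_free <- sqrt(2 * D_free * 1e6 * dt)
  sd_bound <- sqrt(2 * D_bound * 1e6 * dt)
  W <- scene$field[1]; H <- scene$field[2]
  sg <- scene_segments(scene)
  reflect <- function(x, lim) {
    x <- abs(x)
    over <- x > lim
    x[over] <- 2 * lim - x[over]
    pmin(pmax(x, 0), lim)
  }
  with_seed(seed, {
    pos_b <- NULL
    if (n_bound > 0L) {
      place <- function(k) {
        s <- stats::runif(k, 0, sg$cum[length(sg$cum)])
        si <- findInterval(s, c(0, sg$cum), rightmost.closed = TRUE)
        si[si > nrow(sg$segs)] <- nrow(sg$segs)
        t0 <- (s - c(0, sg$cum)[si]) / sg$length[si]
        px <- sg$segs[si, 1] + t0 * (sg$segs[si, 3] - sg$segs[si, 1])
        py <- sg$segs[si, 2] + t0 * (sg$segs[si, 4] - sg$segs[si, 2])
        nx <- -(sg$segs[si, 4] - sg$segs[si, 2]) / sg$length[si]
        ny <- (sg$segs[si, 3] - sg$segs[si, 1]) / sg$length[si]
        hw <- sg$segs[si, 6]
        side <- sample(c(-1, 1), k, replace = TRUE)
        d0 <- stats::runif(k, -bind_band, bind_band)
        p <- cbind(px + side * (hw + d0) * nx,
                   py + side * (hw + d0) * ny)
        p[, 1] <- pmin(pmax(p[, 1], 0), W)
        p[, 2] <- pmin(pmax(p[, 2], 0), H)
        p
      }
      pos_b <- place(n_bound)
      ## a start near one filament's edge may fall deep inside an
      ## overlapping filament: resample until the union constraint holds
      for (it in 1:100) {
        bad <- abs(scene_signed_distance(scene, pos_b)) > bind_band
        if (!any(bad)) break
        pos_b[bad, ] <- place(sum(bad))
      }
    }
    pos_f <- if (n_free > 0L) {
      cbind(stats::runif(n_free, 0, W), stats::runif(n_free, 0, H))
    } else NULL
    xs <- matrix(NA_real_, n_frames, n_particles)
    ys <- matrix(NA_real_, n_frames, n_particles)
    pos <- rbind(pos_b, pos_f)
    bound <- c(rep(TRUE, n_bound), rep(FALSE, n_free))
    if (n_particles > 0L) {
      xs[1L, ] <- pos[, 1]; ys[1L, ] <- pos[, 2]
      for (t in seq_len(n_frames - 1L)) {
        if (n_bound > 0L) {
          prop <- pos[bound, , drop = FALSE] +
            matrix(stats::rnorm(2 * n_bound, 0, sd_bound), n_bound, 2)
          d <- scene_signed_distance(scene, prop)
          ok <- abs(d) <= bind_band &
            prop[, 1] >= 0 & prop[, 1] <= W &
            prop[, 2] >= 0 & prop[, 2] <= H
          cur <- pos[bound, , drop = FALSE]
          cur[ok, ] <- prop[ok, , drop = FALSE]
          pos[bound, ] <- cur
        }
        if (n_free > 0L) {
          prop <- pos[!bound, , drop = FALSE] +
            matrix(stats::rnorm(2 * n_free, 0, sd_free), n_free, 2)
          prop[, 1] <- reflect(prop[, 1], W)
          prop[, 2] <- reflect(prop[, 2], H)
          pos[!bound, ] <- prop
        }
        xs[t + 1L, ] <- pos[, 1]; ys[t + 1L, ] <- pos[, 2]
      }
    }
    out <- data.frame(
      track_id = rep(seq_len(n_particles), each = n_frames),
      frame = rep(seq_len(n_frames), times = n_particles),
      x = as.vector(xs), y = as.vector(ys),
      intensity = rep(NA_real_, n_particles * n_frames),
      bound = rep(bound, each = n_frames))
    attr(out, "params") <- list(D_free = D_free, D_bound = D_bound,
                                dt = dt, bind_band = bind_band, seed = seed)
    class(out) <- c("ev_tracks", "data.frame")
    out
  })
}

#' Render diffraction-limited spot images
#'
#' Renders each point as a pixel-integrated 2-D Gaussian point-spread
#' function of stated integrated intensity, adds sub-threshold free-dye
#' spots and camera noise (constant background plus Gaussian read noise).
#' Ground-truth per-frame point counts are kept in the `truth` attribute.
#'
#' @param points_per_frame List (one element per frame) of n x 2 matrices of
#'   nm coordinates; points outside the field are clipped with a warning.
#' @param dim Image size in pixels, `c(nrow, ncol)`.
#' @param psf_sigma PSF Gaussian SD in nm (> 0).
#' @param pixel Pixel size in nm (> 0).
#' @param intensity Integrated intensity (counts) per rendered point.
#' @param noise `c(gaussian_sd, background_level)` camera noise model.
#' @param free_dye `list(count_per_frame, intensity)`: number and integrated
#'   intensity of free-dye spots added uniformly per frame. Default 30% of
#'   the particle intensity so a free-dye threshold is exercised.
#' @param seed Integer seed.
#' @param frame_rate Frames per second stored in the stack metadata.
#' @return A `frame_stack` (see [frame_stack()]) with a `truth` attribute
#'   listing per-frame true particle counts.
#' @export
render_spot_stack <- function(points_per_frame, dim, psf_sigma, pixel,
                              intensity = 1000,
                              noise = c(0, 0),
                              free_dye = list(count_per_frame = 0,
                                              intensity = 0.3 * intensity),
                              seed = 1, frame_rate = 30) {
  if (psf_sigma <= 0) stop_validation("psf_sigma must be > 0")
  if (pixel <= 0) stop_validation("pixel must be > 0")
  nr <- dim[1]; nc <- dim[2]
  W <- nc * pixel; H <- nr * pixel
  n_clipped <- 0L
  splat <- function(img, pts, I) {
    if (is.null(pts) || nrow(pts) == 0L) return(img)
    r <- 5 * psf_sigma
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, 1]; y <- pts[i, 2]
      c0 <- max(1L, floor((x - r) / pixel) + 1L)
      c1 <- min(nc, floor((x + r) / pixel) + 1L)
      r0 <- max(1L, floor((y - r) / pixel) + 1L)
      r1 <- min(nr, floor((y + r) / pixel) + 1L)
      if (c0 > c1 || r0 > r1) next
      ex <- ((c0 - 1L):c1) * pixel
      ey <- ((r0 - 1L):r1) * pixel
      gx <- diff(stats::pnorm(ex, x, psf_sigma))
      gy <- diff(stats::pnorm(ey, y, psf_sigma))
      img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + I * outer(gy, gx)
    }
    img
  }
  images <- with_seed(seed, {
    lapply(seq_along(points_per_frame), function(f) {
      pts <- rbind(points_per_frame[[f]])
      if (!is.null(pts) && nrow(pts) > 0L) {
        inside <- pts[, 1] >= 0 & pts[, 1] <= W & pts[, 2] >= 0 & pts[, 2] <= H
        n_clipped <<- n_clipped + sum(!inside)
        pts <- pts[inside, , drop = FALSE]
      }
      img <- matrix(noise[2], nr, nc)
      img <- splat(img, pts, intensity)
      if (free_dye$count_per_frame > 0) {
        fd <- cbind(stats::runif(free_dye$count_per_frame, 0, W),
                    stats::runif(free_dye$count_per_frame, 0, H))
        img <- splat(img, fd, free_dye$intensity)
      }
      if (noise[1] > 0) {
        img <- img + matrix(stats::rnorm(nr * nc, 0, noise[1]), nr, nc)
      }
      img
    })
  })
  if (n_clipped > 0L)
    warning(sprintf("%d point(s) outside the field were clipped", n_clipped))
  stk <- frame_stack(images, pixel = pixel, frame_rate = frame_rate)
  attr(stk, "truth") <- list(
    n_points = vapply(points_per_frame,
                      function(p) if (is.null(p)) 0L else nrow(rbind(p)),
                      integer(1)),
    n_clipped = n_clipped)
  stk
}

#' Uniform random points over a region
#'
#' Draws i.i.d. uniform points over either a rectangular field or the
#' in-structure area of a binary mask. This is the generator behind the
#' random-spot null model of the colocalization statistic.
#'
#' @param region Either `c(width, height)` in nm (rectangle anchored at the
#'   origin) or a `binary_mask` (points uniform over in-mask pixels).
#' @param n Number of points (>= 0).
#' @param seed Integer seed.
#' @return n x 2 matrix of nm coordinates.
#' @export
uniform_points <- function(region, n, seed = 1) {
  if (!is_count(n)) stop_validation("n must be a nonnegative integer")
  if (inherits(region, "binary_mask")) {
    idx <- which(region$values == 1L)
    if (length(idx) == 0L) stop_validation("empty region")
    nr <- nrow(region$values)
    with_seed(seed, {
      pick <- idx[sample.int(length(idx), n, replace = TRUE)]
      r <- ((pick - 1L) %% nr) + 1L
      cc <- ((pick - 1L) %/% nr) + 1L
      cbind(region$origin[1] + (cc - 1L + stats::runif(n)) * region$pixel,
            region$origin[2] + (r - 1L + stats::runif(n)) * region$pixel)
    })
  } else {
    if (length(region) != 2 || any(region <= 0)) stop_validation("empty region")
    with_seed(seed, cbind(stats::runif(n, 0, region[1]),
                          stats::runif(n, 0, region[2])))
  }
}
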