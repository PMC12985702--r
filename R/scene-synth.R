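#' Parameters for a synthetic endoscopic scene
#'
#' Describes one synthetic endoscopic frame: a bright circular surgical field
#' on a near-black margin, containing diffuse saturated-red bleeding plumes
#' and, optionally, two red distractor classes -- thin curvilinear vessels and
#' a speckled cancellous-bone patch. All red components are drawn with colours
#' strictly inside the red HSV bands used for weak labelling, and the tissue
#' background strictly outside them, so colour thresholding recovers the
#' component union by construction.
#'
#' @param image_size Pixels per side (square frame), at least 64.
#' @param fov_radius_frac Field-of-view radius as a fraction of the half-width,
#'   in (0, 1].
#' @param n_plumes Number of Gaussian bleeding plumes (>= 0).
#' @param plume_area_frac Target bleeding fraction of the field of view, in
#'   \[0, 1\].
#' @param vessel_on,bone_on Draw the vessel / cancellous-bone distractor.
#' @param color_jitter_sd Per-pixel colour jitter, 8-bit intensity units.
#' @param hard_edges If `TRUE` (default) component boundaries are crisp so the
#'   HSV weak label recovers the red union essentially exactly; if `FALSE` a
#'   slight Gaussian blur is applied to the rendered image (masks untouched).
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   scenes.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size = 512L, fov_radius_frac = 0.9,
                         n_plumes = 3L, plume_area_frac = 0.2,
                         vessel_on = TRUE, bone_on = TRUE,
                         color_jitter_sd = 4, hard_edges = TRUE, seed = 1L) {
  if (image_size < 64) stop("image_size must be >= 64", call. = FALSE)
  if (fov_radius_frac <= 0 || fov_radius_frac > 1)
    stop("fov_radius_frac must be in (0, 1]", call. = FALSE)
  if (plume_area_frac < 0 || plume_area_frac > 1)
    stop("plume_area_frac must be in [0, 1]", call. = FALSE)
  if (n_plumes < 0) stop("n_plumes must be >= 0", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 fov_radius_frac = fov_radius_frac,
                 n_plumes = as.integer(n_plumes),
                 plume_area_frac = plume_area_frac,
                 vessel_on = isTRUE(vessel_on), bone_on = isTRUE(bone_on),
                 color_jitter_sd = color_jitter_sd,
                 hard_edges = isTRUE(hard_edges), seed = as.integer(seed)),
            class = "scene_params")
}

#' Simulated annotator noise model
#'
#' Controls how a simulated rater's mask deviates from the truth mask:
#' a systematic over/under-segmentation (dilation/erosion), random boundary
#' jitter, and a probability of missing small bleeding components entirely.
#' With all parameters zero the rater reproduces the truth exactly.
#'
#' @param dilate_erode_px Signed integer; positive dilates, negative erodes.
#' @param boundary_jitter_sd Boundary perturbation scale in pixels. Expected
#'   Dice against the truth decreases as this grows.
#' @param miss_prob Probability that a small connected component (< 0.5% of
#'   the frame) is dropped.
#' @param seed Integer seed.
#' @return An object of class `rater_noise`.
#' @export
rater_noise <- function(dilate_erode_px = 0L, boundary_jitter_sd = 0,
                        miss_prob = 0, seed = 1L) {
  if (miss_prob < 0 || miss_prob > 1) stop("miss_prob must be in [0,1]", call. = FALSE)
  if (boundary_jitter_sd < 0) stop("boundary_jitter_sd must be >= 0", call. = FALSE)
  structure(list(dilate_erode_px = as.integer(dilate_erode_px),
                 boundary_jitter_sd = boundary_jitter_sd,
                 miss_prob = miss_prob, seed = as.integer(seed)),
            class = "rater_noise")
}

# distance-squared matrix from every pixel to a point (r0, c0)
.dist2 <- function(rows, cols, r0, c0) {
  outer((rows - r0)^2, (cols - c0)^2, "+")
}

# Rasterise a quadratic Bezier polyline of half-width `hw` pixels.
.raster_curve <- function(n, p0, p1, p2, hw) {
  t <- seq(0, 1, length.out = 4L * n)
  pts_r <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  pts_c <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  rmin <- max(1L, floor(min(pts_r) - hw - 1)); rmax <- min(n, ceiling(max(pts_r) + hw + 1))
  cmin <- max(1L, floor(min(pts_c) - hw - 1)); cmax <- min(n, ceiling(max(pts_c) + hw + 1))
  sub_r <- rmin:rmax; sub_c <- cmin:cmax
  d2 <- matrix(Inf, length(sub_r), length(sub_c))
  for (i in seq_along(t)) {
    d2 <- pmin(d2, .dist2(sub_r, sub_c, pts_r[i], pts_c[i]))
  }
  out <- matrix(FALSE, n, n)
  out[sub_r, sub_c] <- d2 <= hw^2
  out
}

# Sample per-pixel reds strictly inside the weak-label HSV bands.
# `base_v` shifts brightness between component classes.
.red_fill <- function(npix, jitter, base_v) {
  band_high <- runif(1) < 0.5
  h0 <- if (band_high) runif(1, 174.5, 177.5) else runif(1, 2.5, 5.5)
  h <- clamp(h0 + rnorm(npix, 0, 0.2 * jitter),
             if (band_high) 173.5 else 1.5,
             if (band_high) 178.5 else 6.5)
  s <- clamp(runif(1, 160, 220) + rnorm(npix, 0, jitter), 130, 250)
  v <- clamp(base_v + rnorm(npix, 0, 2 * jitter), 70, 250)
  hsv_to_rgb255(h, s, v)
}

#' Generate one synthetic endoscopic scene
#'
#' Renders a seeded synthetic frame with per-component truth masks. Plumes are
#' the union of Gaussian blobs thresholded at the exact field quantile that
#' hits `plume_area_frac` of the field of view, giving diffuse irregular
#' boundaries; vessels are quadratic Bezier polylines 2--4 px wide; bone is a
#' speckled ellipse. Component masks are pairwise disjoint (plume takes
#' precedence over vessel over bone) and contained in the field of view;
#' pixels outside the field of view are near-black.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `endo_scene`: list with `image` (H x W x 3
#'   integer array, 0--255), logical matrices `bleeding_mask`, `vessel_mask`,
#'   `bone_mask`, `fov_truth`, and `params`.
#' @export
make_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_local_seed(params$seed, .make_scene_impl(params, params$plume_area_frac))
}

.make_scene_impl <- function(params, area_frac) {
  tpl <- .scene_template(params)
  .compose_scene(tpl, area_frac)
}

# All random draws for a scene happen here, once; composition is deterministic.
.scene_template <- function(params) {
  n <- params$image_size
  ctr <- (n + 1) / 2
  R <- params$fov_radius_frac * n / 2
  rows <- seq_len(n); cols <- seq_len(n)
  d2 <- .dist2(rows, cols, ctr, ctr)
  fov <- d2 <= R^2
  jit <- params$color_jitter_sd

  # plume field: sum of Gaussian blobs with random centres inside the FOV
  field <- matrix(0, n, n)
  if (params$n_plumes > 0) {
    for (k in seq_len(params$n_plumes)) {
      rr <- 0.7 * R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
      cr <- ctr + rr * sin(th); cc <- ctr + rr * cos(th)
      sdk <- runif(1, 0.10, 0.22) * n
      amp <- runif(1, 0.6, 1)
      field <- field + amp * exp(-.dist2(rows, cols, cr, cc) / (2 * sdk^2))
    }
  }

  vessel <- matrix(FALSE, n, n)
  if (params$vessel_on) {
    for (k in 1:2) {
      ang <- runif(3, 0, 2 * pi); rad <- runif(3, 0.2, 0.85) * R
      pr <- ctr + rad * sin(ang); pc <- ctr + rad * cos(ang)
      hw <- runif(1, 1, 2)  # full width 2-4 px
      vessel <- vessel | .raster_curve(n, c(pr[1], pc[1]), c(pr[2], pc[2]),
                                       c(pr[3], pc[3]), hw)
    }
    vessel <- vessel & fov
  }

  bone <- matrix(FALSE, n, n)
  if (params$bone_on) {
    th <- runif(1, 0, 2 * pi); rr <- runif(1, 0, 0.5) * R
    cr <- ctr + rr * sin(th); cc <- ctr + rr * cos(th)
    a <- runif(1, 0.09, 0.15) * n; b <- runif(1, 0.07, 0.12) * n
    phi <- runif(1, 0, pi)
    dr <- outer(rows - cr, rep(1, n)); dc <- outer(rep(1, n), cols - cc)
    u <- dr * cos(phi) + dc * sin(phi); v <- -dr * sin(phi) + dc * cos(phi)
    ellipse <- (u / a)^2 + (v / b)^2 <= 1
    speck <- matrix(runif(n * n), n, n) < 0.55
    bone <- ellipse & speck & fov
  }

  # colour fields, sampled once so video frames share appearance
  npix <- n * n
  tis_h <- clamp(8 + rnorm(npix, 0, 0.3 * jit), 0, 20)
  tis_s <- clamp(72 + rnorm(npix, 0, 0.5 * jit), 66, 78)
  tis_v <- clamp(170 + rnorm(npix, 0, 2 * jit), 100, 230)
  tissue_rgb <- hsv_to_rgb255(tis_h, tis_s, tis_v)
  margin <- runif(npix, 3, 28)  # near-black gray, V < 50 on every channel
  plume_rgb <- .red_fill(npix, jit, base_v = runif(1, 120, 180))
  vessel_rgb <- .red_fill(npix, jit, base_v = runif(1, 80, 120))
  bone_rgb <- .red_fill(npix, jit, base_v = runif(1, 160, 220))

  list(params = params, n = n, fov = fov, field = field,
       vessel = vessel, bone = bone, tissue_rgb = tissue_rgb, margin = margin,
       plume_rgb = plume_rgb, vessel_rgb = vessel_rgb, bone_rgb = bone_rgb)
}

.plume_mask_at <- function(tpl, area_frac) {
  n_fov <- sum(tpl$fov)
  k <- round(area_frac * n_fov)
  if (k <= 0 || tpl$params$n_plumes == 0) return(matrix(FALSE, tpl$n, tpl$n))
  vals <- tpl$field[tpl$fov]
  thr <- sort(vals, decreasing = TRUE)[k]
  tpl$fov & tpl$field >= thr
}

.compose_scene <- function(tpl, area_frac) {
  n <- tpl$n
  bleeding <- .plume_mask_at(tpl, area_frac)
  vessel <- tpl$vessel & !bleeding
  bone <- tpl$bone & !bleeding & !vessel

  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    plane <- matrix(tpl$tissue_rgb[, ch], n, n)
    plane[!tpl$fov] <- tpl$margin[which(!tpl$fov)]
    plane[bleeding] <- matrix(tpl$plume_rgb[, ch], n, n)[bleeding]
    plane[vessel] <- matrix(tpl$vessel_rgb[, ch], n, n)[vessel]
    plane[bone] <- matrix(tpl$bone_rgb[, ch], n, n)[bone]
    img[, , ch] <- plane
  }
  if (!tpl$params$hard_edges) {
    for (ch in 1:3) img[, , ch] <- EBImage::gblur(img[, , ch], sigma = 1.2)
  }
  img <- array(as.integer(round(clamp(img, 0, 255))), dim = dim(img))

  scene <- structure(list(image = img, bleeding_mask = bleeding,
                          vessel_mask = vessel, bone_mask = bone,
                          fov_truth = tpl$fov, params = tpl$params),
                     class = "endo_scene")
  .validate_scene(scene)
  scene
}

.validate_scene <- function(scene) {
  with(scene, {
    stopifnot(!any(bleeding_mask & vessel_mask),
              !any(bleeding_mask & bone_mask),
              !any(vessel_mask & bone_mask),
              !any(bleeding_mask & !fov_truth),
              !any(vessel_mask & !fov_truth),
              !any(bone_mask & !fov_truth))
    if (params$hard_edges) {
      out_max <- max(image[array(rep(!fov_truth, 3), dim = dim(image))])
      stopifnot(out_max < 50)
    }
  })
  invisible(scene)
}

#' Generate a synthetic video with evolving bleeding area
#'
#' Frames share one seeded scene geometry (plume field, vessels, bone,
#' colours); only the plume threshold moves, so the bleeding area of frame
#' `t` (0-based) targets `clamp(plume_area_frac + t * growth, 0, 1)` and the
#' per-frame truth masks are nested as the area grows.
#'
#' @param params A [scene_params()] object.
#' @param n_frames Number of frames (>= 1).
#' @param growth Per-frame increment of the bleeding area fraction.
#' @return List with `frames` (list of `endo_scene`), `truth_ratio` (bleeding
#'   pixels / FOV pixels, computed by pixel count), and `fps` (nominal, 2).
#' @export
make_video <- function(params, n_frames, growth = 0) {
  stopifnot(inherits(params, "scene_params"), n_frames >= 1)
  with_local_seed(params$seed, {
    tpl <- .scene_template(params)
    frames <- vector("list", n_frames)
    truth <- numeric(n_frames)
    for (t in seq_len(n_frames)) {
      frac <- clamp(params$plume_area_frac + (t - 1) * growth, 0, 1)
      frames[[t]] <- .compose_scene(tpl, frac)
      truth[t] <- sum(frames[[t]]$bleeding_mask) / sum(tpl$fov)
    }
    list(frames = frames, truth_ratio = truth, fps = 2)
  })
}

#' Simulate an annotator's mask from a truth mask
#'
#' Applies, in order: dilation/erosion, boundary jitter (the blurred truth
#' mask plus a smooth noise field, re-thresholded at 0.5 -- perturbation is
#' confined to the boundary band so empty and solid masks are stable), and
#' random dropping of small components. All-zero noise returns the truth
#' unchanged.
#'
#' @param truth Binary truth mask (logical matrix).
#' @param noise A [rater_noise()] object.
#' @return Logical matrix, same shape as `truth`.
#' @export
make_rater_mask <- function(truth, noise) {
  stopifnot(inherits(noise, "rater_noise"))
  truth <- as_mask(truth)
  if (noise$dilate_erode_px == 0 && noise$boundary_jitter_sd == 0 &&
      noise$miss_prob == 0) return(truth)
  with_local_seed(noise$seed, {
    m <- truth * 1
    if (noise$dilate_erode_px != 0) {
      k <- 2L * abs(noise$dilate_erode_px) + 1L
      brush <- EBImage::makeBrush(k, shape = "disc")
      m <- if (noise$dilate_erode_px > 0) EBImage::dilate(m, brush)
           else EBImage::erode(m, brush)
    }
    if (noise$boundary_jitter_sd > 0) {
      f <- EBImage::gblur(m, sigma = noise$boundary_jitter_sd)
      u <- EBImage::gblur(matrix(rnorm(length(m)), nrow(m)), sigma = 2)
      u <- u / max(sd(u), 1e-12)
      band <- f > 0.02 & f < 0.98
      m <- (f + 0.25 * u * band) > 0.5
      m <- m * 1
    }
    if (noise$miss_prob > 0 && any(m > 0)) {
      lab <- EBImage::bwlabel(m)
      sizes <- tabulate(lab[lab > 0])
      small <- which(sizes < 0.005 * length(m))
      drop <- small[runif(length(small)) < noise$miss_prob]
      if (length(drop)) m[lab %in% drop] <- 0
    }
    array(m != 0, dim = dim(truth))
  })
}

#' Write a scene to disk (PNG image, PNG 0/255 masks, JSON parameter sidecar)
#'
#' @param scene An `endo_scene`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  stopifnot(inherits(scene, "endo_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             bleeding = file.path(dir, paste0(stem, "_bleeding.png")),
             vessel = file.path(dir, paste0(stem, "_vessel.png")),
             bone = file.path(dir, paste0(stem, "_bone.png")),
             fov = file.path(dir, paste0(stem, "_fov.png")),
             params = file.path(dir, paste0(stem, "_params.json")))
  png::writePNG(scene$image / 255, paths[["image"]])
  write_mask(scene$bleeding_mask, paths[["bleeding"]])
  write_mask(scene$vessel_mask, paths[["vessel"]])
  write_mask(scene$bone_mask, paths[["bone"]])
  write_mask(scene$fov_truth, paths[["fov"]])
  jsonlite::write_json(unclass(scene$params), paths[["params"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
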