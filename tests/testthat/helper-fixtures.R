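# Shared fixtures and independent oracles. Every oracle here is a direct,
# naive computation (per-pixel loops, closed forms) kept deliberately separate
# from the package's vectorised implementations.

tiny_scene <- function(seed = 1, frac = 0.3, size = 96, vessel = TRUE,
                       bone = TRUE, ...) {
  make_scene(scene_params(image_size = size, plume_area_frac = frac,
                          vessel_on = vessel, bone_on = bone, seed = seed, ...))
}

# naive per-pixel RGB(0-255) -> HSV(180/255/255) hexcone conversion
naive_hsv_pixel <- function(r, g, b) {
  r1 <- r / 255; g1 <- g / 255; b1 <- b / 255
  mx <- max(r1, g1, b1); mn <- min(r1, g1, b1); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) 0
  else if (mx == r1) ((g1 - b1) / d) %% 6
  else if (mx == g1) (b1 - r1) / d + 2
  else (r1 - g1) / d + 4
  c(h = (h * 60 / 2) %% 180, s = s * 255, v = v * 255)
}

naive_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    inter <- inter + (a[i] && b[i])
    sa <- sa + a[i]; sb <- sb + b[i]
  }
  if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
}

random_mask <- function(size, p = 0.3, seed = 1) {
  set.seed(seed)
  matrix(runif(size * size) < p, size, size)
}

# exhaustive panel-selection oracle over all subsets of size k
oracle_select <- function(dmat, k) {
  ids <- rownames(dmat)
  combos <- combn(ids, k, simplify = FALSE)
  best <- NULL; best_score <- -Inf
  for (cc in combos) {
    sub <- dmat[cc, cc]
    sc <- mean(sub[upper.tri(sub)])
    if (sc > best_score) { best_score <- sc; best <- cc }
  }
  list(selected = best, score = best_score)
}

make_panel <- function(dmat) {
  structure(list(raters = rownames(dmat), dice = dmat,
                 iou = dmat / (2 - dmat)), class = "rater_panel")
}

# quick per-pair training data for model tests
weak_pairs <- function(scenes) {
  lapply(scenes, function(s) {
    wl <- weak_label(s$image)
    list(image = s$image, mask = wl$mask)
  })
}
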