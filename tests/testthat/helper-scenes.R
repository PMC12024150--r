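## Shared fixtures: scenes are always built in code, never stored.

## a standard disk scene: radius 5 cm at 20 px/cm (analytic area pi * 25)
disk_scene <- function(seed = 7, ppcm = 20, radius_cm = 5, ...) {
  scene_spec(pixels_per_cm = ppcm,
             organism = list(shape = "disk", radius_cm = radius_cm),
             seed = seed, ...)
}

## render + full measurement chain; returns everything the stages produce
measure_scene <- function(spec, min_area_cm2 = 5) {
  sc <- render_scene(spec)
  obs <- detect_marker(sc$image, spec$marker$dictionary_name,
                       spec$marker$marker_id)
  cal <- compute_scale(obs, spec$marker$side_cm)
  mask <- binarize(sc$image)
  mask <- mask_marker_region(mask, obs)
  objs <- measure_objects(mask, cal, min_area_cm2)
  list(scene = sc, obs = obs, cal = cal, mask = mask, objects = objs)
}

## brute-force Otsu oracle: exhaustive search over all 256 candidate
## thresholds, minimizing the within-class weighted variance
otsu_bruteforce <- function(image) {
  v <- round(as.vector(image))
  best_t <- NA_integer_; best <- Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    wcv <- length(lo) * .pop_var(lo) + length(hi) * .pop_var(hi)
    if (wcv < best - 1e-9) { best <- wcv; best_t <- t }
  }
  best_t
}
.pop_var <- function(v) if (length(v) < 2L) 0 else mean((v - mean(v))^2)
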