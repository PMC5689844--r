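# Shared in-code fixtures. Everything is generated at test time; no files.

# A vent_map built directly from arrays, bypassing compute_ventilation, for
# tests that need full control over raw values.
make_vent_map <- function(raw, valid = NULL, spacing = c(1, 1, 1)) {
  if (is.null(valid)) valid <- is.finite(raw)
  structure(list(
    raw = image_volume(raw, spacing, c(0, 0, 0), "unitless"),
    normalized = NULL,
    valid_mask = valid
  ), class = "vent_map")
}

# Two cuboid "lungs" of identical size so every third has the same volume:
# left occupies x 2:5, right x 8:11, both y 3:10, z 2:13 (12 slices -> three
# 4-slice thirds) on a 12x12x14 grid.
cuboid_lungs <- function() {
  d <- c(12L, 12L, 14L)
  left <- array(FALSE, d); right <- array(FALSE, d)
  left[2:5, 3:10, 2:13] <- TRUE
  right[8:11, 3:10, 2:13] <- TRUE
  list(left = left, right = right, dim = d)
}

# Brute-force all-pairs AUC: concordant pairs count, ties worth 0.5.
auc_pairs <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# A small fast phantom for pipeline tests.
small_phantom_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(24, 24, 24), spacing = c(10, 10, 10),
               seed = seed, ...)
}
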