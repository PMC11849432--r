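# Programmatic fixtures shared across test files.

# A small slice with a square hypodense lesion inside a circular brain.
square_lesion_slice <- function(side = 40, lesion_hu = 25, bg_hu = 40,
                                lesion_rc = 15:19, lesion_cc = 8:12,
                                spacing = c(1, 1), patient = "P1",
                                index = 1L, ripple = TRUE) {
  ctr <- (side + 1) / 2
  r <- matrix(seq_len(side), side, side)
  c <- t(r)
  brain <- (((r - ctr)^2 + (c - ctr)^2) <= (0.45 * side)^2) + 0L
  lesion <- matrix(0L, side, side)
  lesion[lesion_rc, lesion_cc] <- 1L
  lesion <- lesion * brain
  img <- matrix(0, side, side)
  img[brain == 1L] <- bg_hu
  img[lesion == 1L] <- lesion_hu
  if (ripple) {
    # deterministic sub-HU texture so region variances are nonzero
    img[brain == 1L] <- img[brain == 1L] +
      0.5 * (((r + 2 * c)[brain == 1L]) %% 5)
  }
  cg_slice(img, brain, lesion, patient, index, spacing)
}

# A noisy phantom-like slice (through the real generator, small side).
small_phantom <- function(target_f, seed, side = 64) {
  cfg <- phantom_config(side = side, lesion_radius_range = c(4, 7))
  generate_phantom_slice(cfg, target_f, seed = seed)
}
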