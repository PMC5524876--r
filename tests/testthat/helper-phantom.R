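dice_coef <- function(a, b) {
  if (inherits(a, "seg_mask")) a <- a$mask
  if (inherits(b, "seg_mask")) b <- b$mask
  2 * sum(a & b) / (sum(a) + sum(b))
}

jaccard_coef <- function(a, b) {
  if (inherits(a, "seg_mask")) a <- a$mask
  if (inherits(b, "seg_mask")) b <- b$mask
  sum(a & b) / sum(a | b)
}

# phantom with measurement noise and biological heterogeneity switched off
noise_free_config <- function(seed = 1L, ...) {
  phantom_config(
    seed = seed,
    noise_sigma = c(dce = 0, dwi = 0, pet = 0),
    adc_sigma = c(background = 0, fibrous = 0, tumor = 0, fluid = 0),
    ...
  )
}

# digital sphere of radius r voxels, isotropic unit spacing unless given
digital_sphere <- function(r, spacing = c(1, 1, 1), pad = 5L) {
  n <- as.integer(2 * r / min(1, min(spacing) / max(spacing)) + 2 * pad + 1)
  n <- rep(n, 3)
  ctr <- (n - 1) / 2 * spacing
  xs <- (seq_len(n[1]) - 1) * spacing[1] - ctr[1]
  ys <- (seq_len(n[2]) - 1) * spacing[2] - ctr[2]
  zs <- (seq_len(n[3]) - 1) * spacing[3] - ctr[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  seg_mask(d2 <= (r * min(spacing))^2 + 1e-9, spacing)
}
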