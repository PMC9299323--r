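# Shared fixture builders. Everything is generated in code at test time.

# A smaller phantom for fast unit tests (160 px at 1 mm keeps the parenchyma
# ellipse above the 100 cm2 inclusion threshold).
small_phantom_spec <- function(...) {
  phantom_spec(shape_px = c(160L, 160L), spacing_mm = 1.0, ...)
}

# Run erosion + SCF + partition on a bundle the way the pipeline wires them
# (SCF windows over the organ mask, partition restricted to the eroded mask).
bundle_partition <- function(bundle, params = scf_params(), ...) {
  eroded <- erode_mask(bundle$organ_mask)
  scf <- compute_scf_map(bundle$image, bundle$organ_mask, params)
  list(scf = scf, eroded = eroded,
       partition = partition_regions(scf, eroded, ...))
}

# Hand-built partition for metric unit tests that do not need a real SCF map.
manual_partition <- function(r_h, r_s) {
  structure(
    list(r_h = r_h, r_s = r_s, eroded_mask = organ_mask(r_h | r_s),
         p10 = NA_real_, p70 = NA_real_, n_defined = sum(r_h | r_s),
         low_pct = 10, high_pct = 70, degenerate = FALSE),
    class = "region_partition"
  )
}

# Hand-built SCF map over a mask, for partition unit tests.
manual_scf_map <- function(values, mask) {
  values[!mask] <- NA_real_
  structure(
    list(values = values, window_px = 9L, params = scf_params(), mask = mask),
    class = "scf_map"
  )
}

# A ct_image of a Gaussian-blurred vertical step edge (erf profile):
# I(col) = contrast * pnorm((col - edge_col) * spacing / sigma_mm).
erf_edge_image <- function(n = 128L, spacing = 0.5, sigma_mm = 1.0,
                           contrast = 100, edge_col = n / 2 + 0.5) {
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ct_image(contrast * pnorm((cols - edge_col) * spacing / sigma_mm),
           spacing_mm = spacing, id = sprintf("erf-sigma%.2g", sigma_mm))
}
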