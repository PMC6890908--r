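# session-memoised fixtures: the template VOI sets are reused across files
.fixtures <- new.env()

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fixture_template <- function() fx("tpl", function() striatal_template())
fixture_fitted <- function() {
  fx("fq", function() build_fitted_vois(fixture_template()))
}
fixture_pentagonal <- function() {
  fx("pv", function() build_pentagonal_vois(fixture_template()))
}
fixture_masks <- function() {
  fx("masks", function() template_masks(fixture_template()))
}

# noiseless phantom with optional blur
fixture_phantom <- function(caudate = 8, anterior = 7, posterior = 7,
                            erosion = 0, asym = 1, psf = 12,
                            total_counts = Inf, seed = 1) {
  make_striatal_phantom(
    phantom_spec(caudate = caudate, anterior_putamen = anterior,
                 posterior_putamen = posterior, shape_erosion = erosion,
                 asymmetry_factor = asym, psf_fwhm_mm = psf,
                 total_counts = total_counts, seed = seed),
    fixture_template())
}

# volume holding an exact discrete power-law threshold profile inside a
# mask: counts[i] voxels at/above fraction[i] of the maximum
powerlaw_volume <- function(mask, fractions, counts, voxel_mm = 4.4) {
  stopifnot(all(diff(counts) < 0), sum(mask) >= counts[1])
  vals <- numeric(length(counts))
  f <- c(fractions, 1)
  for (i in seq_along(counts)) vals[i] <- (f[i] + f[i + 1]) / 2
  vals[length(vals)] <- 1  # the top band carries the maximum
  arr <- array(0, dim(mask))
  idx <- which(mask)
  pos <- 1
  for (i in rev(seq_along(counts))) {  # top band first
    n_band <- counts[i] - if (i < length(counts)) counts[i + 1] else 0
    arr[idx[pos:(pos + n_band - 1)]] <- vals[i]
    pos <- pos + n_band
  }
  spect_volume(arr, voxel_mm)
}

# brute-force FD oracle: explicit two-loop threshold/count computation
fd_oracle <- function(volume, mask, fractions) {
  vals <- volume$data[mask]
  mx <- max(vals)
  n <- numeric(length(fractions))
  for (i in seq_along(fractions)) {
    cnt <- 0
    for (v in vals) if (v >= fractions[i] * mx) cnt <- cnt + 1
    n[i] <- cnt
  }
  fit <- stats::lm(log(n) ~ log(fractions))
  -unname(stats::coef(fit)[2])
}

# pairwise AUC oracle with half-credit for ties
auc_oracle <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  r <- rank(pooled)
  uval <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  obs <- abs(uval(seq_len(na)) - na * length(b) / 2)
  combos <- utils::combn(n, na)
  devs <- apply(combos, 2, function(ix) abs(uval(ix) - na * length(b) / 2))
  mean(devs >= obs - 1e-9)
}
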