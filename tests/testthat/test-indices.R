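test_that("uniform volumes give SBR 0 (both schemes) and PCR 1", {
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  vol <- spect_volume(array(2, dim(fq$masks[[1]])), 4.4)
  sq <- sbr_q(vol, fq)
  expect_equal(sq$left, 0); expect_equal(sq$right, 0)
  sv <- sbr_v(vol, pv)
  expect_equal(sv$mean, 0, tolerance = 1e-12)
  expect_equal(pcr(vol, fq)$mean, 1)
})

test_that("SBR-Q recovers the closed form on an unblurred phantom", {
  # striatal mean exactly 3x occipital mean -> SBR 2
  masks <- fixture_masks()
  arr <- array(0, dim(masks$brain))
  arr[masks$brain] <- 2
  striatal <- Reduce(`|`, masks[grep("caudate|putamen", names(masks))])
  arr[striatal] <- 6
  vol <- spect_volume(arr, 4.4)
  sq <- sbr_q(vol, fixture_fitted())
  expect_equal(sq$left, 2, tolerance = 1e-12)
  expect_equal(sq$right, 2, tolerance = 1e-12)
})

test_that("SBR-V matches the Southampton algebra on unblurred phantoms", {
  k <- 6
  ph <- fixture_phantom(caudate = k, anterior = k, posterior = k, psf = 0)
  vol <- ph$volume
  v_s <- ph$truth$striatal_volume_ml[["right"]]
  sv <- sbr_v(vol, fixture_pentagonal(), v_str_ml = 11.2)
  expect_equal(sv$mean, (k - 1) * v_s / 11.2, tolerance = 1e-10)
  # with the assumed striatal volume equal to the true one, SBR = k - 1
  sv2 <- sbr_v(vol, fixture_pentagonal(), v_str_ml = v_s)
  expect_equal(sv2$mean, k - 1, tolerance = 1e-10)
})

test_that("SBR-V is blur-robust while SBR-Q is blur-sensitive", {
  ph <- fixture_phantom(caudate = 6, anterior = 6, posterior = 6, psf = 0)
  sharp <- ph$volume
  blurred <- spect_volume(gaussian_blur_3d(sharp$data, 12, 4.4), 4.4)
  pv <- fixture_pentagonal(); fq <- fixture_fitted()
  sv_sharp <- sbr_v(sharp, pv)$mean
  sv_blur <- sbr_v(blurred, pv)$mean
  expect_lt(abs(sv_blur - sv_sharp) / sv_sharp, 0.02)
  sq_sharp <- sbr_q(sharp, fq)$mean
  sq_blur <- sbr_q(blurred, fq)$mean
  expect_lt(sq_blur, 0.75 * sq_sharp)
})

test_that("PCR equals the ratio of measured VOI means", {
  ph <- fixture_phantom(caudate = 8, anterior = 5, posterior = 5)
  fq <- fixture_fitted()
  vol <- ph$volume
  ratio <- vapply(c("left", "right"), function(s) {
    put <- fq$masks[[paste0("anterior_putamen_", s)]] |
      fq$masks[[paste0("posterior_putamen_", s)]]
    voi_stats(vol, put)$mean_counts /
      voi_stats(vol, fq$masks[[paste0("caudate_", s)]])$mean_counts
  }, numeric(1))
  pc <- pcr(vol, fq)
  expect_equal(pc$left, ratio[["left"]])
  expect_equal(pc$mean, mean(ratio))
  expect_lt(pc$mean, 1)
})

test_that("asymmetry index follows its defining arithmetic", {
  expect_equal(asymmetry_index(1.5, 1.5), 0)
  expect_equal(asymmetry_index(2, 1, scale = 1), 2 / 3)
  expect_equal(asymmetry_index(2, 1, scale = 100), 200 / 3)
  expect_equal(asymmetry_index(1, 2), asymmetry_index(2, 1))
  expect_error(asymmetry_index(-1, 0.5), "positive")
})

test_that("FD recovers exact power-law profiles and the flat case", {
  pv <- fixture_pentagonal()
  prism <- pv$masks$striatal_prism_right
  counts <- c(1024, 256, 64, 16, 4)
  # N(t) = t^-2 at t = 2^-k
  f2 <- 2^-(5:1)
  vol2 <- powerlaw_volume(prism, f2, counts)
  expect_equal(as.numeric(fractal_dimension(vol2, prism, fd_config(f2))),
               2, tolerance = 1e-12)
  # N(t) = t^-4 at t = 2^(-k/2)
  f4 <- 2^-((5:1) / 2)
  vol4 <- powerlaw_volume(prism, f4, counts)
  expect_equal(as.numeric(fractal_dimension(vol4, prism, fd_config(f4))),
               4, tolerance = 1e-12)
  # threshold-independent count (binary blob) -> FD 0
  blob <- array(0, dim(prism)); blob[which(prism)[1:50]] <- 7
  expect_equal(as.numeric(fractal_dimension(spect_volume(blob, 4.4), prism)),
               0)
})

test_that("FD equals the brute-force two-loop oracle on noisy phantoms", {
  ph <- fixture_phantom(caudate = 6, anterior = 5, posterior = 5,
                        erosion = 0.4, total_counts = 1e6, seed = 5)
  pv <- fixture_pentagonal()
  cfg <- fd_config()
  for (side in c("left", "right")) {
    prism <- pv$masks[[paste0("striatal_prism_", side)]]
    expect_equal(as.numeric(fractal_dimension(ph$volume, prism, cfg)),
                 fd_oracle(ph$volume, prism, cfg$threshold_fractions),
                 tolerance = 1e-10)
  }
})

test_that("erosion toward a dot raises FD at equal compartment intensities", {
  pv <- fixture_pentagonal()
  fd_of <- function(e) {
    ph <- fixture_phantom(caudate = 6, anterior = 6, posterior = 6,
                          erosion = e)
    mean(vapply(c("left", "right"), function(s) {
      as.numeric(fractal_dimension(
        ph$volume, pv$masks[[paste0("striatal_prism_", s)]]))
    }, numeric(1)))
  }
  fds <- vapply(c(0, 0.2, 0.45), fd_of, numeric(1))
  expect_true(all(diff(fds) > 0))
  # a fully eroded caudate-only dot still scores above the intact comma
  expect_gt(fd_of(0.9), fds[1])
})

test_that("all six indices are invariant under positive rescaling", {
  ph <- fixture_phantom(caudate = 7, anterior = 6, posterior = 5,
                        erosion = 0.3, asym = 0.9, total_counts = 1e6,
                        seed = 9)
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  p1 <- compute_panel(ph$volume, fq, pv)
  scaled <- spect_volume(ph$volume$data * 3.7, 4.4)
  p2 <- compute_panel(scaled, fq, pv, subject_id = "s1")
  for (ix in c("sbr_q", "pcr_q", "ai_q", "sbr_v", "fd_v", "ai_v")) {
    expect_equal(p2[[ix]], p1[[ix]], tolerance = 1e-10, info = ix)
  }
})

test_that("left/right exchange swaps sides and preserves AI, mean SBR, FD", {
  ph <- fixture_phantom(caudate = 7, anterior = 6, posterior = 5,
                        erosion = 0.2, asym = 0.85)
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  p1 <- compute_panel(ph$volume, fq, pv)
  flipped <- spect_volume(ph$volume$data[dim(ph$volume$data)[1]:1, , ], 4.4)
  p2 <- compute_panel(flipped, fq, pv)
  expect_equal(p2$sbr_q_left, p1$sbr_q_right, tolerance = 1e-10)
  expect_equal(p2$sbr_q_right, p1$sbr_q_left, tolerance = 1e-10)
  expect_equal(p2$sbr_v_left, p1$sbr_v_right, tolerance = 1e-10)
  for (ix in c("sbr_q", "sbr_v", "ai_q", "ai_v", "fd_v")) {
    expect_equal(p2[[ix]], p1[[ix]], tolerance = 1e-10, info = ix)
  }
})

test_that("reducing striatal uptake never increases either SBR", {
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  ks <- c(8, 6, 4, 2, 1.2)
  res <- vapply(ks, function(k) {
    ph <- fixture_phantom(caudate = k, anterior = k, posterior = k)
    c(sbr_q(ph$volume, fq)$mean, sbr_v(ph$volume, pv)$mean)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) < 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("compute_panel is deterministic and compositional", {
  ph <- fixture_phantom(caudate = 7, anterior = 6, posterior = 5,
                        asym = 0.9, total_counts = 1e6, seed = 17)
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  cfg <- panel_config()
  p1 <- compute_panel(ph$volume, fq, pv, cfg)
  p2 <- compute_panel(ph$volume, fq, pv, cfg)
  expect_identical(p1, p2)
  sq <- sbr_q(ph$volume, fq)
  sv <- sbr_v(ph$volume, pv, cfg$v_str_ml)
  expect_equal(p1$sbr_q, sq$mean)
  expect_equal(p1$sbr_v, sv$mean)
  expect_equal(p1$ai_q, asymmetry_index(sq$left, sq$right, 1))
  expect_equal(p1$ai_v, asymmetry_index(sv$left, sv$right, 100))
  expect_equal(p1$pcr_q, pcr(ph$volume, fq)$mean)
})

test_that("symmetric noiseless phantoms have zero asymmetry indices", {
  ph <- fixture_phantom(asym = 1)
  p <- compute_panel(ph$volume, fixture_fitted(), fixture_pentagonal())
  expect_equal(p$ai_q, 0, tolerance = 1e-10)
  expect_equal(p$ai_v, 0, tolerance = 1e-10)
})

test_that("index preconditions are enforced", {
  fq <- fixture_fitted(); pv <- fixture_pentagonal()
  vol <- spect_volume(array(1, dim(fq$masks[[1]])), 4.4)
  expect_error(sbr_q(vol, pv), "fitted_q")
  expect_error(sbr_v(vol, fq), "pentagonal_v")
  zero <- spect_volume(array(0, dim(fq$masks[[1]])), 4.4)
  expect_error(fractal_dimension(zero, pv$masks$striatal_prism_left),
               "maximum")
  expect_error(fd_config(c(0.3, 0.4, 0.5)), "5 strictly increasing")
  expect_error(fd_config(c(0.5, 0.4, 0.45, 0.5, 0.55)))
})
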