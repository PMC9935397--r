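test_that("radial averages match analytic ring images and constants", {
  n <- 160
  x <- (1:n - (n + 1) / 2)
  r2 <- sqrt(outer(x^2, x^2, "+"))
  img <- exp(-(r2 - 45)^2 / (2 * 9))
  p <- radial_average(img, dr = 1)
  expect_equal(p$r[which.max(p$value)], 45, tolerance = 1)
  expect_lt(max(abs(p$value - exp(-(p$r - 45)^2 / 18))), 0.01)

  flat <- matrix(3.5, 64, 64)
  pf <- radial_average(flat, dr = 1)
  expect_true(all(abs(pf$value - 3.5) < 1e-9))
})

test_that("protein normalization zeroes solvent and is scale/offset invariant", {
  ms <- map_spec(solvent = 0.2)
  m <- generate_density_map(ms)
  n1 <- normalize_map_to_protein(m, c(53, 63))
  m3 <- m
  m3$data <- m$data * 3 + 1.7
  n3 <- normalize_map_to_protein(m3, c(53, 63))
  expect_equal(n3$data, n1$data, tolerance = 1e-10)
  prof <- radial_average(n1)
  expect_lt(abs(mean(prof$value[prof$r >= 0.9 * max(prof$r)])), 1e-6)

  solvent_only <- density_map(array(1, c(16, 16, 16)), 1)
  expect_error(normalize_map_to_protein(solvent_only, c(3, 5)),
               "normalization undefined")
})

test_that("slice alignment makes the contact azimuth z-independent", {
  ms <- map_spec(contact_mod = list(amplitude = 1, kappa = 20))
  m <- generate_density_map(ms)
  al <- align_slices_by_contact_sites(m)
  g <- leafletscope:::map_cyl_grids(ms$shape, ms$voxel_size)
  band <- abs(g$r - 58) < 4
  az <- vapply(seq_len(dim(al$data)[3]), function(k) {
    w <- al$data[, , k][band]
    w <- w - min(w)
    th <- g$theta[band] * pi / 180
    (atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi) %% 360
  }, numeric(1))
  dev <- abs((az - az[25] + 180) %% 360 - 180)
  expect_lt(max(dev), 2)

  # twist = 0 leaves the map unchanged
  m0 <- m
  m0$twist <- 0
  expect_equal(align_slices_by_contact_sites(m0)$data, m$data,
               tolerance = 1e-12)

  # t then -t recovers the original within interpolation error
  a1 <- align_slices_by_contact_sites(m)
  a1$twist <- -a1$twist
  a2 <- align_slices_by_contact_sites(a1)
  rms <- sqrt(mean((a2$data - m$data)^2))
  expect_lt(rms / diff(range(m$data)), 0.01)

  m_na <- m
  m_na$twist <- NA_real_
  expect_error(align_slices_by_contact_sites(m_na), "helical")
})

test_that("central projection averages the requested central slab", {
  set.seed(2)
  arr <- array(rnorm(32 * 32 * 40), c(32, 32, 40))
  m <- density_map(arr, 1)
  expect_equal(central_projection(m, 1), apply(arr, c(1, 2), mean))
  const <- density_map(array(rep(matrix(1:1024, 32), 40),
                             c(32, 32, 40)), 1)
  expect_equal(central_projection(const, 0.3), const$data[, , 1])
  # noise sd shrinks like 1/sqrt(n_slices)
  proj <- central_projection(m, 0.3)
  expect_equal(stats::sd(proj), 1 / sqrt(12), tolerance = 0.1)
  expect_error(central_projection(m, 0), "fraction")
})

test_that("line profiles see shells radially and helical pitch axially", {
  ms <- map_spec(shape = c(96, 96, 96),
                 contact_mod = list(amplitude = 2, kappa = 30))
  m <- generate_density_map(ms)
  lp <- line_profile(m, "radial_at_theta", theta = 90)
  expect_equal(lp$pos[which.max(lp$value)], 58, tolerance = 2)
  # z-constant map: flat axial profile
  m_flat <- generate_density_map(map_spec())
  la <- line_profile(m_flat, "axial_at_r_theta", r = 47.2, theta = 10)
  expect_lt(diff(range(la$value)), 1e-9)
  # helical hot spot: axial periodicity equals the pitch (51 A)
  lh <- line_profile(m, "axial_at_r_theta", r = 58, theta = 0)
  pk <- which(diff(sign(diff(lh$value))) == -2) + 1
  if (length(pk) >= 2) {
    expect_equal(mean(diff(lh$pos[pk])), 51, tolerance = 0.1)
  }
  expect_error(line_profile(m, "axial_at_r_theta", r = 500), "exits")
})

test_that("three-Gaussian fits recover an exact model and resist noise", {
  r <- seq(20, 80, 0.5)
  truth <- 1.2 * exp(-(r - 40)^2 / (2 * 4^2)) -
    0.5 * exp(-(r - 50)^2 / (2 * 5^2)) +
    0.9 * exp(-(r - 62)^2 / (2 * 3^2))
  prof <- radial_profile(r, truth)
  fit <- fit_three_gaussians(prof, window = c(25, 75))
  expect_equal(fit$mu, c(40, 50, 62), tolerance = 1e-4)
  expect_lt(max(abs(fit$mu - c(40, 50, 62))), 0.05)
  expect_equal(fit$thickness_inner, 10, tolerance = 1e-3)
  expect_equal(fit$thickness_outer, 12, tolerance = 1e-3)

  # 5% voxel noise moves the fitted centers by < 0.2 A (radial averaging
  # over the map suppresses the per-voxel noise; 20 seeds)
  ref_fit <- local({
    m <- generate_density_map(map_spec(noise_sigma = 0))
    mn <- normalize_map_to_protein(m, c(53, 63))
    fit_three_gaussians(radial_average(mn), window = c(20, 52))
  })
  for (s in 1:20) {
    m <- generate_density_map(map_spec(noise_sigma = 0.05), seed = s)
    mn <- normalize_map_to_protein(m, c(53, 63))
    fn <- fit_three_gaussians(radial_average(mn), window = c(20, 52))
    expect_lt(max(abs(fn$mu - ref_fit$mu)), 0.2)
  }

  flat <- radial_profile(r, rep(1, length(r)) + 1e-6 * r)
  expect_error(fit_three_gaussians(flat, window = c(25, 75)), "minimum|maxima")
})

test_that("leaflet areas integrate positive lobes between zero crossings", {
  r <- seq(0, 80, 0.2)
  sym <- exp(-(r - 35)^2 / 8) + exp(-(r - 55)^2 / 8) - 0.05
  pa <- leaflet_areas(radial_profile(r, sym), split = 45)
  expect_equal(pa$inner, pa$outer, tolerance = 1e-9)

  neg <- radial_profile(r, rep(-1, length(r)))
  an <- leaflet_areas(neg, split = 45)
  expect_equal(an$inner, 0)
  expect_equal(an$outer, 0)
  expect_length(an$flag, 2)

  # triangular peaks of known area: base 10, height 1 -> area 5 each side
  tri <- pmax(0, 1 - abs(r - 30) / 5) + pmax(0, 1 - abs(r - 60) / 5)
  at <- leaflet_areas(radial_profile(r, tri), split = 45)
  expect_equal(at$inner, 5, tolerance = 0.005)
  expect_equal(at$outer, 5, tolerance = 0.005)

  expect_error(leaflet_areas(radial_profile(r, sym), split = 100),
               "split radius")
})

test_that("bromine differences recover leaflet compositions and their invariances", {
  comp <- list(inner = c(SDPC = 0.5, CHOL = 0.2, POPS = 0.2, PIP2 = 0.1),
               outer = c(SDPC = 0.6, CHOL = 0.15, POPS = 0.15, PIP2 = 0.1))
  br <- c(SDPC = 12, POPS = 2, CHOL = 2, PIP2 = 4)
  ms <- map_spec()
  fam <- generate_map_family(ms, comp, br)
  res <- em_leaflet_composition(fam, br, protein_r_range = c(53, 63),
                                fit_window = c(20, 52), mode = "bulk")
  truth <- c(50, 20, 20, 10, 60, 15, 15, 10)
  expect_lt(max(abs(res$composition$molar_percent - truth)), 2)
  sums <- tapply(res$composition$molar_percent,
                 res$composition$leaflet, sum)
  expect_equal(as.numeric(sums[c("inner", "outer")]), c(100, 100),
               tolerance = 1e-6)

  # doubling all bromine amplitudes leaves percentages unchanged
  ms2 <- map_spec(bromine_unit = 2 * ms$bromine_unit)
  fam2 <- generate_map_family(ms2, comp, br)
  res2 <- em_leaflet_composition(fam2, br, protein_r_range = c(53, 63),
                                 fit_window = c(20, 52), mode = "bulk")
  expect_equal(res2$composition$molar_percent,
               res$composition$molar_percent, tolerance = 0.02)

  # brominated profiles identical to the reference: undefined composition
  prof <- radial_profile(seq(0, 80, 0.5),
                         exp(-(seq(0, 80, 0.5) - 30)^2 / 8) +
                           exp(-(seq(0, 80, 0.5) - 47)^2 / 8))
  expect_error(bromine_composition(list(reference = prof, SDPC = prof),
                                   br, split = 38),
               "composition undefined")
  expect_error(bromine_composition(list(reference = prof, SDPC = prof),
                                   c(SDPC = 0), split = 38),
               "br_atoms")
})

test_that("gain and offset on the input maps do not change EM results", {
  comp <- list(inner = c(SDPC = 0.55, CHOL = 0.25, POPS = 0.1, PIP2 = 0.1),
               outer = c(SDPC = 0.55, CHOL = 0.25, POPS = 0.1, PIP2 = 0.1))
  br <- c(SDPC = 12, POPS = 2, CHOL = 2, PIP2 = 4)
  fam <- generate_map_family(map_spec(), comp, br)
  fam_t <- lapply(fam, function(m) { m$data <- 2.5 * m$data - 0.4; m })
  r1 <- em_leaflet_composition(fam, br, c(53, 63), c(20, 52), mode = "bulk")
  r2 <- em_leaflet_composition(fam_t, br, c(53, 63), c(20, 52),
                               mode = "bulk")
  expect_equal(r2$composition$molar_percent, r1$composition$molar_percent,
               tolerance = 1e-6)
  expect_equal(r2$thickness$mu, r1$thickness$mu, tolerance = 1e-6)
})

test_that("half-map analyses report means and between-half deviations", {
  a <- data.frame(leaflet = "inner", species = c("A", "B"),
                  molar_percent = c(10, 90))
  b <- data.frame(leaflet = "inner", species = c("A", "B"),
                  molar_percent = c(14, 86))
  u <- halfmap_uncertainty(a, b)
  expect_equal(u$molar_percent_mean, c(12, 88))
  expect_equal(u$molar_percent_sd, c(sqrt(8), sqrt(8)))
  # symmetric under argument swap
  u2 <- halfmap_uncertainty(b, a)
  expect_equal(u2$molar_percent_sd, u$molar_percent_sd)
  # identical halves give zero sd
  u3 <- halfmap_uncertainty(a, a)
  expect_equal(u3$molar_percent_sd, c(0, 0))
  expect_error(halfmap_uncertainty(a, a[1, ]), "mismatched")
})
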