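test_that("baselines are pixelwise temporal means and flag nonpositive pixels", {
  st <- channel_stack(array(100, c(2, 2, 5)), 525, 0.1)
  expect_equal(as.vector(compute_baseline(st)), rep(100, 4))
  st2 <- channel_stack(array(rep(c(90, 110), each = 4), c(2, 2, 2)), 525, 0.1)
  expect_equal(as.vector(compute_baseline(st2)), rep(100, 4))
  bad <- array(100, c(2, 2, 2)); bad[1, 1, ] <- 0
  expect_warning(b <- compute_baseline(channel_stack(bad, 525, 0.1)),
                 "nonpositive baseline")
  expect_false(attr(b, "valid")[1, 1])
  expect_true(all(attr(b, "valid")[-1]))
})

test_that("solver constants match the hand-derived explicit solution", {
  b <- matrix(10, 2, 2)
  k <- precompute_constants(toy_eps(), unit_paths(), b, b)
  # hand arithmetic on the toy matrix [[1,2],[3,4]]
  expect_equal(k$c525_hbo, 2.0)
  expect_equal(k$c625_hbo, 1.0)
  expect_equal(k$c525_hbr, -1.5)
  expect_equal(k$c625_hbr, -0.5)
  # a0 = c625*log10(I0_625) - c525*log10(I0_525) = (1 - 2)*log10(10) = -1
  expect_equal(k$a0_hbo, matrix(-1, 2, 2), ignore_attr = TRUE)
})

test_that("scaling all extinction coefficients by k scales the constants by 1/k", {
  b <- matrix(10, 2, 2)
  k1 <- precompute_constants(toy_eps(), unit_paths(), b, b)
  eps10 <- extinction_table(c(525, 625), c(10, 30), c(20, 40))
  k10 <- precompute_constants(eps10, unit_paths(), b, b)
  for (f in c("c525_hbo", "c625_hbo", "c525_hbr", "c625_hbr"))
    expect_equal(k10[[f]], k1[[f]] / 10)
})

test_that("proportional extinction rows raise a degeneracy error", {
  eps <- extinction_table(c(525, 625), c(1, 2), c(2, 4))  # row2 = 2*row1
  b <- matrix(10, 2, 2)
  expect_error(precompute_constants(eps, unit_paths(), b, b), "degenerate")
  expect_error(solve_bruteforce(1, 1, eps), "degenerate")
})

test_that("intensities at baseline give identically zero concentration changes", {
  i0 <- matrix(c(200, 300, 400, 500), 2, 2)
  st <- function(nm) channel_stack(array(rep(i0, 6), c(2, 2, 6)), nm, 0.1)
  k <- precompute_constants(toy_eps(), unit_paths(),
                            compute_baseline(st(525)), compute_baseline(st(625)))
  m <- estimate_hemodynamics(st(525), st(625), k)
  expect_equal(max(abs(m$hbo)), 0, tolerance = 1e-12)
  expect_equal(max(abs(m$hbr)), 0, tolerance = 1e-12)
  expect_identical(m$hbt, m$hbo + m$hbr)
})

test_that("a unit optical-density step inverts the toy 2x2 system by hand", {
  # dOD = 1 at both wavelengths, X = 1: I = I0 * 10^-1
  i0 <- matrix(100, 1, 1)
  s525 <- channel_stack(array(c(100, 10), c(1, 1, 2)), 525, 0.1)
  s625 <- channel_stack(array(c(100, 10), c(1, 1, 2)), 625, 0.1)
  b <- matrix(100, 1, 1)
  k <- precompute_constants(toy_eps(), unit_paths(), b, b)
  m <- estimate_hemodynamics(s525, s625, k)
  expect_equal(m$hbo[1, 1, 2], -1)   # [[1,2],[3,4]] x = (1,1) -> (-1, 1)
  expect_equal(m$hbr[1, 1, 2], 1)
  o <- solve_bruteforce(1, 1, toy_eps())
  expect_equal(o$hbo, -1)
  expect_equal(o$hbr, 1)
  expect_equal(unlist(solve_bruteforce(0, 0, toy_eps())), c(hbo = 0, hbr = 0))
})

test_that("explicit-constant solver matches the per-sample linear-solve oracle", {
  set.seed(42)
  n <- 2000
  eps <- default_extinction_table()
  paths <- pathlength_set()
  dod525 <- runif(n, -0.05, 0.05)  # cm^-1, spans realistic transients
  dod625 <- runif(n, -0.05, 0.05)
  oracle <- solve_bruteforce(dod525, dod625, eps)
  # route the same dODs through the explicit-constant path as intensities
  i0 <- 1000
  i525 <- channel_stack(array(i0 * 10^(-paths$x525 * dod525), c(1, 1, n)), 525, 0.1)
  i625 <- channel_stack(array(i0 * 10^(-paths$x625 * dod625), c(1, 1, n)), 625, 0.1)
  b <- matrix(i0, 1, 1)
  k <- precompute_constants(eps, paths, b, b)
  m <- estimate_hemodynamics(i525, i625, k)
  scale <- max(abs(unlist(oracle)))
  expect_lt(max(abs(as.vector(m$hbo) - oracle$hbo)) / scale, 1e-10)
  expect_lt(max(abs(as.vector(m$hbr) - oracle$hbr)) / scale, 1e-10)
})

test_that("forward-model scenes invert to ground truth", {
  sc <- small_scene()
  ch <- demultiplex(sc$acq)
  k <- precompute_constants(default_extinction_table(), pathlength_set(),
                            scene_baseline(sc, "525"), scene_baseline(sc, "625"))
  m <- estimate_hemodynamics(ch[["525"]], ch[["625"]], k)
  scale <- max(abs(sc$truth$hbo))
  expect_lt(max(abs(m$hbo - sc$truth$hbo)) / scale, 1e-10)
  expect_lt(max(abs(m$hbr - sc$truth$hbr)) / scale, 1e-10)
  expect_identical(m$hbt, m$hbo + m$hbr)
})

test_that("with a full-record mean baseline, small transients average to ~zero", {
  # |dOD| stays below 1e-3 so the log-domain mean approximation holds
  n <- 50
  tcv <- sin(2 * pi * seq_len(n) / n)  # integer number of periods
  sc <- generate_scene(scene_params(height = 4, width = 4, n_cycles = n,
                                    hbo_amp_m = 1e-8, hbr_amp_m = -4e-9,
                                    hbo_tc = 1e-8 * tcv, hbr_tc = -4e-9 * tcv),
                       seed = 3)
  ch <- demultiplex(sc$acq)
  k <- precompute_constants(default_extinction_table(), pathlength_set(),
                            compute_baseline(ch[["525"]]),
                            compute_baseline(ch[["625"]]))
  m <- estimate_hemodynamics(ch[["525"]], ch[["625"]], k)
  expect_lt(max(abs(apply(m$hbo, c(1, 2), mean))), 1e-6)
  expect_lt(max(abs(apply(m$hbr, c(1, 2), mean))), 1e-6)
})

test_that("a constant gain on one channel leaves the maps unchanged", {
  sc <- small_scene()
  ch <- demultiplex(sc$acq)
  eps <- default_extinction_table(); paths <- pathlength_set()
  run <- function(ch525) {
    k <- precompute_constants(eps, paths,
                              compute_baseline(ch525, sc$truth$baseline_cycles),
                              scene_baseline(sc, "625"))
    estimate_hemodynamics(ch525, ch[["625"]], k)
  }
  m1 <- run(ch[["525"]])
  gained <- ch[["525"]]; gained$data <- gained$data * 3.7
  m2 <- run(gained)
  expect_equal(m2$hbo, m1$hbo, tolerance = 1e-10)
  expect_equal(m2$hbr, m1$hbr, tolerance = 1e-10)
})

test_that("nonpositive intensities at valid pixels are masked with a warning", {
  i0 <- matrix(100, 2, 2)
  a525 <- array(100, c(2, 2, 3)); a525[1, 1, 2] <- 0
  s525 <- channel_stack(a525, 525, 0.1)
  s625 <- channel_stack(array(100, c(2, 2, 3)), 625, 0.1)
  b <- matrix(100, 2, 2)
  k <- precompute_constants(toy_eps(), unit_paths(), b, b)
  expect_warning(m <- estimate_hemodynamics(s525, s625, k), "nonpositive")
  expect_true(all(is.na(m$hbo[1, 1, ])))
  expect_false(anyNA(m$hbo[2, , ]))
})

test_that("mismatched stack shapes are a dimension error", {
  b <- matrix(100, 2, 2)
  k <- precompute_constants(toy_eps(), unit_paths(), b, b)
  s525 <- channel_stack(array(100, c(2, 2, 3)), 525, 0.1)
  s625 <- channel_stack(array(100, c(2, 2, 4)), 625, 0.1)
  expect_error(estimate_hemodynamics(s525, s625, k), "differ in shape")
})
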