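test_that("Poisson-model threshold separates two populations", {
  # two-value image: any valid separator lies strictly between the modes
  x <- matrix(c(rep(10, 50), rep(100, 50)), 10, 10)
  thr <- poisson_threshold(x)
  expect_gt(thr, 10); expect_lt(thr, 100)

  # mixture of two Poisson populations: near-optimal misclassification
  set.seed(42)
  v <- c(rpois(1e4, 5), rpois(1e4, 50))
  truth <- rep(c(FALSE, TRUE), each = 1e4)
  thr2 <- poisson_threshold(v)
  mis <- mean((v > thr2) != truth)
  expect_lte(mis, 0.02)
  # exhaustive scan over all candidate thresholds as oracle
  cand <- seq(min(v), max(v))
  best <- min(vapply(cand, function(t) mean((v > t) != truth), numeric(1)))
  expect_lte(mis, best + 0.02)

  expect_error(poisson_threshold(matrix(3, 4, 4)), "constant")
  # binarization is unchanged under the identity scaling
  expect_identical(v > poisson_threshold(v * 1), v > thr2)
})

test_that("adaptive mask recovers a clean object footprint", {
  sc <- make_object(shape = c(250L, 250L), phase_pattern = "none",
                    seed = 7)
  img <- 1 - sc$amplitude          # object bright on dark
  m <- adaptive_mask(img)
  expect_gte(jaccard(m, sc$amp_footprint), 0.95)
  expect_false(attr(m, "degenerate"))
  # deterministic: identical input, bit-identical mask
  expect_identical(m, adaptive_mask(img))
  # polarity auto matches the dark-object reading of the raw amplitude
  m2 <- adaptive_mask(sc$amplitude)
  expect_gte(jaccard(m2, sc$amp_footprint), 0.95)
})

test_that("salt-and-pepper speckle is removed by the morphological cascade", {
  sc <- make_object(shape = c(250L, 250L), phase_pattern = "none",
                    seed = 7)
  img <- 1 - sc$amplitude
  clean_mask <- adaptive_mask(img)
  set.seed(123)
  speckle_idx <- sample(which(img < 0.5), round(0.005 * length(img)))
  noisy <- img
  noisy[speckle_idx] <- 1
  noisy_mask <- adaptive_mask(noisy)
  # isolated speckle pixels (not adjacent to the object) must be absent
  iso <- setdiff(speckle_idx, which(dilate(clean_mask, disk_se(2))))
  expect_false(any(noisy_mask[iso]))
  expect_gte(jaccard(noisy_mask, clean_mask), 0.95)
})

test_that("degenerate images give an empty flagged mask with a warning", {
  flat <- matrix(0.5, 64, 64)
  expect_warning(m <- adaptive_mask(flat), "degenerate|empty")
  expect_false(any(m))
  expect_true(attr(m, "degenerate"))
})

unclass_strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }

test_that("constraint state handles pure-amplitude objects and global phase", {
  sc <- make_object(shape = c(250L, 250L), phase_pattern = "none",
                    seed = 7)
  expect_warning(st <- constraint_state(sc$field), "degenerate|empty|object")
  expect_true(st$phase_degenerate)
  expect_false(any(st$phase_mask))
  expect_gte(jaccard(st$amp_mask, sc$amp_footprint), 0.9)
  # a global unit-modulus factor does not change the masks
  f2 <- complex_field(sc$field$values * exp(0.4i), sc$pitch, sc$wavelength)
  expect_warning(st2 <- constraint_state(f2))
  expect_identical(st$amp_mask, st2$amp_mask)
  expect_identical(unclass_strip(st$phase_mask), unclass_strip(st2$phase_mask))
})

test_that("complex objects give distinct amplitude and phase masks", {
  sc <- make_object(shape = c(250L, 250L), seed = 7)   # letters amp+phase
  st <- constraint_state(sc$field)
  expect_false(identical(st$amp_mask, st$phase_mask))
  expect_gte(jaccard(st$amp_mask, sc$amp_footprint), 0.85)
  expect_gte(jaccard(st$phase_mask, sc$phase_footprint), 0.85)
})

test_that("constraint application follows the stated elementwise rules", {
  set.seed(8)
  n <- 16L
  v <- matrix(complex(modulus = runif(n * n, 0.2, 1.5),
                      argument = runif(n * n, -1, 1),
                      length.out = n * n), n, n)
  f <- complex_field(v, 5.86e-6, 500e-9)
  all_true <- matrix(TRUE, n, n)
  st_true <- constraint_from_mask(all_true, background_amplitude = 0.7)
  # all-true masks: identity under both modes (hadamard exactly)
  expect_identical(apply_constraint(f, st_true, "hadamard")$values |>
                     Mod(), Mod(v))
  expect_lt(rel_err(apply_constraint(f, st_true, "background_fill")$values,
                    v), 1e-12)
  # all-false masks with unit background: unit plane wave
  st_false <- constraint_from_mask(!all_true, background_amplitude = 1)
  out <- apply_constraint(f, st_false, "background_fill")
  expect_equal(out$values, matrix(1 + 0i, n, n), tolerance = 1e-12)
  # checkerboard masks: hand-evaluated formula
  cb <- (row(v) + col(v)) %% 2L == 0L
  st_cb <- structure(list(amp_mask = cb, phase_mask = !cb,
                          background_amplitude = 0.5,
                          amp_degenerate = FALSE, phase_degenerate = FALSE),
                     class = "constraint_state")
  got <- apply_constraint(f, st_cb, "background_fill")$values
  want_amp <- Mod(v) * cb + 0.5 * !cb
  want_ph <- Arg(v) * !cb
  expect_equal(Mod(got), want_amp, tolerance = 1e-12)
  expect_equal(Arg(got), want_ph, tolerance = 1e-12)
  got_h <- apply_constraint(f, st_cb, "hadamard")$values
  expect_equal(Mod(got_h), Mod(v) * cb, tolerance = 1e-12)
  # shape mismatch is rejected
  small <- complex_field(v[1:8, 1:8], 5.86e-6, 500e-9)
  expect_error(apply_constraint(small, st_cb), "shape|mask")
})

test_that("static aperture masks have the right geometry", {
  m <- support_mask(c(10, 12), "rect", bounds = c(1, 10, 1, 12))
  expect_true(all(m))
  m0 <- support_mask(c(21, 21), "circle", center = c(11, 11), radius = 0)
  expect_equal(sum(m0), 1L)
  expect_true(m0[11, 11])
  for (r in c(5, 9, 20)) {
    mc <- support_mask(c(64, 64), "circle", center = c(32, 32), radius = r)
    expect_lte(abs(sum(mc) - pi * r^2), 4 * r + 4)
  }
  expect_error(support_mask(c(10, 10), "rect", bounds = c(0, 5, 1, 5)),
               "bounds")
  expect_error(support_mask(c(10, 10), "circle", center = c(50, 5),
                            radius = 2), "centre|range")
})
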