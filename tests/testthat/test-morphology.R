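test_that("structuring-element constructors give the stated footprints", {
  d0 <- disk_se(0)
  expect_equal(dim(d0$footprint), c(1L, 1L))
  expect_true(all(d0$footprint))

  d1 <- disk_se(1)
  expect_equal(dim(d1$footprint), c(3L, 3L))
  expect_equal(sum(d1$footprint), 5L)           # plus shape
  expect_false(d1$footprint[1, 1])

  # brute-force membership r^2 + c^2 <= radius^2 for radius 1 and 2
  for (r in 1:2) {
    d <- disk_se(r)
    ref <- outer(seq(-r, r)^2, seq(-r, r)^2, `+`) <= r^2
    expect_identical(d$footprint, ref)
  }
  expect_equal(sum(disk_se(2)$footprint), 13L)

  s2 <- square_se(2)
  expect_true(all(s2$footprint) && all(dim(s2$footprint) == 2L))
  expect_equal(s2$origin, c(1L, 1L))            # even: top-left origin
  expect_equal(square_se(3)$origin, c(2L, 2L))  # odd: centre
  expect_error(disk_se(-1), "radius")
  expect_error(square_se(0), "positive")
})

test_that("erosion and dilation match hand-derived small cases", {
  # single isolated pixel is erased by the radius-1 disk
  f <- matrix(FALSE, 7, 7); f[4, 4] <- TRUE
  expect_false(any(erode(f, disk_se(1))))
  # ... and dilates to the 5-pixel plus
  d <- dilate(f, disk_se(1))
  expect_equal(sum(d), 5L)
  expect_true(all(d[cbind(c(3, 4, 4, 4, 5), c(4, 3, 4, 5, 4))]))
  # single-cell SE is the identity element
  g <- matrix(runif(64) < 0.5, 8, 8)
  expect_identical(erode(g, square_se(1)), g)
  expect_identical(dilate(g, square_se(1)), g)
  # all-false input stays empty under dilation
  expect_false(any(dilate(matrix(FALSE, 5, 5), disk_se(1))))
  # 3x3 block eroded by the 2x2 square (origin top-left) leaves a 2x2
  # block anchored at the original corner
  f2 <- matrix(FALSE, 7, 7); f2[3:5, 3:5] <- TRUE
  e2 <- erode(f2, square_se(2))
  ref <- matrix(FALSE, 7, 7); ref[3:4, 3:4] <- TRUE
  expect_identical(e2, ref)
})

test_that("all six operations agree exactly with the set-translation oracle", {
  set.seed(1234)
  s1 <- disk_se(1); s2 <- square_se(2)
  for (i in seq_len(200)) {
    f <- random_mask(32L, p = runif(1, 0.2, 0.8))
    se <- if (i %% 2L == 0L) s1 else s2
    expect_identical(erode(f, se), brute_erode(f, se))
    expect_identical(dilate(f, se), brute_dilate(f, se))
    if (i %% 10L == 0L) {      # cascades on a subsample (they compose
      expect_identical(mopen(f, se), brute_open(f, se))      # the two
      expect_identical(mclose(f, se), brute_close(f, se))    # primitives)
      expect_identical(open_close(f, s1, s2), brute_oc(f, s1, s2))
      expect_identical(close_open(f, s1, s2), brute_co(f, s1, s2))
    }
  }
})

test_that("morphology satisfies duality, idempotence, extensivity, monotonicity", {
  set.seed(99)
  s1 <- disk_se(1); s2 <- square_se(2)
  # reflection of the footprint about the origin cell
  reflect_se <- function(se) {
    fp <- se$footprint[rev(seq_len(nrow(se$footprint))),
                       rev(seq_len(ncol(se$footprint))), drop = FALSE]
    struct_el(fp, dim(fp) + 1L - se$origin)
  }
  # keep the foreground clear of the border: the classical identities
  # hold for finite sets in the plane, and the background-false border
  # convention makes the image boundary behave like empty plane only
  # when nothing touches it
  padded_mask <- function() {
    f <- matrix(FALSE, 32L, 32L)
    f[4:29, 4:29] <- random_mask(26L)
    f
  }
  for (i in 1:20) {
    f <- padded_mask()
    for (se in list(s1, s2)) {
      # duality: dilation is the complement of eroding the complement
      inner <- 2:31
      expect_identical(dilate(f, se)[inner, inner],
                       (!erode(!f, reflect_se(se)))[inner, inner])
      # idempotence
      expect_identical(mopen(mopen(f, se), se), mopen(f, se))
      expect_identical(mclose(mclose(f, se), se), mclose(f, se))
      # anti-extensive opening, extensive closing
      expect_true(all(mopen(f, se) <= f))
      expect_true(all(f <= mclose(f, se)))
    }
    # monotonicity: F1 subset of F2 is preserved
    f2 <- f | padded_mask()
    expect_true(all(erode(f, s1) <= erode(f2, s1)))
    expect_true(all(dilate(f, s1) <= dilate(f2, s1)))
  }
})

test_that("solid blocks pass the cascades intact up to SE geometry", {
  f <- matrix(FALSE, 20, 20); f[6:15, 6:15] <- TRUE
  s1 <- disk_se(1); s2 <- square_se(2)
  # square elements leave a square block exactly unchanged
  expect_identical(open_close(f, s2, s2), f)
  expect_identical(close_open(f, s2, s2), f)
  # the disk element rounds the four corners when opening (a square is
  # not a union of plus-shaped translates); everything else survives
  oc <- open_close(f, s1, s2)
  corners <- cbind(c(6, 6, 15, 15), c(6, 15, 6, 15))
  inner <- f; inner[corners] <- FALSE
  expect_true(all(oc[inner]))
  expect_true(all(!oc[!f]))
  # isolated speckle pixels are removed by the open-closing cascade
  fs <- f
  fs[cbind(c(2, 3, 18), c(2, 18, 3))] <- TRUE
  ocs <- open_close(fs, s1, s2)
  expect_false(any(ocs[cbind(c(2, 3, 18), c(2, 18, 3))]))
  expect_true(all(ocs[inner]))
})
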