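test_that("ripple offsets follow the sinusoidal displacement formulas", {
  p <- ripple_params(0.04, 2)
  # zero amplitude kills the displacement everywhere
  z <- ripple_offsets(c(0, 3, 17), c(0, 5, 9), ripple_params(0.5, 0))
  expect_equal(z$offset_x, c(0, 0, 0))
  expect_equal(z$offset_y, c(0, 0, 0))
  # zero frequency: sin 0 = 0, cos 0 = 1
  z0 <- ripple_offsets(4, 7, ripple_params(0, 2))
  expect_equal(z0$offset_x, 0)
  expect_equal(z0$offset_y, 2)
  # frozen values from direct evaluation of the two trig formulas
  o <- ripple_offsets(0:3, 0:3, p)
  expect_equal(o$offset_x,
               c(0, 0.4973797743, 0.9635073482, 1.3690942119), tolerance = 1e-9)
  expect_equal(o$offset_y,
               c(2, 1.9371663223, 1.7526133601, 1.4579372548), tolerance = 1e-9)
  expect_true(all(abs(o$offset_x) <= 2 + 1e-12))
  expect_error(ripple_params(-0.1, 1), "frequency")
  expect_error(ripple_params(0.1, -1), "amplitude")
})

test_that("water-ripple warp matches the frozen hand-worked 4x4 example", {
  img <- image_grid(array(rep(matrix(1:16, 4, 4, byrow = TRUE), 3), c(4, 4, 3)))
  out <- apply_water_ripple(img, ripple_params(0.25, 1))
  expected <- matrix(c(5, 2, 15, 4,
                       10, 7, 4, 5,
                       13, 10, 7, 12,
                       4, 13, 10, 15), 4, 4, byrow = TRUE)
  expect_equal(unclass(out)[, , 1], expected, ignore_attr = TRUE)
})

test_that("water-ripple warp has the required identities", {
  img <- rand_img(8, 8, seed = 1)
  # zero amplitude is the identity under replace blending
  expect_identical(unclass(apply_water_ripple(img, ripple_params(0.3, 0))),
                   unclass(img))
  # warping a constant field changes nothing
  const <- image_grid(array(77, c(6, 9, 3)))
  expect_identical(unclass(apply_water_ripple(const, ripple_params(0.13, 5))),
                   unclass(const))
  # integer frequency on integer pixel indices equals frequency zero
  expect_identical(unclass(apply_water_ripple(img, ripple_params(2, 3))),
                   unclass(apply_water_ripple(img, ripple_params(0, 3))))
  # shape preserved
  r <- apply_water_ripple(rand_img(5, 11, seed = 2), ripple_params(0.07, 4))
  expect_identical(dim(r), c(5L, 11L, 3L))
})

test_that("water-ripple warp equals the per-pixel brute-force oracle", {
  withr::with_seed(42, {
    for (i in 1:12) {
      h <- sample(2:8, 1); w <- sample(2:8, 1)
      img <- rand_img(h, w)
      f <- runif(1, 0, 0.5); a <- runif(1, 0, 6)
      blend <- sample(c("replace", "mean"), 1)
      expect_identical(
        unclass(apply_water_ripple(img, ripple_params(f, a, blend))),
        unclass(ripple_oracle(img, f, a, blend)))
    }
  })
})

test_that("ripple warp preserves the pixel multiset when the map is a bijection", {
  # F = 0.5 on even dims: offsets alternate +/-A along each axis, a permutation
  img <- rand_img(8, 8, seed = 7)
  out <- apply_water_ripple(img, ripple_params(0.5, 1))
  expect_equal(sort(as.vector(unclass(out)[, , 1])),
               sort(as.vector(unclass(img)[, , 1])))
})

test_that("light reflection is additive, bounded and seeded-deterministic", {
  img <- rand_img(40, 40, seed = 3)
  p0 <- reflection_params(0.6, 0, px_per_cm = 50, seed = 5)
  expect_identical(unclass(apply_light_reflection(img, p0)), unclass(img))
  p <- reflection_params(0.6, 250, px_per_cm = 50, seed = 5)
  out <- apply_light_reflection(img, p)
  expect_gte(mean(out), mean(img))
  expect_true(max(out) <= 255)
  expect_identical(unclass(out), unclass(apply_light_reflection(img, p)))
  expect_identical(dim(out), dim(unclass(img)))
  # oversized disc rejected
  expect_error(apply_light_reflection(rand_img(10, 10), reflection_params(1, 100)),
               "radius")
})

test_that("a single reflection spot lights up approximately the disc area", {
  black <- image_grid(array(0, c(120, 120, 3)))
  p <- reflection_params(0.6, 400, px_per_cm = 50, n_spots = 1, seed = 2)
  # centre the spot away from borders by trying seeds until it fits
  out <- apply_light_reflection(black, p)
  lit <- sum(unclass(out)[, , 1] > 0)
  expect_lt(abs(lit - pi * 15^2) / (pi * 15^2), 0.35)  # falloff/rounding slack
})

test_that("noise-variant expansion replicates the manifest per configuration", {
  m <- data.frame(path = sprintf("img_%03d.png", 1:50),
                  label = rep(c("a", "b"), 25), split = "train",
                  stringsAsFactors = FALSE)
  refl <- reflection_noise_grid()
  rip <- ripple_noise_grid()
  out <- build_noise_variants(m, ripple_grid = rip, reflection_grid = refl)
  expect_equal(nrow(out), 50 * (9 + 3))
  expect_equal(length(unique(out$variant_tag)), 12)
  expect_setequal(unique(out$variant_tag[grepl("^D_", out$variant_tag)]),
                  c("D_0.6_E_100", "D_0.6_E_250", "D_0.6_E_400",
                    "D_0.8_E_100", "D_0.8_E_250", "D_0.8_E_400",
                    "D_1_E_100", "D_1_E_250", "D_1_E_400"))
  expect_error(build_noise_variants(m[0, ], ripple_grid = rip), "non-empty")
  expect_error(build_noise_variants(m, ripple_grid = c(rip, rip[1])), "collision")
})
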