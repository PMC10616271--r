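# Categorical raster operations: harmonisation, resampling, masking,
# per-square change metrics, temperature trends.

toy_raster <- function(m, res = 1, nodata = 255L) {
  cat_raster(m, resolution = res, nodata = nodata)
}

test_that("harmonize remaps codes, pools classes, preserves nodata", {
  m <- matrix(c(11L, 12L, 20L, 255L), 2, 2)
  r <- toy_raster(m)
  # identity
  id_map <- c(`11` = 11L, `12` = 12L, `20` = 20L)
  expect_identical(harmonize(r, id_map)$values, r$values)
  # two native heath codes pool into one grassland code; counts add
  pool <- c(`11` = 2L, `12` = 2L, `20` = 3L)
  h <- harmonize(r, pool)
  expect_identical(sum(h$values == 2L), 2L)
  expect_identical(sum(h$values == 255L), 1L)
  # littoral-style drop to nodata
  drop <- c(`11` = 2L, `12` = NA_integer_, `20` = 3L)
  expect_identical(sum(harmonize(r, drop)$values == 255L), 2L)
  # unmapped code named in the error
  r99 <- toy_raster(matrix(c(11L, 99L), 1, 2))
  expect_error(harmonize(r99, id_map), "99")
})

test_that("nearest-neighbour resampling follows pixel-centre geometry", {
  u <- toy_raster(matrix(3L, 4, 4))
  expect_identical(resample_nearest(u, 1), u)
  # upsample of a uniform raster stays uniform
  up <- resample_nearest(u, 0.5)
  expect_identical(dim(up$values), c(8L, 8L))
  expect_true(all(up$values == 3L))
  # 2x downsample of a checkerboard: each 2-unit target pixel centre at
  # (1, 1), (3, 1), ... falls in the source pixel with index (1,1), (1,3)...
  cb <- matrix(rep(c(1L, 2L), 8), 4, 4)  # rows alternate 1,2,1,2
  down <- resample_nearest(toy_raster(cb), 2)
  expect_identical(down$values, matrix(c(1L, 1L, 1L, 1L), 2, 2))
})

test_that("common mask buffers geometry and aligns nodata footprints", {
  a <- toy_raster(matrix(1L, 5, 5))
  b <- toy_raster(matrix(2L, 5, 5))
  b$values[1, 1] <- 255L
  out <- apply_common_mask(a, b, mask = NULL)
  # mutual nodata alignment only
  expect_identical(out$a$values[1, 1], 255L)
  expect_identical(sum(out$a$values == 255L), 1L)
  # horizontal line through the centre (y = 2.5), buffer of one pixel:
  # pixel centres at y = 1.5, 2.5, 3.5 are within distance 1
  seg <- data.frame(x0 = 0, y0 = 2.5, x1 = 5, y1 = 2.5)
  out2 <- apply_common_mask(toy_raster(matrix(1L, 5, 5)),
                            toy_raster(matrix(2L, 5, 5)),
                            mask = seg, buffer_width = 1)
  expect_identical(sum(out2$a$values == 255L), 15L)  # 3-row band
  expect_identical(out2$a$values == 255L, out2$b$values == 255L)
  # misaligned grids rejected
  c5 <- cat_raster(matrix(1L, 5, 5), resolution = 2)
  expect_error(apply_common_mask(a, c5), "co-registered")
})

test_that("category fractions sum to one over valid pixels", {
  # one square, 3 grassland + 1 arable
  r <- toy_raster(matrix(c(2L, 2L, 2L, 3L), 2, 2))
  fr <- category_fractions(r, 2)
  expect_equal(fr$fraction[fr$category == 2], 0.75)
  expect_equal(fr$fraction[fr$category == 3], 0.25)
  # uniform raster
  u <- category_fractions(toy_raster(matrix(4L, 4, 4)), 4)
  expect_equal(u$fraction[u$category == 4], 1)
  # half nodata, remainder uniform: fraction 1 over valid pixels
  m <- matrix(4L, 4, 4); m[, 1:2] <- 255L
  expect_equal(category_fractions(toy_raster(m), 4)$fraction, 1)
  # rows sum to 1 on a busy raster
  w <- test_world()
  fr2 <- category_fractions(w$raster_hist, 10)
  sums <- tapply(fr2$fraction, fr2$square_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fractional change is modern minus historical and sums to zero", {
  h <- toy_raster(matrix(c(2L, 2L, 2L, 3L), 2, 2))
  m <- toy_raster(matrix(c(2L, 3L, 3L, 3L), 2, 2))
  ch <- fractional_change(category_fractions(h, 2), category_fractions(m, 2))
  expect_equal(ch$change[ch$category == 2], -0.5)
  expect_equal(ch$change[ch$category == 3], 0.5)
  # identical epochs give all zeros
  ch0 <- fractional_change(category_fractions(h, 2), category_fractions(h, 2))
  expect_true(all(ch0$change == 0))
  # complete swap gives -1 / +1 (shared declared category set)
  a <- cat_raster(matrix(1L, 2, 2), categories = 1:2)
  b <- cat_raster(matrix(2L, 2, 2), categories = 1:2)
  chs <- fractional_change(category_fractions(a, 2), category_fractions(b, 2))
  expect_equal(sort(chs$change[chs$category %in% 1:2]), c(-1, 1))
  # per-square changes sum to zero on the synthetic world
  w <- test_world()
  chw <- fractional_change(category_fractions(w$raster_hist, 10),
                           category_fractions(w$raster_mod, 10))
  sums <- tapply(chw$change, chw$square_id, sum)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("land conversion counts changed valid pixels", {
  a <- toy_raster(matrix(c(1L, 1L, 1L, 1L), 2, 2))
  expect_equal(land_conversion(a, a, 2)$L, 0)
  b <- toy_raster(matrix(2L, 2, 2))
  expect_equal(land_conversion(a, b, 2)$L, 1)
  c1 <- toy_raster(matrix(c(2L, 1L, 1L, 1L), 2, 2))
  expect_equal(land_conversion(a, c1, 2)$L, 0.25)
})

test_that("land conversion bounds category-level fractional change", {
  w <- test_world()
  L <- land_conversion(w$raster_hist, w$raster_mod, 10)
  ch <- fractional_change(category_fractions(w$raster_hist, 10),
                          category_fractions(w$raster_mod, 10))
  maxch <- tapply(abs(ch$change), ch$square_id, max)
  j <- match(L$square_id, as.integer(names(maxch)))
  expect_true(all(L$L >= maxch[j] - 1e-9))
})

test_that("land conversion is invariant to category relabelling", {
  w <- test_world()
  relabel <- c(`1` = 6L, `2` = 5L, `3` = 4L, `4` = 3L, `5` = 2L, `6` = 1L)
  L1 <- land_conversion(w$raster_hist, w$raster_mod, 10)
  L2 <- land_conversion(harmonize(w$raster_hist, relabel),
                        harmonize(w$raster_mod, relabel), 10)
  expect_equal(L1$L, L2$L)
})

test_that("transition matrix rows are probability vectors", {
  a <- toy_raster(matrix(c(2L, 2L, 3L, 3L), 2, 2))
  tm0 <- transition_matrix(a, a)
  expect_true(all(tm0$proportion[tm0$from == tm0$to] == 1))
  # all grassland to arable
  g <- toy_raster(matrix(2L, 2, 2)); ar <- toy_raster(matrix(3L, 2, 2))
  tm1 <- transition_matrix(g, ar, from_category = 2)
  expect_equal(tm1$proportion[tm1$to == 3], 1)
  # mixed toy vs brute-force tally
  h <- toy_raster(matrix(c(2L, 2L, 2L, 3L, 3L, 1L), 2, 3))
  m <- toy_raster(matrix(c(2L, 3L, 6L, 3L, 1L, 1L), 2, 3))
  tm <- transition_matrix(h, m, from_category = 2)
  expect_equal(tm$proportion[order(tm$to)],
               c(1 / 3, 1 / 3, 1 / 3))  # 2->2, 2->3, 2->6, one pixel each
  # world-scale: every from-row sums to 1
  w <- test_world()
  tw <- transition_matrix(w$raster_hist, w$raster_mod)
  sums <- tapply(tw$proportion, tw$from, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # absent from-category flagged
  expect_warning(out <- transition_matrix(g, ar, from_category = 5), "absent")
  expect_identical(nrow(out), 0L)
})

test_that("specialist change extracts one habitat's change as covariate", {
  h <- toy_raster(matrix(c(2L, 2L, 2L, 3L), 2, 2))   # grassland 0.75
  m <- toy_raster(matrix(c(2L, 2L, 3L, 3L), 2, 2))   # grassland 0.50
  ch <- fractional_change(category_fractions(h, 2), category_fractions(m, 2))
  sc <- specialist_change(ch, 2)
  expect_equal(sc$habitat_change, -0.25)
  # unchanged habitat everywhere -> zeros
  ch0 <- fractional_change(category_fractions(h, 2), category_fractions(h, 2))
  expect_equal(specialist_change(ch0, 2)$habitat_change, 0)
  expect_error(specialist_change(ch, 9), "unknown habitat")
})

test_that("temperature trend is the OLS slope times ten", {
  s <- tibble::tibble(square_id = 1, year = 1961:1999,
                      temp = 8 + 0.02 * (1961:1999))
  expect_equal(temperature_trend(s)$temp_trend, 0.2, tolerance = 1e-10)
  s0 <- tibble::tibble(square_id = 1, year = 1961:1999, temp = 9)
  expect_equal(temperature_trend(s0)$temp_trend, 0)
  # noisy series vs closed-form normal equations
  set.seed(1)
  sn <- tibble::tibble(square_id = 1, year = 1961:1999,
                       temp = 8 + 0.015 * (1961:1999) + rnorm(39, sd = 0.3))
  ols <- with(sn, sum((year - mean(year)) * (temp - mean(temp))) /
                sum((year - mean(year))^2))
  expect_equal(temperature_trend(sn)$temp_trend, 10 * ols, tolerance = 1e-10)
  # window filter and <3 year drop
  short <- tibble::tibble(square_id = c(1, 1, 2, 2, 2),
                          year = c(1961, 1962, 1961, 1962, 1963),
                          temp = c(8, 8.1, 8, 8.2, 8.4))
  tt <- temperature_trend(short)
  expect_identical(tt$square_id, 2)
  expect_identical(attr(tt, "dropped"), 1)
  # monthly data are averaged to annual means first
  mo <- tidyr::expand_grid(square_id = 1, year = 1990:1999, month = 1:12)
  mo$temp <- 8 + 0.05 * (mo$year - 1990) + rep(c(-3, 3), 60)
  expect_equal(temperature_trend(mo)$temp_trend, 0.5, tolerance = 1e-9)
})

test_that("digitisation agreement utilities match hand counts", {
  a <- toy_raster(matrix(c(1L, 1L, 2L, 2L), 2, 2))
  b <- toy_raster(matrix(c(1L, 2L, 2L, 2L), 2, 2))
  expect_equal(pixel_agreement(a, b), 0.75)
  expect_equal(square_rmsd(a, b, 2),
               sqrt(mean(c(0.5 - 0.25, 0.75 - 0.5)^2)))
})

test_that("ASCII grid round-trips a raster losslessly", {
  w <- test_world()
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(w$raster_hist, path)
  r2 <- read_asc(path)
  expect_identical(r2$values, w$raster_hist$values)
  expect_equal(r2$resolution, w$raster_hist$resolution)
  expect_equal(r2$origin, w$raster_hist$origin)
})
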