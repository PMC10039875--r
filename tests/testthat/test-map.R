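test_that("slice coordinates reduce to axis-aligned distances for a flat
           surface and are invariant to rigid rotation", {
  surface <- cbind(runif(10, 0, 400), runif(10, 0, 400), 0)
  cells <- rbind(c(100, 100, -50), c(250, 80, -120))
  dors <- c(200, 400, 0); vent <- c(200, 0, 0)
  out <- slice_coordinate_transform(surface, dors, vent, cells)
  expect_equal(out$ap_um, c(50, 120), tolerance = 1e-6)
  expect_equal(abs(out$ml_um), c(100, 50), tolerance = 1e-6)

  # rigid rotation of the whole scene preserves all three coordinates
  th <- 11.2 * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- function(m) t(Rx %*% t(m))
  out_rot <- slice_coordinate_transform(rot(surface), drop(Rx %*% dors),
                                        drop(Rx %*% vent), rot(cells))
  expect_equal(out_rot$ap_um, out$ap_um, tolerance = 1e-6)
  expect_equal(abs(out_rot$ml_um), abs(out$ml_um), tolerance = 1e-6)
  expect_equal(abs(out_rot$dv_um), abs(out$dv_um), tolerance = 1e-6)
  # pairwise inter-cell distances preserved (isometry composition)
  d1 <- dist(cbind(out$ap_um, out$ml_um, out$dv_um))
  d0 <- dist(cells)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-6)
  expect_error(slice_coordinate_transform(cbind(1:3, 1:3, 0) * 1,
                                          dors, vent, cells), "collinear")
})

test_that("a tilted surface yields true normal depth, not the vertical
           difference", {
  th <- 11.2 * pi / 180
  # plane through origin tilted about x-axis
  xs <- runif(12, 0, 400); ys <- runif(12, 0, 400)
  surface <- cbind(xs, ys * cos(th), -ys * sin(th))
  cell <- matrix(c(200, 200 * cos(th), -200 * sin(th) - 80), 1)
  out <- slice_coordinate_transform(surface, surface[1, ], surface[2, ],
                                    cell)
  # a straight-down 80 um offset lies 80 cos(theta) from the tilted plane;
  # the naive z-difference (80) overestimates it
  expect_equal(out$ap_um[1], 80 * cos(th), tolerance = 1e-4)
  expect_lt(out$ap_um[1], 80)
})

test_that("map summaries follow the stated probability and zero-fill
           rules", {
  map <- tibble::tibble(
    ml_um = c(-50, 50, 100, 200, 350),
    dv_um = c(0, 0, 0, 0, 0),
    responsive = TRUE,
    connected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    strength_pa = c(20, 0, 0, 0, 0))
  rec <- list(ml_um = 0, dv_um = 0)
  s <- map_summaries(map, rec, radius_um = 300)
  expect_equal(s$probability, 2 / 4)   # the 350 um cell is outside
  expect_equal(s$weighted_input_pa, 4)  # 20/5
  expect_equal(s$input_medial_pa, 20)   # only the medial cell has strength
  expect_equal(s$input_lateral_pa, 0)
  # weighted input never exceeds the mean strength of connected cells
  expect_lte(s$weighted_input_pa, s$mean_strength_pa)
  expect_error(map_summaries(dplyr::mutate(map, responsive = FALSE), rec),
               "responsive")
})

test_that("co-stimulation bias matches its closed form and grows with the
           ellipsoid", {
  expect_equal(costim_bias_from_fraction(0.13), 1 - 1 / 1.13)
  expect_equal(round(100 * costim_bias_from_fraction(0.13), 1), 11.5)
  expect_equal(costim_bias_from_fraction(0), 0)
  expect_equal(costim_bias_from_fraction(1), 0.5)

  # isolated cells: no neighbors, no bias
  grid <- expand.grid(x_um = seq(0, 900, 300), y_um = seq(0, 900, 300),
                      z_um = 0)
  cb <- costimulation_bias(grid)
  expect_equal(cb$f_co, 0)
  expect_equal(cb$bias, 0)

  # a dense cluster: everyone has a neighbor
  dense <- tibble::tibble(x_um = c(0, 5, 10), y_um = 0, z_um = 0)
  cb2 <- costimulation_bias(dense)
  expect_equal(cb2$f_co, 1)
  expect_equal(cb2$bias, 0.5)

  # monotone in the FWHM arguments
  set.seed(9)
  pts <- tibble::tibble(x_um = runif(150, 0, 420), y_um = runif(150, 0, 420),
                        z_um = runif(150, 0, 300))
  b_small <- costimulation_bias(pts, 30, 15)$f_co
  b_big <- costimulation_bias(pts, 80, 40)$f_co
  expect_gte(b_big, b_small)
  # semi-axis reading doubles the ellipsoid
  b_semi <- costimulation_bias(pts, 30, 15, semantics = "semi_axis")$f_co
  expect_gte(b_semi, b_small)
})

test_that("depth-split connectivity recovers planted shell ratios", {
  set.seed(10)
  n <- 6000
  maps <- tibble::tibble(
    map_id = rep(1:10, each = n / 10),
    depth_um = runif(n, 0, 140),
    recorded_depth_um = 70,
    responsive = TRUE)
  p_above <- 0.02; p_below <- 0.02 * 1.77
  deep <- maps$depth_um > maps$recorded_depth_um
  maps$connected <- runif(n) < ifelse(deep, p_below, p_above)
  maps$strength_pa <- ifelse(maps$connected, rlnorm(n, log(15), 0.3), 0)
  ds <- depth_split_connectivity(maps)
  expect_lt(abs(ds$ratio_below_above - 1.77) / 1.77, 0.35)
  # strengths drawn identically in both shells agree within tolerance
  expect_lt(abs(ds$strength_below_pa - ds$strength_above_pa) /
              ds$strength_above_pa, 0.2)
})

test_that("attenuation compensation follows the monoexponential law", {
  expect_equal(attenuation_compensation(0), 1)
  expect_equal(attenuation_compensation(147.6), exp(1))
  expect_equal(attenuation_compensation(147.6, tau_um = 147.6), exp(1))
  expect_error(attenuation_compensation(-5), "depth_um")
})
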