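# Analysis battery: order parameters, area per lipid, profiles, thickness,
# core water density, pore detection, block errors.

test_that("the order-parameter formula hits its analytic limits", {
  expect_identical(scd_from_cosines(c(1, 1, 1)), 1)
  expect_identical(scd_from_cosines(c(0, 0)), -0.5)
  expect_error(scd_from_cosines(numeric(0)), "empty")
  expect_error(scd_from_cosines(c(0.5, 1.2)), "\\[-1, 1\\]")
})

test_that("isotropic bond orientations average to zero", {
  set.seed(12)
  n <- 1e6
  cosines <- runif(n, -1, 1)  # cos(theta) uniform on [-1,1] <=> isotropy
  s <- scd_from_cosines(cosines)
  se <- sd((3 * cosines^2 - 1) / 2) / sqrt(n)
  expect_lt(abs(s), 3 * se)
})

test_that("untilted rigid chains give S_CD = -1/2 and tilt follows the closed form", {
  r0 <- gen_bilayer_trajectory(synthetic_spec(n_lipids = 12, n_frames = 4,
                                              tilt = 0, n_water = 0, seed = 2))
  op0 <- order_parameter(r0$trajectory)
  expect_equal(op0$mean_scd, -0.5, tolerance = 1e-6)
  expect_true(all(abs(op0$per_carbon + 0.5) < 1e-6))

  # alpha = 30 deg, uniform spin: rotational average -1/2 * P2(cos 30) = -0.3125
  spec <- synthetic_spec(n_lipids = 40, n_frames = 20, tilt = 30,
                         n_water = 0, p_jitter = 0, seed = 5)
  r <- gen_bilayer_trajectory(spec)
  op <- order_parameter(r$trajectory)
  n_samp <- 40 * 10  # lipids x post-equilibration frames
  se <- mc_chain_scd_sd(30) / sqrt(n_samp)
  expect_lt(abs(op$mean_scd - (-0.3125)), 3 * se)
  expect_equal(r$truth$mean_scd, -0.3125, tolerance = 1e-12)
})

test_that("the vectorised order parameter matches brute-force reconstruction", {
  spec <- synthetic_spec(n_lipids = 10, n_frames = 3, tilt = 20,
                         ox_fraction = 0.4, ox_species = "OX2",
                         n_water = 0, seed = 9)
  traj <- gen_bilayer_trajectory(spec)$trajectory
  op <- order_parameter(traj, equil_time = 0)
  p <- traj$particles
  vals <- c()
  for (sp in c("POPC", "OX2")) {
    tpl <- build_template(sp)
    for (id in unique(p$lipid_id[p$species == sp])) {
      rows <- which(p$lipid_id == id & p$species == sp)
      for (f in traj$frames) {
        co <- unwrap_chain(f$xyz[rows, ], f$box)
        vals <- rbind(vals, brute_chain_scd(co, tpl))
      }
    }
  }
  expect_equal(op$mean_scd, mean(colMeans(vals)), tolerance = 1e-12)
  expect_equal(unname(op$per_carbon), unname(colMeans(vals)), tolerance = 1e-12)
})

test_that("time averaging is idempotent on frozen frames", {
  spec <- synthetic_spec(n_lipids = 8, n_frames = 1, tilt = 15, n_water = 0,
                         seed = 3)
  traj1 <- gen_bilayer_trajectory(spec)$trajectory
  f <- traj1$frames[[1]]
  frames10 <- lapply(1:10, function(i) list(time = i * 100, box = f$box, xyz = f$xyz))
  traj10 <- bilayer_trajectory(traj1$particles, frames10)
  expect_equal(order_parameter(traj1, equil_time = 0)$mean_scd,
               order_parameter(traj10, equil_time = 0)$mean_scd,
               tolerance = 1e-14)
})

test_that("order parameters stay within physical bounds and C2 is switchable", {
  spec <- synthetic_spec(n_lipids = 16, n_frames = 6, tilt_sigma = 20, seed = 21,
                         n_water = 0)
  op <- order_parameter(gen_bilayer_trajectory(spec)$trajectory)
  expect_true(all(op$per_carbon >= -0.5 & op$per_carbon <= 1))
  op_noc2 <- order_parameter(gen_bilayer_trajectory(spec)$trajectory,
                             include_c2 = FALSE)
  expect_false("C2" %in% names(op_noc2$per_carbon))
  expect_length(op_noc2$per_carbon, length(op$per_carbon) - 1)
})

test_that("area per lipid is exact arithmetic on the box area", {
  traj <- make_area_traj(rep(36, 5))  # constant 6 x 6 nm box
  apl <- area_per_lipid(traj, 36, equil_time = 0)
  expect_identical(apl$value, 1)     # 1.00 nm^2 = 100 A^2
  expect_identical(apl$error, 0)

  traj2 <- make_area_traj(rep(c(35, 37), 10))  # 3500 / 3700 A^2 alternating
  apl2 <- area_per_lipid(traj2, 36, equil_time = 0)
  expect_equal(apl2$value, 1, tolerance = 1e-12)
  expect_error(area_per_lipid(traj, 36, equil_time = 1e6), "no frames")
})

test_that("area-per-lipid error tracks the AR(1) closed form", {
  n <- 2^14; phi <- 0.8; sig <- 0.4
  areas <- 36 + gen_ar1_series(n, 0, sig, phi, seed = 17)
  apl <- area_per_lipid(make_area_traj(areas), 36, equil_time = 0)
  se_true <- (sig / 36) / sqrt(n) * sqrt((1 + phi) / (1 - phi))
  expect_lt(abs(apl$error - se_true) / se_true, 0.15)
})

test_that("uniformly filling waters give a flat profile at the analytic density", {
  set.seed(8)
  n <- 1e5
  box <- c(4, 4, 6)
  xyz <- cbind(runif(n) * box[1], runif(n) * box[2], runif(n) * box[3])
  traj <- make_manual_traj(rep("OW", n), rep("SOL", n), rep(18.015, n),
                           rep(NA_integer_, n), xyz, box)
  prof <- density_profile(traj, water_selection, n_bins = 20, equil_time = 0)
  rho <- n * 18.015 / prod(box) * 1.66053906892
  expect_true(all(abs(prof$density - rho) / rho < 0.05))
  # mass conservation to 0.1%
  tot <- sum(prof$density) * attr(prof, "mean_bin_volume") / 1.66053906892
  expect_equal(tot, n * 18.015, tolerance = 1e-3)
})

test_that("profiles conserve mass under NPT-like box fluctuations", {
  r <- gen_bilayer_trajectory(synthetic_spec(n_lipids = 16, n_frames = 8,
                                             area_sigma = 0.4, seed = 14))
  for (sel in list(phosphate_selection, water_selection, "POPC")) {
    prof <- density_profile(r$trajectory, sel)
    tot <- sum(prof$density) * attr(prof, "mean_bin_volume") / 1.66053906892
    expect_equal(tot, attr(prof, "total_mass"), tolerance = 1e-3)
  }
})

test_that("point selections land in a single bin; empty selections warn", {
  n <- 20
  xyz <- cbind(runif(n, 0, 4), runif(n, 0, 4), rep(2.37, n))
  traj <- make_manual_traj(rep("OW", n), rep("SOL", n), rep(18.015, n),
                           rep(NA_integer_, n), xyz, c(4, 4, 6))
  prof <- density_profile(traj, water_selection, equil_time = 0)
  expect_identical(sum(prof$density > 0), 1L)
  expect_warning(z <- density_profile(traj, "POPC", equil_time = 0),
                 "empty selection")
  expect_true(all(z$density == 0))
})

test_that("thickness is the P-peak distance with a bin-width error bar", {
  np <- 40
  mkframe <- function(zoff) {
    xyz <- cbind(runif(np, 0, 4), runif(np, 0, 4),
                 5 + zoff * rep(c(1, -1), each = np / 2))
    make_manual_traj(rep("P", np), rep("POPC", np), rep(30.974, np),
                     seq_len(np), xyz, c(4, 4, 10))
  }
  th <- bilayer_thickness(density_profile(mkframe(1.93), phosphate_selection,
                                          equil_time = 0))
  expect_equal(th$value, 3.86, tolerance = 0.1 / 3.86)  # within one bin
  expect_equal(th$error, 0.1, tolerance = 1e-9)
  expect_identical(th$method, "bin-width")

  # z-mirror invariance on a symmetric profile
  tr <- mkframe(1.93)
  tr_m <- tr; tr_m$frames[[1]]$xyz[, 3] <- 10 - tr$frames[[1]]$xyz[, 3]
  th_m <- bilayer_thickness(density_profile(tr_m, phosphate_selection,
                                            equil_time = 0))
  expect_equal(th_m$value, th$value, tolerance = 1e-9)

  # merged leaflets are flagged
  expect_error(bilayer_thickness(density_profile(mkframe(0.001),
                                                 phosphate_selection,
                                                 equil_time = 0)),
               "merged|peaks")
})

test_that("gaussian leaflet peaks recover the separation within one bin", {
  set.seed(6)
  for (d in c(3.4, 3.8, 4.2)) {
    np <- 2000
    xyz <- cbind(runif(np, 0, 4), runif(np, 0, 4),
                 5 + rnorm(np, d / 2 * rep(c(1, -1), each = np / 2), 0.2))
    traj <- make_manual_traj(rep("P", np), rep("POPC", np), rep(30.974, np),
                             seq_len(np), xyz, c(4, 4, 10),
                             times = c(100, 200, 300))
    th <- bilayer_thickness(density_profile(traj, phosphate_selection,
                                            equil_time = 0))
    expect_lt(abs(th$value - d), attr(density_profile(traj, phosphate_selection,
                                                      equil_time = 0),
                                      "bin_width") + 1e-9)
  }
})

test_that("core water density: dry core is zero, full box matches bulk", {
  dry <- gen_bilayer_trajectory(synthetic_spec(n_lipids = 12, n_frames = 4,
                                               seed = 4))
  expect_identical(water_density_center(dry$trajectory), 0)

  set.seed(15)
  n <- 2e4; box <- c(3, 3, 5)
  xyz <- cbind(runif(n) * box[1], runif(n) * box[2], runif(n) * box[3])
  traj <- make_manual_traj(rep("OW", n), rep("SOL", n), rep(18.015, n),
                           rep(NA_integer_, n), xyz, box)
  rho <- water_density_center(traj, equil_time = 0)
  rho_bulk <- n * 18.015 / prod(box) * 1.66053906892
  expect_equal(rho, rho_bulk, tolerance = 0.02)
})

test_that("a generated water cylinder matches the geometric slab prediction", {
  spec <- synthetic_spec(n_lipids = 24, n_frames = 10, pore_radius = 9,
                         seed = 23)
  r <- gen_bilayer_trajectory(spec)
  rho <- water_density_center(r$trajectory)
  expect_lt(abs(rho - r$truth$core_water_density) / r$truth$core_water_density,
            0.10)
})

test_that("pore detection recovers constructed pores and rejects broken ones", {
  r <- gen_bilayer_trajectory(synthetic_spec(n_lipids = 24, n_frames = 12,
                                             pore_radius = 7.5, seed = 31))
  pr <- detect_pore(r$trajectory)
  expect_true(pr$spanning)
  expect_lt(abs(pr$diameter_max - 15), 2)
  expect_lte(pr$diameter_min, pr$diameter_max)
  expect_identical(pr$frame_of_onset, 700)  # first post-equilibration frame

  dry <- gen_bilayer_trajectory(synthetic_spec(n_lipids = 24, n_frames = 8,
                                               seed = 32))
  expect_false(detect_pore(dry$trajectory)$spanning)
})

test_that("two disjoint half-channels do not count as a spanning pore", {
  np <- 60
  build <- function(zw) {
    pxyz <- cbind(runif(np, 0, 4), runif(np, 0, 4),
                  5 + 1.93 * rep(c(1, -1), each = np / 2))
    wxyz <- cbind(2, 2, zw)
    nm <- c(rep("P", np), rep("OW", length(zw)))
    rn <- c(rep("POPC", np), rep("SOL", length(zw)))
    make_manual_traj(nm, rn, c(rep(30.974, np), rep(18.015, length(zw))),
                     c(seq_len(np), rep(NA_integer_, length(zw))),
                     rbind(pxyz, wxyz), c(4, 4, 10))
  }
  set.seed(44)
  # gap of 0.6 nm at the midplane > 0.35 nm linkage cutoff
  broken <- build(c(seq(3.2, 4.7, by = 0.2), seq(5.3, 6.8, by = 0.2)))
  expect_false(detect_pore(broken, equil_time = 0)$spanning)
  connected <- build(seq(3.2, 6.8, by = 0.2))
  expect_true(detect_pore(connected, equil_time = 0)$spanning)
})

test_that("block error converges to the closed forms", {
  # iid normal: sigma / sqrt(n)
  x <- gen_ar1_series(1e4, 5, 1, 0, seed = 51)
  be <- block_error(x)
  expect_lt(abs(be$error - 0.01) / 0.01, 0.10)
  expect_equal(be$value, mean(x))

  # AR(1): sigma / sqrt(n) * sqrt((1+phi)/(1-phi))
  y <- gen_ar1_series(1e5, 0, 1, 0.9, seed = 52)
  se_true <- 1 / sqrt(1e5) * sqrt(1.9 / 0.1)
  bey <- block_error(y)
  expect_lt(abs(bey$error - se_true) / se_true, 0.15)
  # positively autocorrelated data must not report below the naive SE
  expect_gte(bey$error, sd(y) / sqrt(1e5))

  expect_identical(block_error(rep(2.5, 100))$error, 0)
  expect_error(block_error(rnorm(10)), ">= 16")
})

test_that("relative change is a plain percentage", {
  expect_identical(relative_change(110, 100), 10)
  expect_identical(relative_change(100, 100), 0)
  expect_identical(relative_change(90, 100), -10)
  expect_error(relative_change(1, 0), "non-zero")
})

test_that("metrics are invariant under rigid translation and lipid relabeling", {
  spec <- synthetic_spec(n_lipids = 12, n_frames = 6, tilt = 18, seed = 61)
  traj <- gen_bilayer_trajectory(spec)$trajectory
  ref_apl <- area_per_lipid(traj, 6)$value
  ref_scd <- order_parameter(traj)$mean_scd
  ref_th <- bilayer_thickness(density_profile(traj, phosphate_selection))$value
  ref_w <- water_density_center(traj)

  shift <- c(0.31, -0.12, 0.57)
  tr2 <- traj
  tr2$frames <- lapply(traj$frames, function(f) {
    f$xyz <- sweep(f$xyz, 2, shift, "+")
    for (k in 1:3) f$xyz[, k] <- f$xyz[, k] %% f$box[k]
    f
  })
  expect_equal(area_per_lipid(tr2, 6)$value, ref_apl, tolerance = 1e-12)
  expect_equal(order_parameter(tr2)$mean_scd, ref_scd, tolerance = 1e-9)
  expect_equal(bilayer_thickness(density_profile(tr2, phosphate_selection))$value,
               ref_th, tolerance = 0.11 + 1e-9)  # binning may shift by one bin
  expect_equal(water_density_center(tr2), ref_w, tolerance = 1e-9)

  # relabel lipid ids by a permutation
  tr3 <- traj
  ids <- unique(na.omit(tr3$particles$lipid_id))
  set.seed(1); perm <- sample(ids)
  tr3$particles$lipid_id <- perm[match(tr3$particles$lipid_id, ids)]
  expect_equal(order_parameter(tr3)$mean_scd, ref_scd, tolerance = 1e-12)
})
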