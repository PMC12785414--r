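test_that("kabsch is exact on identical and rigidly moved point sets", {
  set.seed(1)
  pts <- matrix(rnorm(15), ncol = 3)
  fit <- kabsch(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  for (i in 1:5) {
    tr <- random_rigid()
    moved <- pts %*% t(tr$rot) + matrix(tr$trans, nrow(pts), 3, byrow = TRUE)
    fit <- kabsch(moved, pts)
    expect_equal(fit$rmsd, 0, tolerance = 1e-10)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    # rmsd invariant under a further rigid transform of either input
    tr2 <- random_rigid()
    again <- moved %*% t(tr2$rot) + matrix(tr2$trans, nrow(pts), 3, byrow = TRUE)
    expect_equal(kabsch(again, pts)$rmsd, 0, tolerance = 1e-10)
  }
})

test_that("kabsch agrees with a brute-force rotation search", {
  set.seed(42)
  for (rep in 1:3) {
    base <- matrix(rnorm(12), ncol = 3)          # 4-point toy set
    displaced <- base
    displaced[1, ] <- displaced[1, ] + c(0.3, -0.2, 0.1)  # one point moved
    tr <- random_rigid()
    mob <- displaced %*% t(tr$rot) + matrix(tr$trans, 4, 3, byrow = TRUE)
    got <- kabsch(mob, base)$rmsd
    oracle <- rmsd_rotation_search(mob, base)
    expect_equal(got, oracle, tolerance = 1e-5)
    expect_gt(got, 0)
  }
})

test_that("kabsch agrees with an established superposition routine", {
  set.seed(7)
  a <- matrix(rnorm(30), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 0.05), ncol = 3)
  got <- kabsch(b, a)$rmsd
  xa <- as.numeric(t(a)) * 10; xb <- as.numeric(t(b)) * 10  # nm -> A
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xa, mobile = xb))
  ref <- bio3d::rmsd(xa, fitted) / 10    # bio3d rounds to 3 decimals (A)
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("kabsch rejects degenerate input", {
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(matrix(0, 4, 3), matrix(0, 4, 3)), "coincident")
  expect_error(kabsch(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "different atom counts")
})

test_that("rmsd_series reports zero on copies and forced displacement exactly", {
  ca <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.3, 1), ncol = 3, byrow = TRUE)
  cro <- matrix(c(0.5, 0.5, 0.5, 0.6, 0.5, 0.5), ncol = 3, byrow = TRUE)
  f1 <- rbind(ca, cro)
  f2 <- f1; f2[5:6, 3] <- f2[5:6, 3] + 0.25   # chromophore shifted 0.25 nm
  tr <- make_traj(list(f1, f1, f2),
                  names = c("CA", "CA", "CA", "CA", "C2", "C3"),
                  resids = c(1, 2, 3, 4, 66, 66))
  ser <- rmsd_series(tr, 1L, atom_select(name = "CA"),
                     atom_select(resid = 66))
  expect_equal(ser$values[1:2], c(0, 0), tolerance = 1e-10)
  expect_equal(ser$values[3], 0.25, tolerance = 1e-10)
  expect_error(rmsd_series(tr, 1L, atom_select(name = "ZZ"),
                           atom_select(resid = 66)), "no atoms")
})

test_that("rmsf is zero for static input and exact for forced alternation", {
  ca <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  probe <- c(0.5, 0.5, 0.5)
  mk <- function(dz) rbind(ca, probe + c(0, 0, dz))
  nm <- c("CA", "CA", "CA", "CA", "P1")
  static <- make_traj(list(mk(0), mk(0), mk(0)), names = nm, resids = 1:5)
  expect_true(all(rmsf(static, fit_sel = atom_select(name = "CA"))$rmsf < 1e-12))
  expect_error(rmsf(make_traj(list(mk(0)), names = nm, resids = 1:5)),
               "two frames")
  d <- 0.2
  alt <- make_traj(list(mk(-d), mk(d), mk(-d), mk(d)), names = nm, resids = 1:5)
  prof <- rmsf(alt, fit_sel = atom_select(name = "CA"))
  expect_equal(prof$rmsf[prof$key == "5:P1"], d, tolerance = 1e-10)
  expect_true(all(prof$rmsf[prof$key != "5:P1"] < 1e-10))
})

test_that("rmsf of isotropic jitter approaches sigma * sqrt(3)", {
  sigma <- 0.02
  g <- gen_trajectory(trajectory_spec(duration = 4, frame_interval = 0.01,
                                      noise_sd = sigma, seed = 13))
  prof <- rmsf(g$trajectory, by = "residue")
  # superposition absorbs a little variance; 5% slack on the closed form
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.05)
})

test_that("delta_rmsf subtracts matched keys and is antisymmetric", {
  a <- structure(data.frame(key = c("x", "y"), rmsf = c(0.11, 0.05)),
                 class = c("fluct_profile", "data.frame"))
  b <- structure(data.frame(key = c("x", "y"), rmsf = c(0.051, 0.07)),
                 class = c("fluct_profile", "data.frame"))
  d <- delta_rmsf(a, b)
  expect_equal(d$rmsf[d$key == "x"], 0.059)
  expect_equal(delta_rmsf(a, a)$rmsf, c(0, 0))
  d2 <- delta_rmsf(b, a)
  expect_equal(d2$rmsf, -d$rmsf)
  bad <- structure(data.frame(key = c("x", "z"), rmsf = c(1, 2)),
                   class = c("fluct_profile", "data.frame"))
  expect_error(delta_rmsf(a, bad), "missing")
})

test_that("pair_distance_series measures fixed and scripted separations", {
  f <- matrix(c(0, 0, 0, 1.1, 0, 0, 0.5, 0.5, 0.5), ncol = 3, byrow = TRUE)
  tr <- make_traj(list(f, f), names = c("A1", "A2", "A3"), resids = 1:3)
  ser <- pair_distance_series(tr, atom_select(name = "A1"),
                              atom_select(name = "A2"))
  expect_equal(ser$values, c(1.1, 1.1))
  coincident <- f; coincident[2, ] <- f[1, ]
  tr2 <- make_traj(list(coincident), names = c("A1", "A2", "A3"), resids = 1:3)
  expect_equal(pair_distance_series(tr2, atom_select(name = "A1"),
                                    atom_select(name = "A2"))$values, 0)
  expect_error(pair_distance_series(tr, atom_select(resid = c(1, 2)),
                                    atom_select(name = "A3")),
               "single-atom")
})

test_that("scripted gap-breathing is recovered within noise", {
  sp <- trajectory_spec(duration = 2, frame_interval = 0.01, noise_sd = 0.005,
                        breathing = list(amplitude = 0.2, period = 1),
                        seed = 5)
  g <- gen_trajectory(sp)
  ser <- pair_distance_series(g$trajectory,
                              atom_select(name = "CA", resid = 145),
                              atom_select(name = "CA", resid = 198))
  err <- ser$values - g$truth$breathing$distance_nm
  expect_lt(max(abs(err)), 6 * 0.005 * sqrt(2))
  expect_gt(diff(range(g$truth$breathing$distance_nm)), 0.39)
})

test_that("histogram bins conserve counts and break ties to the lower bin", {
  s <- series_stat(1:3 * 0.01, c(0.05, 0.15, 0.15))
  h <- distance_histogram(s, 0.1)
  expect_equal(h$counts, c(1L, 2L))
  expect_equal(h$mode, 0.15)
  # constant series: single populated bin
  h2 <- distance_histogram(series_stat(1:4 * 0.01, rep(1.1, 4)), 0.1)
  expect_equal(sum(h2$counts > 0), 1L)
  expect_equal(h2$mode, 1.15)
  # tie: counts equal in bins 0 and 1 -> lower bin wins
  h3 <- distance_histogram(series_stat(1:4 * 0.01, c(0.02, 0.08, 0.12, 0.18)), 0.1)
  expect_equal(h3$mode, 0.05)
  # conservation on random input
  set.seed(3)
  v <- abs(rnorm(500))
  h4 <- distance_histogram(series_stat(seq_along(v) * 0.01, v), 0.07)
  expect_equal(sum(h4$counts), 500L)
  expect_true(h4$mode %in% h4$centers[h4$counts > 0])
  expect_error(distance_histogram(s, 0), "bin_width")
})
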