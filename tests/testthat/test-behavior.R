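test_that("Tait-Bryan decomposition round-trips against the matrix oracle", {
  expect_equal(unname(quaternion_to_tait_bryan(c(1, 0, 0, 0))[1, ]),
               c(0, 0, 0))
  # pure yaw of 90 degrees about y
  q_yaw <- c(cos(pi / 4), 0, sin(pi / 4), 0)
  expect_equal(unname(quaternion_to_tait_bryan(q_yaw)[1, ]), c(90, 0, 0),
               tolerance = 1e-9)
  set.seed(11)
  q <- matrix(rnorm(4000), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  ang <- quaternion_to_tait_bryan(q)
  for (i in seq_len(nrow(q))) {
    m_q <- palscale:::quat_to_matrix(q[i, ])
    m_r <- yxz_matrix(ang[i, 1], ang[i, 2], ang[i, 3])
    expect_lt(max(abs(m_q - m_r)), 1e-8)
  }
  expect_error(quaternion_to_tait_bryan(c(1, 1, 0, 0)), "non-unit")
})

test_that("angular velocity handles ramps, wraps and static traces", {
  t <- seq(0, 10, by = 1 / 90)
  q_static <- tait_bryan_to_quaternion(rep(5, length(t)), rep(-3, length(t)),
                                       rep(1, length(t)))
  tr <- data.frame(t = t, qw = q_static[, 1], qx = q_static[, 2],
                   qy = q_static[, 3], qz = q_static[, 4])
  v <- angular_velocity(tr)
  expect_lt(max(abs(c(v$vyaw, v$vpitch, v$vroll))), 1e-8)
  # linear yaw ramp at 20 deg/s
  q_ramp <- tait_bryan_to_quaternion(20 * t, rep(0, length(t)),
                                     rep(0, length(t)))
  v_r <- angular_velocity(data.frame(t = t, qw = q_ramp[, 1],
                                     qx = q_ramp[, 2], qy = q_ramp[, 3],
                                     qz = q_ramp[, 4]))
  expect_equal(mean(abs(v_r$vyaw)), 20, tolerance = 1e-6)
  expect_lt(max(abs(v_r$vpitch)), 1e-6)
  # crossing the +/-180 wrap must not produce a spike
  t2 <- seq(0, 20, by = 1 / 90)
  yaw2 <- 20 * t2 - 190
  q2 <- tait_bryan_to_quaternion(yaw2, rep(0, length(t2)), rep(0, length(t2)))
  v2 <- angular_velocity(data.frame(t = t2, qw = q2[, 1], qx = q2[, 2],
                                    qy = q2[, 3], qz = q2[, 4]))
  expect_lt(max(abs(v2$vyaw - 20)) / 20, 0.01)
  expect_error(angular_velocity(tr[c(2, 1, 3), ]), "increasing")
})

test_that("movement classification applies a strict threshold monotonically", {
  expect_equal(classify_movement(c(2, 3, 1)), "static")
  expect_equal(classify_movement(c(2, 30, 1)), "dynamic")
  expect_equal(classify_movement(c(10, 10, 10)), "static")  # strict
  expect_equal(classify_movement(c(10.001, 10, 10)), "dynamic")
  # monotone: raising any component never flips dynamic -> static
  base <- c(4, 9, 2)
  for (k in 1:3) {
    up <- base
    up[k] <- 50
    expect_equal(classify_movement(up), "dynamic")
  }
})

test_that("gaze area matches the smoothed-Gaussian closed form", {
  # point cloud at a single location: area of the KDE itself
  pt <- matrix(rep(c(0, 0), 50), ncol = 2, byrow = TRUE)
  a_pt <- gaze_area(pt + rnorm(100, 0, 1e-9), bandwidth = 2)
  expect_equal(a_pt, gauss_disc_area_pct(2), tolerance = 0.15)
  # isotropic Gaussian of sd 5, smoothed by bandwidth 2
  g <- simulate_gaze(observer_profile(gaze_sd = 5, gaze_center = c(0, 0),
                                      seed = 9), n = 1e4)
  a_g <- gaze_area(g, bandwidth = 2)
  expect_equal(a_g, gauss_disc_area_pct(sqrt(5^2 + 2^2)), tolerance = 0.15)
  # nested superlevel sets: more mass, strictly larger area
  expect_gt(gaze_area(g, mass = 0.95), gaze_area(g, mass = 0.5))
  # rotation symmetry within discretization error
  ll <- palscale:::binocular_lonlat(g)
  rot <- cbind(-ll[, 2], ll[, 1])
  expect_equal(gaze_area(rot), gaze_area(ll), tolerance = 0.02)
})

test_that("Mann-Whitney U agrees with enumeration and is label-symmetric", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)     # 2 / choose(6, 3) extreme assignments
  expect_equal(r$method, "exact")
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p, 1)
  # label swap: p unchanged, U maps to na*nb - U
  a <- c(0.3, 1.2, 2.2, 0.9)
  b <- c(1.5, 2.8, 3.1)
  r_ab <- mann_whitney_u(a, b)
  r_ba <- mann_whitney_u(b, a)
  expect_equal(r_ab$p, r_ba$p)
  expect_equal(r_ab$u, length(a) * length(b) - r_ba$u)
  # agreement with the stats implementation where it is exact
  w <- wilcox.test(a, b)
  expect_equal(r_ab$u, unname(w$statistic))
  expect_equal(r_ab$p, w$p.value)
  # large-sample normal path against the stats implementation
  set.seed(2)
  x <- rnorm(15)
  y <- rnorm(12, 0.8)
  r_n <- mann_whitney_u(x, y)
  expect_equal(r_n$method, "normal")
  expect_equal(r_n$p, wilcox.test(x, y, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("behavior OLS recovers effects and keeps null terms at chance", {
  ss <- default_stimuli()
  set.seed(5)
  n_rep <- 200
  false_pos <- 0
  n_terms <- 0
  for (k in seq_len(n_rep)) {
    cls <- rep(c("dynamic", "static"), length.out = 8)
    gaze <- runif(8, 1, 8)
    tab <- do.call(rbind, lapply(1:8, function(j) {
      data.frame(value = 0.1 * ss$sph + rnorm(11, 0, 0.05),
                 sph = ss$sph, add = ss$add,
                 movement_class = cls[j], gaze_area = gaze[j])
    }))
    fit <- behavior_ols(tab)
    behav <- grepl("moving|gaze", fit$term)
    false_pos <- false_pos + sum(fit$p[behav] < 0.05)
    n_terms <- n_terms + sum(behav)
    if (k == 1) {
      expect_equal(fit$estimate[fit$term == "sph"], 0.1, tolerance = 0.05)
      expect_lt(fit$p[fit$term == "sph"], 1e-10)
    }
  }
  rate <- false_pos / n_terms
  # nominal alpha = 0.05; allow binomial fluctuation around it
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_terms) + 0.01)
  # constructed collinearity must raise a naming error
  bad <- data.frame(value = rnorm(22), sph = rep(ss$sph, 2),
                    add = rep(ss$add, 2),
                    movement_class = "static", gaze_area = 3)
  expect_error(behavior_ols(bad), "collinear")
})
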