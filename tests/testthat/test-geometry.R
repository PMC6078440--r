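random_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("Kabsch superposition handles identity and rigid motion", {
  set.seed(101)
  A <- matrix(rnorm(30), ncol = 3)
  s0 <- kabsch_superpose(A, A)
  expect_equal(s0$rmsd, 0)
  expect_equal(s0$rotation, diag(3))

  R <- random_rotation()
  B <- sweep(A %*% t(R), 2, c(3, -2, 7), "+")
  s <- kabsch_superpose(A, B)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch reaches the global optimum found by a numerical oracle", {
  set.seed(103)
  for (rep in 1:5) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    s <- kabsch_superpose(A, B)
    oracle <- superpose_oracle_rmsd(A, B)
    expect_lt(abs(s$rmsd - oracle), 1e-5)
    expect_lte(s$rmsd, oracle + 1e-9) # closed form is the minimum
  }
})

test_that("Kabsch agrees with the reference library implementation", {
  set.seed(104)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A %*% t(random_rotation()) + matrix(rnorm(60, 0, 0.4), ncol = 3)
  s <- kabsch_superpose(A, B)
  ref <- bio3d::rmsd(as.vector(t(B)), as.vector(t(A)), fit = TRUE)
  expect_equal(s$rmsd, ref, tolerance = 5e-3) # bio3d rounds its value
})

test_that("Kabsch rejects malformed input", {
  A <- matrix(rnorm(30), ncol = 3)
  expect_error(kabsch_superpose(A, A[1:5, ]), "equal")
  expect_error(kabsch_superpose(A[1:2, ], A[1:2, ]), "At least 3")
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd_to_mean is zero for identical models and matches the
           closed-form jitter expectation", {
  tpl <- make_helix_template(40)
  same <- coord_ensemble(dplyr::bind_rows(lapply(1:5, function(m) {
    x <- as_tibble_ens(tpl)
    x$model <- m
    x
  })))
  r0 <- rmsd_to_mean(same, "1-40:backbone")
  expect_equal(r0$mean_rmsd, 0)
  expect_equal(r0$sd_rmsd, 0)

  # template + iid Gaussian jitter sigma: E[RMSD to mean] is
  # sigma * sqrt(3) * sqrt((m-1)/m)
  m <- 10
  sigma <- 0.3
  vals <- vapply(1:20, function(k) {
    ens <- generate_ensemble(tpl, sigma = sigma, n_models = m,
                             seed = 500 + k)
    rmsd_to_mean(ens, "1-40:heavy")$mean_rmsd
  }, numeric(1))
  expected <- sigma * sqrt(3) * sqrt((m - 1) / m)
  expect_lt(abs(mean(vals) - expected) / expected, 0.05)
})


test_that("rmsd_to_mean is invariant to rigid motion of the ensemble", {
  tpl <- make_helix_template(20)
  ens <- generate_ensemble(tpl, sigma = 0.4, n_models = 6, seed = 9)
  r1 <- rmsd_to_mean(ens, "1-20:backbone")
  R <- random_rotation()
  moved <- as_tibble_ens(ens)
  xyz <- as.matrix(moved[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1] + 11
  moved$y <- xyz[, 2] - 4
  moved$z <- xyz[, 3] + 2
  r2 <- rmsd_to_mean(coord_ensemble(moved), "1-20:backbone")
  expect_equal(r2$mean_rmsd, r1$mean_rmsd, tolerance = 1e-9)
  expect_equal(r2$per_model$rmsd, r1$per_model$rmsd, tolerance = 1e-9)
})

test_that("mean pairwise RMSD dominates mean RMSD-to-mean", {
  tpl <- make_helix_template(15)
  ens <- generate_ensemble(tpl, sigma = 0.5, n_models = 8, seed = 77)
  rtm <- rmsd_to_mean(ens, "1-15:backbone")
  sel <- parse_selection("1-15:backbone")
  coords <- lapply(1:8, function(m) solnmr:::select_coords(ens, m, sel))
  pairs <- combn(8, 2)
  pw <- apply(pairs, 2, function(ij) {
    kabsch_superpose(coords[[ij[1]]], coords[[ij[2]]])$rmsd
  })
  expect_gte(mean(pw), rtm$mean_rmsd)
})

test_that("segment RMSD is symmetric and matches the oracle on a hinge", {
  tpl <- make_helix_template(40)
  bent <- as_tibble_ens(tpl)
  hinge <- bent$resno > 20
  R <- random_rotation()
  xyz <- as.matrix(bent[hinge, c("x", "y", "z")]) %*% t(R)
  bent$x[hinge] <- xyz[, 1] + 2
  bent$y[hinge] <- xyz[, 2]
  bent$z[hinge] <- xyz[, 3] - 1
  bent <- coord_ensemble(bent)

  expect_equal(segment_rmsd(tpl, tpl, "1-40", "1-40"), 0)

  r_ab <- segment_rmsd(tpl, bent, "1-18,20-29,31-40", "1-18,20-29,31-40")
  r_ba <- segment_rmsd(bent, tpl, "1-18,20-29,31-40", "1-18,20-29,31-40")
  expect_equal(r_ab, r_ba, tolerance = 1e-9)

  sel <- parse_selection("1-18,20-29,31-40")
  ca <- function(e) {
    a <- as_tibble_ens(e)
    a <- a[a$elety == "CA" & a$resno %in% sel$residues, ]
    as.matrix(a[order(a$resno), c("x", "y", "z")])
  }
  set.seed(6)
  oracle <- superpose_oracle_rmsd(ca(tpl), ca(bent))
  expect_lt(abs(r_ab - oracle), 1e-5)

  expect_error(segment_rmsd(tpl, bent, "1-10", "1-12"), "equal")
})

test_that("selection parsing and atom sets behave as documented", {
  sel <- parse_selection("44-47,50-52:heavy")
  expect_equal(sel$residues, c(44:47, 50:52))
  expect_equal(sel$atoms, "heavy")
  expect_equal(parse_selection("1-5")$atoms, "backbone")
  expect_error(parse_selection("1-5:sidechain"), "atom set")
  expect_error(parse_selection("1-5,3-8"), "overlap")

  tpl <- make_helix_template(5)
  m_bb <- solnmr:::select_coords(tpl, 1, parse_selection("1-5:backbone"))
  expect_equal(nrow(m_bb), 15) # N, CA, C only
  m_o <- solnmr:::select_coords(tpl, 1, parse_selection("1-5:backbone_o"))
  expect_equal(nrow(m_o), 20)
  expect_error(solnmr:::select_coords(tpl, 1, parse_selection("1-9")),
               "absent")
})
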