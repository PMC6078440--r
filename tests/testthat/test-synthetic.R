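test_that("the architecture template is fixed and tiles the chain", {
  a1 <- make_dkk4_like(seed = 1)
  a2 <- make_dkk4_like(seed = 999)
  expect_identical(a1$regions, a2$regions)
  expect_identical(a1$sequence, a2$sequence)
  expect_equal(a1$regions$start[1], 19)
  expect_equal(a1$regions$end[nrow(a1$regions)], 224)
  # regions tile 19-224 without gaps or overlaps
  expect_equal(a1$regions$start[-1], a1$regions$end[-5] + 1L)
  expect_equal(as.data.frame(a1$regions[c(1, 3, 5), c("start", "end")]),
               data.frame(start = c(19L, 98L, 220L),
                          end = c(40L, 139L, 224L)))
  expect_true(all(a1$site_lost >= 140 & a1$site_lost <= 219))
  expect_true(all(a1$site_shifted %in% 19:40))
})

test_that("generation is bitwise reproducible from the seed", {
  arch <- make_dkk4_like(seed = 21)
  f1 <- generate_free_state(arch)
  f2 <- generate_free_state(arch)
  expect_identical(f1, f2)
  b1 <- generate_bound_state(arch, f1)
  b2 <- generate_bound_state(arch, f2)
  expect_identical(b1, b2)
  h1 <- generate_hetnoe_pairs(arch, f1)
  h2 <- generate_hetnoe_pairs(arch, f1)
  expect_identical(h1, h2)
  # a different seed moves the noise but not the frame
  f3 <- generate_free_state(make_dkk4_like(seed = 22))
  expect_identical(f3$shifts$residue, f1$shifts$residue)
  expect_false(identical(f3$shifts$H, f1$shifts$H))
})

test_that("free-state shifts honor the class dispersions and guarantees", {
  arch <- make_dkk4_like(seed = 33)
  free <- generate_free_state(arch)
  ref <- predict_random_coil(arch$sequence, 308, 6.5, first_residue = 19)
  prof <- secondary_shift_profile(free$shifts, ref)
  cls <- arch_cls <- solnmr:::arch_classes(arch)
  flex <- prof$combined[cls == "flexible" & !prof$missing]
  strong <- prof$combined[cls == "structured" & !prof$missing]
  expect_lt(mean(flex), 0.05)      # flexible sit near random coil
  expect_gt(mean(strong), 0.2)     # structured are dispersed

  # separation guarantee: global floor plus site clearance
  pk <- free$peaks
  P <- cbind(pk$w2, pk$w1 * 0.2)
  d <- as.matrix(dist(P))
  diag(d) <- Inf
  expect_gte(min(d), 0.05)
  res <- as.integer(sub("^[A-Z](\\d+)N-H$", "\\1", pk$label))
  site <- res %in% arch$site_lost
  expect_gte(min(d[site, !site]), 0.15)
})

test_that("bound-state generation plants exactly the requested site", {
  arch <- make_dkk4_like(seed = 44)
  free <- generate_free_state(arch)
  bnd <- generate_bound_state(arch, free)
  n_assigned_site <- sum(!is.na(free$shifts$H) &
                           free$shifts$residue %in% arch$site_lost)
  expect_equal(nrow(free$peaks) - nrow(bnd$peaks), n_assigned_site)
  expect_equal(length(bnd$truth$lost), n_assigned_site)
  # planted displacement magnitudes are inside the declared range
  planted <- bnd$truth$true_shift[bnd$truth$true_shift > 0]
  expect_equal(length(planted), length(arch$site_shifted))
  expect_true(all(planted >= 0.04 & planted <= 0.10))

  # an architecture with no binding site leaves the spectrum unchanged
  arch0 <- make_dkk4_like(seed = 44)
  arch0$site_lost <- integer()
  arch0$site_shifted <- integer()
  free0 <- generate_free_state(arch0)
  bnd0 <- generate_bound_state(arch0, free0)
  expect_equal(as.data.frame(bnd0$peaks)[, c("w1", "w2")],
               as.data.frame(free0$peaks)[, c("w1", "w2")])
})

test_that("noiseless binding curves equal the model exactly", {
  conc <- c(0, 1, 10, 30, 100, 300, 1000) * 1e-9
  curve <- generate_binding_curve(KD = 64e-9, Rmax = 1.5, conc_M = conc,
                                  sigma = 0)
  expect_equal(curve$response_nm,
               one_site_response(conc, 64e-9, 1.5))
  expect_error(generate_binding_curve(1e-7, 1, conc, sigma = -1), ">= 0")
})

test_that("generated ensembles keep the template roster", {
  tpl <- make_helix_template(12)
  ens <- generate_ensemble(tpl, sigma = 0.25, n_models = 7, seed = 5)
  expect_equal(length(unique(ens$model)), 7)
  expect_equal(nrow(ens), 7 * nrow(tpl))
  e1 <- generate_ensemble(tpl, sigma = 0.25, n_models = 7, seed = 5)
  expect_identical(as.data.frame(e1), as.data.frame(ens))
})
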