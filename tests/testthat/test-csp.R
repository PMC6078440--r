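test_that("minimal shift matches hand evaluation and the identity case", {
  st <- shift_table(data.frame(residue = 1, aa = "G", H = 8.00, N = 120.0))
  pk <- peaklist(data.frame(w1 = 121.0, w2 = 8.10))
  prof <- minimal_shift_map(st, pk)
  expect_equal(prof$min_shift, sqrt(0.1^2 + (1.0 * 0.2)^2))
  expect_equal(prof$min_shift, 0.223606797749979)

  free <- random_shift_table(25, seed = 1)
  same <- shifts_to_peaklist(free)
  prof0 <- minimal_shift_map(free, same)
  expect_true(all(prof0$min_shift == 0))

  expect_error(minimal_shift_map(free, peaklist(
    data.frame(w1 = double(), w2 = double()))), "empty")
})

test_that("minimal-shift map equals the exhaustive double-loop oracle", {
  set.seed(19)
  for (rep in 1:25) {
    n_res <- sample(5:50, 1)
    n_pk <- sample(5:80, 1)
    free <- random_shift_table(n_res)
    bound <- random_peaklist(n_pk)
    prof <- minimal_shift_map(free, bound)
    oracle <- minimal_shift_oracle(free, bound)
    expect_equal(prof$min_shift, oracle$min_shift)
    expect_equal(prof$bound_peak, oracle$bound_peak) # tie -> lower index
  }
})

test_that("adding bound peaks never increases any minimal shift", {
  set.seed(23)
  free <- random_shift_table(40)
  bound <- random_peaklist(50)
  extra <- random_peaklist(20)
  extra$label <- paste0("extra_", extra$label)
  prof1 <- minimal_shift_map(free, bound)
  prof2 <- minimal_shift_map(
    free, peaklist(rbind(as.data.frame(bound), as.data.frame(extra))))
  expect_true(all(prof2$min_shift <= prof1$min_shift))
})

test_that("minimal shift underestimates the true perturbation", {
  arch <- make_dkk4_like(seed = 11)
  free <- generate_free_state(arch)
  bnd <- generate_bound_state(arch, free)
  prof <- minimal_shift_map(free$shifts, bnd$peaks)
  truth <- bnd$truth
  surv <- prof$residue %in% truth$residue
  true_shift <- truth$true_shift[match(prof$residue[surv], truth$residue)]
  expect_true(all(prof$min_shift[surv] <= true_shift + 1e-12))
})

test_that("lost-peak detection is exact on generated data", {
  arch <- make_dkk4_like(seed = 13)
  free <- generate_free_state(arch)
  bnd <- generate_bound_state(arch, free)

  # bound identical to free: nothing lost
  none <- detect_lost_peaks(free$shifts, free$peaks, radius = 0.15)
  expect_false(any(none$lost))

  lost <- detect_lost_peaks(free$shifts, bnd$peaks, radius = 0.15)
  expect_setequal(lost$residue[lost$lost], bnd$truth$lost)

  # infinite radius: nothing is ever lost
  inf_r <- detect_lost_peaks(free$shifts, bnd$peaks, radius = 1e6)
  expect_false(any(inf_r$lost))

  expect_error(detect_lost_peaks(free$shifts, bnd$peaks, radius = 0),
               "> 0")
})

test_that("height floors can declare weak peaks lost", {
  st <- shift_table(data.frame(residue = 1:2, aa = c("G", "A"),
                               H = c(8.0, 8.6), N = c(109, 122)))
  bound <- peaklist(data.frame(w1 = c(109, 122), w2 = c(8.0, 8.6),
                               height = c(1e6, 1e3)))
  flags <- detect_lost_peaks(st, bound, radius = 0.1,
                             height_floor = 1e4)
  expect_equal(flags$lost, c(FALSE, TRUE))
})

test_that("binding-region inference reports the planted sites by segment", {
  arch <- make_dkk4_like(seed = 17)
  free <- generate_free_state(arch)
  bnd <- generate_bound_state(arch, free)
  ref <- predict_random_coil(arch$sequence, 308, 6.5, first_residue = 19)
  seg <- segment_regions(secondary_shift_profile(free$shifts, ref))

  prof <- minimal_shift_map(free$shifts, bnd$peaks, lost_radius = 0.15)
  rep_ <- infer_binding_regions(prof, seg)
  tight <- rep_[rep_$type == "tight_site", ]
  expect_equal(nrow(tight), 1)
  expect_equal(c(tight$start, tight$end), c(140, 219))
  expect_match(tight$segments, "structured")
  weak <- rep_[rep_$type == "weak_perturbation", ]
  weak_res <- unlist(purrr::map2(weak$start, weak$end, seq))
  expect_setequal(weak_res, arch$site_shifted)

  # no perturbation at all: empty report
  prof0 <- minimal_shift_map(free$shifts, free$peaks, lost_radius = 0.15)
  rep0 <- infer_binding_regions(prof0, seg)
  expect_equal(nrow(rep0), 0)
})

test_that("short lost runs are isolated losses, not sites", {
  st <- random_shift_table(30, seed = 3)
  pk <- shifts_to_peaklist(st)
  # delete a single residue's peak
  pk2 <- peaklist(as.data.frame(pk)[-10, ])
  prof <- minimal_shift_map(st, pk2, lost_radius = 1e-6)
  seg <- segment_regions(secondary_shift_profile(st, st),
                         threshold = 0.1)
  rep_ <- infer_binding_regions(prof, seg)
  expect_true("isolated_loss" %in% rep_$type)
  expect_false("tight_site" %in% rep_$type)
})
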