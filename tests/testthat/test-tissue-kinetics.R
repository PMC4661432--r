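wb_pop <- function() wholebody_params(k_pc = 0.0096, k_cp = 0.0163,
                                      A_wb = 0.105, B_wb = 0.14)

test_that("whole-body model matches the ODE oracle and conserves activity", {
  skip_if_not_installed("deSolve")
  p <- wb_pop()
  mr <- 40
  kel <- 0.105 * mr^0.14
  inf <- infusion_record(185, 0, 0.5)
  tt <- c(0.25, 1, 4, 24, 96, 168)
  wb <- predict_wholebody(p, mr, inf, tt)
  ora <- ode_oracle(p$k_pc, p$k_cp, kel, inf, tt)
  expect_lt(max(abs(wb - (ora$central + ora$peripheral)) /
                  (ora$central + ora$peripheral)), 1e-6)
  # just after a bolus-limit infusion nothing has been eliminated
  wb0 <- predict_wholebody(p, mr, infusion_record(185, 0, 1e-4), 1e-4)
  expect_equal(wb0, 185, tolerance = 1e-4)
  # terminal slope equals the slow eigenvalue
  lb <- log(2) / halflives(two_compartment_params(p$k_pc, p$k_cp,
                                                  kel))["beta"]
  tail <- predict_wholebody(p, mr, inf, c(600, 700))
  expect_equal((log(tail[1]) - log(tail[2])) / 100, unname(lb),
               tolerance = 1e-6)
  expect_error(predict_wholebody(p, -1, inf, tt), "positive")
})

test_that("organ model matches the ODE oracle and is linear in activity", {
  skip_if_not_installed("deSolve")
  p <- wb_pop()
  mr <- 40
  kel <- 0.105 * mr^0.14
  inf <- infusion_record(185, 0, 0.5)
  inp <- wholebody_input(p, mr, inf, vc = 12)
  tp <- tissue_params(4.35e-3, 2.22e-2, 5.91e-2, 0.31)  # kidney-like
  tt <- c(0.25, 0.5, 1, 4, 24, 96, 168)
  pred <- predict_tissue(inp, tp, tt)
  ora <- ode_oracle(p$k_pc, p$k_cp, kel, inf, tt,
                    k_on = 4.35e-3, k_off = 2.22e-2)
  oracle <- 5.91e-2 * 0.31 * ora$central / 12 + ora$store
  expect_lt(max(abs(pred - oracle) / oracle), 1e-6)
  # linear in administered activity
  inp2 <- wholebody_input(p, mr, infusion_record(370, 0, 0.5), vc = 12)
  expect_equal(predict_tissue(inp2, tp, tt), 2 * pred, tolerance = 1e-10)
  # degenerate organ: no uptake, no fraction
  expect_equal(predict_tissue(inp, tissue_params(0, 0, 0, 1), tt),
               rep(0, length(tt)))
})

test_that("tissue store approaches k_on * A0 / k_off at steady state", {
  # quasi-constant central activity: negligible elimination and exchange
  p <- wholebody_params(3e-8, 0, 1e-8, 0)
  inp <- wholebody_input(p, 1, infusion_record(100, 0, 0.5), vc = 10)
  tp <- tissue_params(k_on = 0.02, k_off = 0.5, fraction = 0,
                      tissue_mass = 1)
  d_inf <- predict_tissue(inp, tp, 5000)
  expect_equal(d_inf, 0.02 * 100 / 0.5, tolerance = 1e-3)
})

test_that("noise-free organ curves are recovered by the population fit", {
  p <- wb_pop()
  tt <- c(1, 4, 24, 48, 96, 168)
  pts <- list(list(id = "P1", mr = 30, act = 185, vc = 11),
              list(id = "P2", mr = 80, act = 185, vc = 13))
  inputs <- list()
  curves <- list()
  for (pt in pts) {
    inp <- wholebody_input(p, pt$mr, infusion_record(pt$act, 0, 0.5),
                           vc = pt$vc)
    inputs[[paste(pt$id, "S1", sep = ".")]] <- inp
    for (org in c("kidneys", "liver")) {
      tp <- if (org == "kidneys") tissue_params(4.35e-3, 2.22e-2,
                                                5.91e-2, 0.31)
            else tissue_params(1.45e-3, 1.14e-2, 2.33e-2, 1.8)
      curves[[paste(pt$id, org)]] <- data.frame(
        patient_id = pt$id, session = "S1", organ = org, time_h = tt,
        activity_MBq = predict_tissue(inp, tp, tt))
    }
  }
  fit <- fit_tissue(do.call(rbind, curves), inputs,
                    masses = c(kidneys = 0.31, liver = 1.8))
  kid <- fit[fit$organ == "kidneys", ]
  expect_equal(kid$k_on, 4.35e-3, tolerance = 1e-3)
  expect_equal(kid$k_off, 2.22e-2, tolerance = 1e-3)
  expect_equal(kid$fraction, 5.91e-2, tolerance = 1e-3)
  expect_equal(kid$level, "population")
  liv <- fit[fit$organ == "liver", ]
  expect_equal(liv$k_on, 1.45e-3, tolerance = 1e-3)
})

test_that("an all-zero organ curve yields zero uptake parameters", {
  p <- wb_pop()
  inp <- wholebody_input(p, 30, infusion_record(185, 0, 0.5), vc = 12)
  curves <- data.frame(patient_id = "P1", session = "S1", organ = "aorta",
                       time_h = c(1, 24, 96), activity_MBq = 0)
  fit <- fit_tissue(curves, list(P1.S1 = inp), masses = c(aorta = 0.1))
  expect_equal(fit$k_on, 0)
  expect_equal(fit$fraction, 0)
})

test_that("uptake rates survive noise with small median bias", {
  # 15% imaging noise, 4 time points per curve, organ fitted with the
  # shared population structure it is designed for (several records
  # with distinct input functions)
  p <- wb_pop()
  tt <- c(1, 24, 48, 96)
  mrs <- c(20, 45, 90, 120)
  vcs <- c(10, 11, 12, 13)
  acts <- c(185, 185, 2000, 2100)
  tp <- tissue_params(4.35e-3, 2.22e-2, 5.91e-2, 0.31)
  inputs <- list()
  truths <- list()
  for (i in 1:4) {
    inputs[[paste0("P", i, ".S1")]] <-
      wholebody_input(p, mrs[i], infusion_record(acts[i], 0, 0.5),
                      vc = vcs[i])
    truths[[i]] <- predict_tissue(inputs[[paste0("P", i, ".S1")]], tp, tt)
  }
  set.seed(99)
  ratios <- vapply(1:120, function(r) {
    curves <- do.call(rbind, lapply(1:4, function(i)
      data.frame(patient_id = paste0("P", i), session = "S1",
                 organ = "kidneys", time_h = tt,
                 activity_MBq = truths[[i]] * rlnorm(4, 0, 0.15))))
    f <- fit_tissue(curves, inputs, masses = c(kidneys = 0.31),
                    settings = fit_settings(n_restarts = 3))
    f$k_on / 4.35e-3
  }, 0)
  expect_lt(abs(median(ratios) - 1), 0.10)
})

test_that("fitted per-mass uptake preserves the generating organ order", {
  p <- wb_pop()
  tis <- tissue_table()
  tis <- tis[tis$organ != "tumor", ]
  masses <- c(lung = 1.0, liver = 1.8, kidneys = 0.31, spleen = 0.18,
              heart = 0.33, aorta = 0.10)
  inp <- wholebody_input(p, 30, infusion_record(185, 0, 0.5), vc = 12)
  tt <- c(1, 4, 24, 48, 96, 168)
  curves <- do.call(rbind, lapply(seq_len(nrow(tis)), function(i) {
    tp <- tissue_params(tis$k_on[i], tis$k_off[i], tis$fraction[i],
                        masses[tis$organ[i]])
    data.frame(patient_id = "P1", session = "S1", organ = tis$organ[i],
               time_h = tt, activity_MBq = predict_tissue(inp, tp, tt))
  }))
  fit <- fit_tissue(curves, list(P1.S1 = inp), masses = masses)
  fit <- fit[match(tis$organ, fit$organ), ]
  expect_equal(cor(fit$k_on, tis$k_on, method = "spearman"), 1)
  # kidneys and liver lead lungs/spleen, aorta and heart trail
  expect_gt(fit$k_on[fit$organ == "kidneys"],
            fit$k_on[fit$organ == "lung"])
  expect_gt(fit$k_on[fit$organ == "lung"],
            fit$k_on[fit$organ == "heart"])
})

test_that("modeled organ activities never exceed whole-body activity", {
  pt <- sample_patient(seed = 31, cohort = "II")
  tr <- simulate_trial(pt, noise = noise_config(serum_cv = 0,
                                                imaging_cv = 0),
                       seed = 31)
  for (ses in c("S1", "S2")) {
    wb <- predict_wholebody(pt$wb, tr[[ses]]$mr,
                            tr[[ses]]$hapten_infusion,
                            tr$noise$imaging_times)
    tot <- tapply(tr[[ses]]$organs$activity_MBq,
                  tr[[ses]]$organs$time_h, sum)
    tot <- tot[as.character(tr$noise$imaging_times)]
    expect_true(all(tot <= wb + 1e-9))
  }
})

test_that("organ curves with too few points are rejected", {
  p <- wb_pop()
  inp <- wholebody_input(p, 30, infusion_record(185, 0, 0.5), vc = 12)
  curves <- data.frame(patient_id = "P1", session = "S1",
                       organ = "liver", time_h = c(1, 24),
                       activity_MBq = c(1, 2))
  expect_error(fit_tissue(curves, list(P1.S1 = inp),
                          masses = c(liver = 1.8)), "fewer than 3")
})
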