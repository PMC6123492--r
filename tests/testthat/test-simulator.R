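G21 <- substr(strrep("ACGC", 6), 1, 21)  # U-free 21-nt guide

test_that("make_substrate computes overhangs per binding mode", {
  # duplex with 6-nt 3' overhang (a miR166:T6-style substrate)
  d6 <- make_substrate(G21, 6, "DUPLEX")
  expect_equal(overhang(d6), 6)
  expect_equal(d6$paired_len, 15)
  # free ssRNA: the whole guide is the overhang
  expect_equal(overhang(make_substrate(G21, mode = "SS")), 21)
  # AGO-bound: only the PAZ-displaced stretch is accessible
  expect_equal(overhang(make_substrate(G21, 3, "AGO_BOUND")), 3)
  # overhang longer than the guide is a construction error
  expect_error(make_substrate(G21, 25, "DUPLEX"), "guide length")
  expect_error(make_substrate(G21, NULL, "DUPLEX"), "required")
})

test_that("engagement requires pocket-depth overhang and active enzyme", {
  enz <- enzyme_params(engage_factor = 1)
  # overhang below the 4-nt pocket depth can never engage
  set.seed(1)
  expect_false(can_engage(make_substrate(G21, 2, "DUPLEX"), enz))
  expect_false(can_engage(make_substrate(G21, 0, "DUPLEX"), enz))
  # o = 6, engage_factor 1, unmethylated: always engages
  expect_true(all(replicate(50, can_engage(make_substrate(G21, 6, "DUPLEX"),
                                           enz))))
  # catalytically dead never engages
  expect_false(can_engage(make_substrate(G21, 6, "DUPLEX"),
                          sdn_preset("D283A")))
})

test_that("methylation reduces engagement frequency to alpha_me", {
  enz <- enzyme_params(engage_factor = 1, alpha_me = 0.1)
  sub <- make_substrate(G21, 6, "DUPLEX", methylated = TRUE)
  set.seed(2024)
  n <- 10000L
  freq <- mean(replicate(n, can_engage(sub, enz)))
  # binomial check: 0.1 within 4 sd = 4 * sqrt(0.1 * 0.9 / 10000) = 0.012
  expect_lt(abs(freq - 0.1), 0.012)
})

test_that("single-molecule hand traces follow the cutting rules", {
  enz1 <- enzyme_params(p_proc = 1)
  # free 21-nt ssRNA, fully processive, one encounter: trimmed to the 4-nt
  # floor (the pocket-depth product size)
  set.seed(5)
  out <- simulate_molecule(make_substrate(G21, mode = "SS"), enz1,
                           max_rounds = 1)
  expect_equal(out$final_length, 4)
  expect_equal(out$cuts, 17)
  # duplex overhang 6 -> 5 -> 4 -> 3 -> 2, stopping at the 2-nt floor
  set.seed(5)
  outd <- simulate_molecule(make_substrate(G21, 6, "DUPLEX"), enz1,
                            max_rounds = 1)
  expect_equal(outd$final_length - 15, 2)
  expect_equal(outd$cuts, 4)
  # overhang 2 is untouched over any number of rounds
  set.seed(5)
  out2 <- simulate_molecule(make_substrate(G21, 2, "DUPLEX"), enz1,
                            max_rounds = 50)
  expect_equal(out2$final_length, 21)
  expect_equal(out2$cuts, 0)
})

test_that("catalytic-dead enzymes are the identity map on lengths", {
  set.seed(9)
  for (sub in list(make_substrate(G21, mode = "SS"),
                   make_substrate(G21, 6, "DUPLEX"),
                   make_substrate(G21, 5, "AGO_BOUND"),
                   make_substrate(G21, 6, "DUPLEX", methylated = TRUE))) {
    res <- simulate_ensemble(sub, sdn_preset("D283A"), n = 200, seed = 31)
    expect_true(all(res$molecules$final_length == 21))
    expect_true(all(res$molecules$cuts == 0))
  }
})

test_that("lengths are non-increasing and never cross the floor", {
  set.seed(77)
  for (rep in 1:30) {
    mode <- sample(c("SS", "DUPLEX", "AGO_BOUND"), 1L)
    o <- if (mode == "SS") NULL else sample(0:8, 1L)
    sub <- make_substrate(random_rna(sample(18:24, 1L)), o, mode,
                          methylated = stats::runif(1) < 0.3)
    enz <- enzyme_params(p_proc = stats::runif(1),
                         engage_factor = stats::runif(1),
                         mn_mode = stats::runif(1) < 0.2)
    out <- simulate_molecule(sub, enz, max_rounds = sample(1:30, 1L))
    expect_lte(out$final_length, sub$g)
    floor_len <- switch(mode,
                        SS = enz$L_floor,
                        DUPLEX = if (enz$mn_mode) enz$L_floor else
                          sub$paired_len + enz$f_duplex,
                        AGO_BOUND = sub$g - sub$accessible_3p)
    if (out$cuts > 0) expect_gte(out$final_length, floor_len)
  }
})

test_that("seeded ensembles are exactly reproducible", {
  sub <- make_substrate(G21, 6, "DUPLEX")
  a <- simulate_ensemble(sub, sdn_preset("WT"), tailing_params(0.3, 2),
                         n = 300, seed = 123)
  b <- simulate_ensemble(sub, sdn_preset("WT"), tailing_params(0.3, 2),
                         n = 300, seed = 123)
  expect_identical(a$molecules, b$molecules)
  c_ <- simulate_ensemble(sub, sdn_preset("WT"), tailing_params(0.3, 2),
                          n = 300, seed = 124)
  expect_false(identical(a$molecules, c_$molecules))
})

test_that("trimmed duplex products end with 2-3 nt overhangs", {
  res <- simulate_ensemble(make_substrate(G21, 6, "DUPLEX"),
                           sdn_preset("WT"), n = 2000, seed = 7)
  over <- res$molecules$final_length - 15
  trimmed <- res$molecules$cuts > 0
  expect_true(all(trimmed))  # engage_factor 1, 50 rounds
  expect_true(all(over[trimmed] %in% c(2, 3)))
  expect_true(all(c(2, 3) %in% over))  # both endpoints occur
})

test_that("Mn2+ mode degrades a methylated duplex to the ssRNA floor", {
  res <- simulate_ensemble(make_substrate(G21, 6, "DUPLEX",
                                          methylated = TRUE),
                           sdn_preset("WT", mn_mode = TRUE),
                           n = 300, max_rounds = 200, seed = 15)
  expect_true(all(res$molecules$final_length == 4))
  # but short overhangs still resist engagement in Mn2+ mode
  res2 <- simulate_ensemble(make_substrate(G21, 2, "DUPLEX",
                                           methylated = TRUE),
                            sdn_preset("WT", mn_mode = TRUE),
                            n = 100, max_rounds = 200, seed = 15)
  expect_true(all(res2$molecules$final_length == 21))
})

test_that("more encounter rounds never decrease trimming on average", {
  sub <- make_substrate(G21, 5, "AGO_BOUND")
  enz <- sdn_preset("2FA")
  means <- vapply(c(1, 5, 20, 50), function(r) {
    res <- simulate_ensemble(sub, enz, n = 1500, max_rounds = r, seed = 99)
    mean(21 - res$molecules$final_length)
  }, numeric(1))
  # non-decreasing up to Monte-Carlo jitter at the saturation plateau
  expect_true(all(diff(means) >= -0.02))
  expect_gt(means[3], means[1])
})

test_that("competition without cold RNA reduces to the labeled ensemble", {
  sub <- make_substrate(G21, mode = "SS")
  cmp <- simulate_competition(sub, n_labeled = 400, n_cold = 0,
                              enz = sdn_preset("WT"), seed = 21)
  # every labeled molecule sees many encounters; WT drives all to floor
  expect_true(all(cmp$molecules$final_length == 4))
})

test_that("cold competitor separates distributive from processive enzymes", {
  sub <- make_substrate(G21, mode = "SS")
  dis <- simulate_competition(sub, n_labeled = 1500, n_cold = 6e6,
                              enz = sdn_preset("2FA"), seed = 8)
  td <- dis$truncation_dist
  mode_t <- as.integer(names(td)[which.max(td)])
  expect_true(mode_t %in% c(1, 2))
  pro <- simulate_competition(sub, n_labeled = 400, n_cold = 1.6e6,
                              enz = sdn_preset("WT"), seed = 8)
  # processive enzyme reaches near-floor lengths for most labeled molecules
  expect_gt(mean(pro$molecules$final_length <= 6), 0.8)
  # qualitative ordering: distributive trims far less
  expect_lt(mean(21 - dis$molecules$final_length),
            mean(21 - pro$molecules$final_length))
})

test_that("processivity estimator matches its closed form and errors", {
  expect_equal(estimate_processivity(rep(1L, 20))$p_hat, 0)
  expect_equal(estimate_processivity(rep(10L, 50))$p_hat, 0.9)
  expect_error(estimate_processivity(integer()), "no cut counts")
  expect_error(estimate_processivity(c(2L, 0L)), "at least one cut")
})

test_that("processivity is recovered from simulated cut counts", {
  # single-encounter molecules on a long guide so the floor never censors
  guide <- strrep("AC", 100)
  for (p in c(0.3, 0.7)) {
    res <- simulate_ensemble(make_substrate(guide, mode = "SS"),
                             enzyme_params(p_proc = p, engage_factor = 1,
                                           alpha_me = 1),
                             n = 4000, max_rounds = 1, seed = 55)
    cuts <- res$molecules$cuts[res$molecules$engagements == 1]
    est <- estimate_processivity(cuts)
    expect_lt(abs(est$p_hat - p), 3 * est$se + 1e-6)
  }
})
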