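test_that("annihilation is all-or-none at the complementarity threshold", {
  lib <- test_library()
  mk <- function(antis) assemble_repressor(antis, lib$theophylline)
  a <- random_test_rna(20L, 5)
  expect_equal(annihilate(mk(a), mk(reverse_complement(a))), 0)
  expect_equal(annihilate(mk(strrep("A", 20)), mk(strrep("A", 20))), 1)

  # exactly 16 of 20 complementary: at the threshold boundary -> 0
  b <- reverse_complement(a)
  # a base never complements itself, so copying a's bases breaks 4 matches
  substr(b, 1, 4) <- paste(rev(strsplit(substr(a, 17, 20), "")[[1]]),
                           collapse = "")
  n_comp <- sum(strsplit(a, "")[[1]] ==
                  chartr("ACGU", "UGCA", rev(strsplit(b, "")[[1]])))
  expect_equal(n_comp, 16L)
  expect_equal(annihilate(mk(a), mk(b)), 0)
  expect_equal(annihilate(mk(a), mk(b), threshold = 17L), 1)
})

test_that("digitisation thresholds at the calibrated midpoint", {
  expect_identical(digitize(10, 10, 1), 1L)
  expect_identical(digitize(1, 10, 1), 0L)
  expect_identical(digitize(5.5, 10, 1), 1L)      # midpoint counts as ON
  expect_identical(digitize(5.4999, 10, 1), 0L)
  expect_error(digitize(1, 1, 1), "strictly greater")
})

pool <- demo_device_pool(seed = 1)

test_that("all seven gate truth tables match the expected logic", {
  expected <- list(AND = c(0, 0, 0, 1), NAND = c(1, 1, 1, 0),
                   OR = c(0, 1, 1, 1), NOR = c(1, 0, 0, 0),
                   XOR = c(0, 1, 1, 0), XNOR = c(1, 0, 0, 1))
  for (g in names(expected)) {
    tt <- simulate_gate(build_gate(g, pool$devices, inputs = pool$inputs))
    expect_identical(nrow(tt), 4L)
    expect_equal(tt$digital, expected[[g]], info = g)
  }
  for (lig in c("theophylline", "tetracycline")) {
    tt <- simulate_gate(build_gate("NOT", pool$devices,
                                   inputs = pool$inputs[lig]))
    expect_equal(tt$digital, c(1, 0), info = lig)
  }
})

test_that("gate recipes reject unusable pools", {
  # AND demands individually weak activators: a strong-only pool fails
  strong_only <- Filter(function(d) {
    d$design$topology == "switch_activator" &&
      d$design$scores$composite > 0.5
  }, pool$devices)
  expect_error(build_gate("AND", strong_only, inputs = pool$inputs),
               "no weak switch_activator")

  # XOR requires a complementary antisense pair among strong activators
  no_pair <- pool$devices[c("swi_theophylline_s5", "swi_tetracycline_s35")]
  expect_error(build_gate("XOR", no_pair, inputs = pool$inputs),
               "complementary")

  # repressor gates use the capped reporter; overriding is an error
  expect_error(build_gate("NOT", pool$devices, inputs = pool$inputs,
                          reporter_mode = "uncapped"), "capped")
})

test_that("symmetric gates are invariant under input swap", {
  for (g in c("AND", "OR", "XOR")) {
    spec <- build_gate(g, pool$devices, inputs = pool$inputs)
    # make the device parameters symmetric, keep the wiring
    for (k in seq_along(spec$devices)) {
      spec$devices[[k]]$params <- regulation_params(K = 100, h = 1.5,
                                                    Emax_r = 0.9, Fmax = 15)
      spec$devices[[k]]$design$scores$composite <- 0.9
    }
    spec$inputs[] <- 1000
    tt <- simulate_gate(spec)
    swapped <- tt[order(tt[[2L]], tt[[1L]]), ]
    expect_equal(tt$analog, swapped$analog, tolerance = 1e-12, info = g)
  }
})

test_that("network models validate their wiring", {
  sp <- data.frame(name = c("A", "B"), production = 1, decay = 0.1, init = 0)
  expect_error(network_model(sp, list(list(sensor = "A", target = "Z",
                                           sign = "activate",
                                           params = regulation_params()))),
               "undeclared")
  expect_error(network_model(data.frame(name = "A", production = 0,
                                        decay = 0.1, init = 0)),
               "> 0")
})

test_that("with no edges each species relaxes to production/decay", {
  sp <- data.frame(name = c("A", "B"), production = c(1, 2),
                   decay = c(0.1, 0.5), init = c(0, 0))
  traj <- simulate_network(network_model(sp), t_end = 120, dt = 0.05)
  final <- traj[nrow(traj), ]
  expect_equal(final$A, 10, tolerance = 1e-5)
  expect_equal(final$B, 4, tolerance = 1e-5)
  # closed form along the way: x(t) = x_inf (1 - exp(-d t))
  mid <- traj[which.min(abs(traj$time - 10)), ]
  expect_equal(mid$A, 10 * (1 - exp(-0.1 * mid$time)), tolerance = 1e-6)
})

test_that("negative feedback loop is stable and directional", {
  model <- opn_vegf_loop("negative")
  base <- simulate_network(model, t_end = 60, dt = 0.01)
  ss <- unlist(base[nrow(base), c("OPN", "VEGF")])

  # transient VEGF spike: OPN drops, then returns to within 1% of its SS
  traj <- simulate_network(model, t_end = 160, dt = 0.01,
                           perturbations = data.frame(time = 60,
                                                      species = "VEGF",
                                                      action = "set",
                                                      value = 25))
  during <- traj$OPN[traj$time > 60 & traj$time < 75]
  expect_lt(min(during), ss[["OPN"]] * 0.95)
  expect_lt(abs(traj$OPN[nrow(traj)] - ss[["OPN"]]) / ss[["OPN"]], 0.01)

  # sustained VEGF overexpression suppresses OPN; knockdown restores it
  kd <- simulate_network(model, t_end = 160, dt = 0.01,
                         perturbations = data.frame(
                           time = c(60, 100), species = "VEGF",
                           action = "production", value = c(10, 0.05)))
  opn_suppressed <- kd$OPN[which.min(abs(kd$time - 100))]
  expect_lt(opn_suppressed, ss[["OPN"]] * 0.7)
  expect_gt(kd$OPN[nrow(kd)], opn_suppressed * 1.5)
})

test_that("positive feedback loop amplifies", {
  model <- opn_vegf_loop("positive")
  base <- simulate_network(model, t_end = 120, dt = 0.01)
  ss <- unlist(base[nrow(base), c("OPN", "VEGF")])
  expect_gt(ss[["OPN"]], 10)   # above the unregulated steady state

  pert <- simulate_network(model, t_end = 120, dt = 0.01,
                           perturbations = data.frame(time = 40,
                                                      species = "OPN",
                                                      action = "production",
                                                      value = 3))
  expect_gt(pert$VEGF[nrow(pert)], ss[["VEGF"]] * 1.2)
})

test_that("halving the integration step leaves final states unchanged", {
  model <- opn_vegf_loop("negative")
  f1 <- simulate_network(model, t_end = 20, dt = 0.02)
  f2 <- simulate_network(model, t_end = 20, dt = 0.01)
  expect_lt(max(abs(unlist(f1[nrow(f1), -1L]) - unlist(f2[nrow(f2), -1L]))),
            1e-6)
})

test_that("rewiring uncouples transcript and protein readouts", {
  sc <- demo_scenarios(1)
  base <- rewire_scenario(0, sc$rewire$design, sc$rewire$params)
  expect_equal(base$protein, base$mrna)

  hi <- rewire_scenario(100, sc$rewire$design, sc$rewire$params)
  expect_gt(hi$mrna, base$mrna)          # transcriptional arm responds
  expect_lt(hi$protein, base$protein)    # translational arm represses

  # null connector (efficacy 0): protein tracks mRNA
  null_d <- sc$rewire$design
  null_d$scores$composite <- 0
  nullr <- rewire_scenario(100, null_d, sc$rewire$params)
  expect_equal(nullr$protein, nullr$mrna)
})

test_that("the AND classifier requires both promoter and ligand", {
  sc <- demo_scenarios(1)
  d <- sc$classifier$design
  p <- sc$classifier$params
  expect_gt(and_classifier(TRUE, TRUE, d, p), 0)
  expect_equal(and_classifier(TRUE, FALSE, d, p), 0)
  expect_equal(and_classifier(FALSE, TRUE, d, p), 0)
  expect_equal(and_classifier(FALSE, FALSE, d, p), 0)

  plain <- sc$rewire$design
  expect_error(and_classifier(TRUE, TRUE, plain, p), "ribozyme")
})

test_that("redirection moves both arms simultaneously", {
  sc <- demo_scenarios(1)
  base <- redirect_scenario(0, sc$redirect$activators, sc$redirect$repressors,
                            sc$redirect$params, sc$redirect$params)
  expect_true(all(abs(base$output - 1) < 1e-9))

  hi <- redirect_scenario(100, sc$redirect$activators, sc$redirect$repressors,
                          sc$redirect$params, sc$redirect$params)
  expect_true(all(hi$output[hi$arm == "activated"] > 1.2))
  expect_true(all(hi$output[hi$arm == "repressed"] < 0.8))

  # zero-efficacy activators decouple the activation arm
  acts0 <- lapply(sc$redirect$activators, function(d) {
    d$scores$composite <- 0
    d
  })
  dec <- redirect_scenario(100, acts0, sc$redirect$repressors,
                           sc$redirect$params, sc$redirect$params)
  expect_true(all(abs(dec$output[dec$arm == "activated"] - 1) < 1e-9))
  expect_true(all(dec$output[dec$arm == "repressed"] < 0.8))
})
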