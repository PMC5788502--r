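test_that("window enumeration respects regions, length and step", {
  tx <- transcript("t", strrep("A", 100), utr5_end = 25, cds_end = 100)
  w <- enumerate_windows(tx, "utr5", length = 20, step = 5)
  expect_equal(w$start, c(1L, 6L))
  expect_equal(w$end, c(20L, 25L))

  # region shorter than the window: empty with a warning
  tx2 <- transcript("t2", strrep("A", 100), utr5_end = 10, cds_end = 100)
  expect_warning(w2 <- enumerate_windows(tx2, "utr5", length = 20), "shorter")
  expect_identical(nrow(w2), 0L)

  # step 1 over a span of n yields n - 19 windows
  w3 <- enumerate_windows(tx, "cds", length = 20, step = 1)
  expect_identical(nrow(w3), 75L - 19L)
  expect_true(all(diff(w3$start) == 1L))

  w4 <- enumerate_windows(tx, "both", length = 20, step = 5)
  expect_true(all(w4$start == sort(w4$start)))
})

test_that("reverse complement is a correct involution", {
  expect_identical(reverse_complement("AUGC"), "GCAU")
  expect_identical(reverse_complement("AAAA"), "UUUU")
  for (seed in 1:20) {
    s <- random_test_rna(15L, seed)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("AUX"), "invalid character")
})

test_that("assembly contracts: copies, roles, module layout", {
  lib <- test_library()
  a20 <- strrep("A", 20)

  d2 <- assemble_repressor(a20, lib$theophylline, copies = 2)
  expect_identical(sum(d2$modules$kind == "aptamer"), 2L)
  expect_identical(nchar(d2$full_sequence),
                   20L + 2L * nchar(lib$theophylline$sequence))

  d1 <- assemble_repressor(a20, lib$theophylline, copies = 1, linker = "CCC")
  expect_identical(nchar(d1$full_sequence),
                   20L + 3L + nchar(lib$theophylline$sequence))

  expect_error(assemble_repressor(a20, lib$theophylline, copies = 4),
               "1, 2 or 3")
  expect_error(assemble_repressor(a20, lib$eif4g), "sensor-role")

  act <- assemble_activator(a20, lib$eif4g)
  expect_identical(act$copies, 2L)
  expect_length(act$flags, 0L)
  act1 <- assemble_activator(a20, lib$eif4g, copies = 1)
  expect_identical(act1$flags, "reduced-efficacy")
  expect_error(assemble_activator(a20, lib$theophylline), "effector-role")
})

test_that("switch assembly demands stem/antisense complementarity", {
  lib <- test_library()
  a20 <- strrep("A", 20)
  sensor <- make_switch_sensor(lib$theophylline, a20)
  expect_identical(substr(sensor$sequence, 1, 6), "UUUUUU")

  sw <- assemble_switch_activator(sensor, a20, lib$eif4g)
  expect_identical(sw$topology, "switch_activator")

  # mismatched antisense: error reports the mismatching stem positions
  bad <- strrep("AG", 10)
  expect_error(assemble_switch_activator(sensor, bad, lib$eif4g),
               "mismatch")
})

test_that("position prior is exponential in 5' distance", {
  expect_equal(position_prior(1), 1.0)
  expect_equal(position_prior(301, lambda = 300), exp(-1), tolerance = 1e-12)
  starts <- c(1, 10, 50, 200, 600)
  expect_true(all(diff(position_prior(starts)) < 0))
})

test_that("scoring measures exposedness, preservation and the prior", {
  lib <- test_library()
  # poly-A antisense on a G/C hairpin context: fully exposed, preserved
  d <- assemble_repressor(strrep("A", 20), lib$theophylline,
                          window = c(1L, 20L), region = "utr5")
  s <- score_design(d)
  expect_equal(s$exposedness, 1.0)
  expect_equal(s$preservation, 1.0)
  expect_equal(s$position_prior, 1.0)
  expect_equal(s$composite, 1.0)
  expect_true(s$pass)

  # toy chimera: hairpin plus poly-A tail, checked against the oracle
  chim <- "GGGAAACCCAAAAA"
  f <- fold(chim)
  expect_equal(f$score, oracle_max_score(chim))
  pm <- pair_partner_map(f)
  expect_true(all(is.na(pm[10:14])))          # tail unpaired
  expect_equal(pm[1:3], c(9L, 8L, 7L))        # hairpin intact

  # the antisense/window duplex is verified literally against the target
  tx <- transcript("t", paste0(strrep("U", 40), strrep("G", 60)),
                   utr5_end = 40, cds_end = 100)
  d2 <- assemble_repressor(reverse_complement(substr(tx$sequence, 5, 24)),
                           lib$theophylline, window = c(5L, 24L),
                           region = "utr5")
  expect_silent(score_design(d2, tx))
  d2$window <- c(50L, 69L)  # window no longer matches the antisense
  expect_error(score_design(d2, tx), "reverse complement")
})

test_that("scores stay within bounds on randomized designs", {
  lib <- test_library()
  for (seed in 1:500) {
    antis <- random_test_rna(20L, 1000 + seed)
    d <- assemble_repressor(antis, lib$theophylline,
                            copies = 1L + (seed %% 3L))
    s <- score_design(d)
    expect_gte(s$exposedness, 0); expect_lte(s$exposedness, 1)
    expect_gte(s$preservation, 0); expect_lte(s$preservation, 1)
    expect_gte(s$composite, 0)
    expect_lte(s$composite, min(s$exposedness, s$preservation))
  }
})

test_that("ranking filters failures and orders deterministically", {
  lib <- test_library()
  mk <- function(id, comp, ws, e = 0.9, p = 0.9) {
    d <- assemble_repressor(strrep("A", 20), lib$theophylline, id = id,
                            window = c(ws, ws + 19L))
    d$scores <- structure(list(exposedness = e, preservation = p,
                               position_prior = comp / (e * p),
                               composite = comp, pass = TRUE),
                          class = "structure_score")
    d
  }
  ds <- list(mk("a", 0.5, 40), mk("b", 0.9, 10), mk("c", 0.5, 20),
             mk("fail", 0.9, 1, e = 0.5))
  r <- rank_designs(ds)
  expect_identical(vapply(r, `[[`, character(1), "id"), c("b", "c", "a"))
  # pure function of scores: same input, same order
  expect_identical(vapply(rank_designs(ds), `[[`, character(1), "id"),
                   c("b", "c", "a"))
  expect_error(rank_designs(list(assemble_repressor(strrep("A", 20),
                                                    lib$theophylline))),
               "scored")
})

test_that("switch two-state logic responds to ligand and bonus", {
  lib <- test_library()
  a20 <- strrep("A", 20)
  sw <- assemble_switch_activator(make_switch_sensor(lib$theophylline, a20),
                                  a20, lib$eif4g)
  off <- evaluate_switch(sw, ligand_present = FALSE)
  on <- evaluate_switch(sw, ligand_present = TRUE)
  expect_identical(off$state, "OFF")
  expect_identical(on$state, "ON")
  expect_equal(on$on_score - off$on_score, lib$theophylline$binding_bonus)

  # zero bonus: ligand makes no difference
  sw0 <- sw
  sw0$sensor$binding_bonus <- 0
  s_off <- evaluate_switch(sw0, FALSE)
  s_on <- evaluate_switch(sw0, TRUE)
  expect_identical(s_off$state, s_on$state)

  # raising the bonus can only flip OFF -> ON, never back
  states <- vapply(c(0.001, 1, 3, 10, 30), function(b) {
    swb <- sw
    swb$sensor$binding_bonus <- b
    evaluate_switch(swb, TRUE)$state
  }, character(1))
  expect_true(all(diff(states == "ON") >= 0))   # OFF -> ON only
  expect_identical(states[length(states)], "ON")

  expect_error(evaluate_switch(tiny_scored_repressor(), TRUE),
               "switch_activator")
})
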