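test_that("yield deltas: arithmetic, significance and error paths", {
  d <- yield_deltas(mono_a = c(100, 100, 100), co_a = c(160, 160, 160),
                    mono_b = c(50, 50, 50), co_b = c(50, 50, 50))
  expect_equal(d$delta_a, 0.6)
  expect_equal(d$delta_b, 0)
  expect_false(d$sig_b)                     # identical arms: not significant
  # log and absolute scales
  dl <- yield_deltas(c(100, 100), c(200, 200), c(10, 10), c(10, 10),
                     scale = "log")
  expect_equal(dl$delta_a, log(2))
  da <- yield_deltas(c(100, 100), c(160, 160), c(10, 10), c(10, 10),
                     scale = "absolute")
  expect_equal(da$delta_a, 60)
  expect_error(yield_deltas(c(0, 1), c(1, 1), c(1, 1), c(1, 1)), "> 0")
  # one warning per strain arm
  expect_warning(expect_warning(d1 <- yield_deltas(100, 160, 50, 40),
                                "single replicate"), "single replicate")
  expect_true(is.na(d1$sig_a))
})

test_that("polar angle reproduces the published coordinate convention", {
  expect_equal(as.numeric(polar_angle(1, 1)), 90)      # equally facilitated
  expect_equal(as.numeric(polar_angle(-1, -1)), -90)   # equally inhibited
  expect_equal(as.numeric(polar_angle(1, -1)), 0)      # reference line y = -x
  expect_equal(as.numeric(polar_angle(0, 1)), 45)      # reflected to (1, 0)
  expect_true(attr(polar_angle(0, 1), "reflected"))
  expect_error(polar_angle(0, 0), "origin")
})

test_that("polar angle is symmetric in the unordered pair and scale-free", {
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    if (a == 0 && b == 0) next
    expect_identical(as.numeric(polar_angle(a, b)),
                     as.numeric(polar_angle(b, a)))
    k <- runif(1, 0.1, 10)
    expect_equal(as.numeric(polar_angle(k * a, k * b)),
                 as.numeric(polar_angle(a, b)), tolerance = 1e-9)
    th <- as.numeric(polar_angle(a, b))
    expect_true(th >= -90 && th <= 90)
  }
})

test_that("magnitude defaults to the Euclidean norm and is pluggable", {
  expect_equal(interaction_magnitude(3, 4), 5)
  expect_equal(interaction_magnitude(0, 0), 0)
  expect_equal(interaction_magnitude(-1, 2), interaction_magnitude(2, -1))
  expect_equal(interaction_magnitude(1, 1, formula = function(a, b) abs(a) + abs(b)),
               2)
  # scaling both deltas scales m linearly
  expect_equal(interaction_magnitude(3 * 2, 4 * 2), 10)
})

test_that("angle-mode classification partitions [-90, 90]", {
  expect_equal(classify_interaction(60), "mutualism")
  expect_equal(classify_interaction(-70), "competition")
  expect_equal(classify_interaction(-90), "equally inhibited")
  expect_equal(classify_interaction(-45), "amensalism")
  expect_equal(classify_interaction(45), "commensalism")
  expect_equal(classify_interaction(90), "equally facilitated")
  expect_equal(classify_interaction(20), "parasitism")
  expect_equal(classify_interaction(-20), "parasitism")
  expect_equal(classify_interaction(0), "parasitism")
  expect_equal(classify_interaction(0, zero_label = "neutral"), "neutral")
  # every theta receives exactly one label
  for (th in seq(-90, 90, 0.5))
    expect_length(classify_interaction(th), 1)
  expect_error(classify_interaction(120), "\\[-90, 90\\]")
})

test_that("gated mode consults significance before the angle", {
  expect_equal(classify_interaction(80, sig_a = FALSE, sig_b = FALSE,
                                    mode = "gated"), "neutral")
  expect_equal(classify_interaction(80, sig_a = TRUE, sig_b = FALSE,
                                    mode = "gated"), "commensalism")
  expect_equal(classify_interaction(-80, sig_a = FALSE, sig_b = TRUE,
                                    mode = "gated"), "amensalism")
  expect_equal(classify_interaction(60, sig_a = TRUE, sig_b = TRUE,
                                    mode = "gated"), "mutualism")
})

test_that("classifier agrees with a dense-grid region-lookup oracle", {
  grid <- seq(-2, 2, by = 0.1)
  for (a in grid) for (b in grid) {
    if (a == 0 && b == 0) next
    th <- as.numeric(polar_angle(a, b))
    th_oracle <- oracle_theta(a, b)
    expect_equal(th, th_oracle, tolerance = 1e-7,
                 info = sprintf("deltas (%g, %g)", a, b))
    expect_identical(classify_interaction(th), oracle_label(th_oracle),
                     info = sprintf("deltas (%g, %g)", a, b))
  }
})

test_that("call_interactions aggregates replicates into one call per pair", {
  cc <- simulate_coculture(n_pairs = 30, noise_sd = 0.05, seed = 5)
  calls <- call_interactions(cc$records, mode = "gated")
  expect_equal(nrow(calls), 30)
  expect_setequal(calls$pair_id, unique(cc$records$pair_id))
  expect_true(all(calls$magnitude >= 0))
  expect_true(all(is.na(calls$theta) | (calls$theta >= -90 & calls$theta <= 90)))
  expect_error(call_interactions(data.frame(pair_id = "p")), "missing column")
})

test_that("planted interaction types are recovered at low noise", {
  cc <- simulate_coculture(n_pairs = 120, noise_sd = 0.05, seed = 9)
  calls <- call_interactions(cc$records, mode = "gated")
  truth <- cc$truth$planted_interactions[calls$pair_id]
  expect_gte(mean(calls$label == truth), 0.9)
})

test_that("summaries report proportions and group comparisons", {
  cc <- simulate_coculture(n_pairs = 40, type_mix = c(mutualism = 1),
                           noise_sd = 0.02, seed = 6)
  calls <- call_interactions(cc$records, mode = "gated")
  s <- summarize_interactions(calls, by = "temperature")
  expect_true(all(s$groups$prop_mutualism == 1))
  expect_equal(sum(s$groups$n), 40)
  # identical magnitude distributions: comparison non-significant
  calls2 <- calls
  calls2$temperature <- rep(c(37, 50), length.out = nrow(calls2))
  calls2$magnitude <- 1
  s2 <- summarize_interactions(calls2, by = "temperature")
  expect_gte(s2$comparisons$p[1], 0.99)
  expect_error(summarize_interactions(calls, by = "nope"), "absent")
})

test_that("planted mutualism proportion is recovered within 5 points", {
  props <- sapply(1:10, function(s) {
    cc <- simulate_coculture(n_pairs = 100, noise_sd = 0.02, seed = s)
    calls <- call_interactions(cc$records, mode = "gated")
    mean(calls$label == "mutualism")
  })
  expect_lt(abs(mean(props) - 0.4), 0.05)
})

test_that("marker-overlap helper subtracts the partner yield", {
  expect_equal(subtract_partner_yield(c(100, 120), c(40, 50)), c(60, 70))
  expect_warning(out <- subtract_partner_yield(10, 15), "floored")
  expect_equal(out, 1e-6)
})
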