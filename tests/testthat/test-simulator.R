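test_that("working-memory duration follows its definition", {
  empty <- data.frame(neuron = integer(0), time = numeric(0))
  d0 <- wm_duration(empty, cue_offset = 1000, delay_end = 5000)
  expect_equal(as.numeric(d0), 0)
  expect_false(attr(d0, "censored"))
  one <- data.frame(neuron = 1, time = 1500)
  expect_equal(as.numeric(wm_duration(one, cue_offset = 1000,
                                      delay_end = 5000)), 500)
  # spikes through the delay end: duration capped and censored
  thru <- data.frame(neuron = rep(1, 50), time = seq(1100, 5000, length.out = 50))
  d <- wm_duration(thru, cue_offset = 1000, delay_end = 5000)
  expect_equal(as.numeric(d), 4000)
  expect_true(attr(d, "censored"))
  # spikes after delay_end are ignored
  post <- data.frame(neuron = 1, time = c(1200, 5400))
  expect_equal(as.numeric(wm_duration(post, cue_offset = 1000,
                                      delay_end = 5000)), 200)
  # population filter
  two <- data.frame(neuron = c(1, 2), time = c(2000, 4000))
  expect_equal(as.numeric(wm_duration(two, population = 1,
                                      cue_offset = 1000, delay_end = 5000)),
               1000)
})

test_that("state taxonomy thresholds", {
  expect_equal(as.character(classify_state(0, FALSE)), "silent")
  expect_equal(as.character(classify_state(199, FALSE)), "silent")
  expect_equal(as.character(classify_state(1200, FALSE)), "transient")
  expect_equal(as.character(classify_state(4000, TRUE)), "persistent")
  expect_equal(as.character(classify_state(500, FALSE, theta_s = 600)),
               "silent")
  expect_equal(levels(classify_state(0, FALSE)),
               c("silent", "transient", "persistent"))
})

test_that("per-neuron durations restrict the definition to one cell", {
  r <- data.frame(neuron = c(1, 1, 2), time = c(1500, 2500, 4990))
  pn <- per_neuron_duration(r, cue_offset = 1000, delay_end = 5000)
  expect_equal(pn$duration[pn$neuron == 1], 1500)
  expect_equal(pn$duration[pn$neuron == 2], 3990)
  expect_true(pn$censored[pn$neuron == 2])
  expect_false(pn$censored[pn$neuron == 1])
})

test_that("rate traces conserve spike counts", {
  empty <- data.frame(neuron = integer(0), time = numeric(0))
  rt0 <- rate_trace(empty, t_end = 1000, bin = 10,
                    pop_sizes = c(all = 10))
  expect_true(all(rt0$rate == 0))
  # N spikes in one bin over population P: rate = N / (P * bin)
  r <- data.frame(neuron = rep(1:5, 4), time = runif(20, 100, 110))
  rt <- rate_trace(r, t_end = 200, bin = 10, pop_sizes = c(all = 5))
  expect_equal(max(rt$rate), 20 / 5 / 0.010)
  # integral of rate x population equals the total spike count
  set.seed(31)
  r2 <- data.frame(neuron = sample(1:8, 300, TRUE),
                   time = runif(300, 0, 900))
  rt2 <- rate_trace(r2, t_end = 900, bin = 20, pop_sizes = c(all = 8))
  expect_equal(sum(rt2$rate) * 8 * 0.020, 300, tolerance = 1 / 300)
  expect_error(rate_trace(r2, t_end = 900, bin = 0), "bin")
})

test_that("trials are reproducible from their two seeds", {
  fx <- make_fixture("mini", seed = 4)
  t1 <- run_trial(fx$network, protocol = fx$protocol, seed = 21,
                  syn_scale = fx$syn_scale)
  t2 <- run_trial(fx$network, protocol = fx$protocol, seed = 21,
                  syn_scale = fx$syn_scale)
  expect_identical(t1$raster, t2$raster)
  expect_equal(as.numeric(t1$duration), as.numeric(t2$duration))
  t3 <- run_trial(fx$network, protocol = fx$protocol, seed = 22,
                  syn_scale = fx$syn_scale)
  expect_false(identical(t1$raster, t3$raster))
})

test_that("without a cue the network stays near-silent", {
  fx <- make_fixture("mini", seed = 4)
  proto <- protocol_spec(t_precue = 50, t_cue = 100, t_delay = 300,
                         t_match = 100, t_settle = 100, I_cue = 1e-6)
  tr <- run_trial(fx$network, protocol = proto, seed = 23,
                  syn_scale = fx$syn_scale)
  expect_lt(nrow(tr$raster), 10)
  expect_equal(as.numeric(tr$duration), 0, tolerance = 300)
  expect_equal(as.character(tr$state), "silent")
})

test_that("rasters export as TSV with a population header", {
  fx <- make_fixture("mini", seed = 4)
  tr <- run_trial(fx$network, protocol = fx$protocol, seed = 25,
                  syn_scale = fx$syn_scale)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_raster(tr, f)
  first <- readLines(f, n = 2)
  expect_match(first[1], "^# populations: ")
  expect_equal(first[2], "neuron\ttime")
  df <- utils::read.delim(f, skip = 1)
  expect_equal(nrow(df), nrow(tr$raster))
})

test_that("ensembles vary exactly the requested randomness source", {
  fx <- make_fixture("mini", seed = 1)
  args <- list(n = 3, seed = 7, sensory = fx$sensory,
               association = fx$association, protocol = fx$protocol,
               syn_scale = fx$syn_scale)
  both <- do.call(wm_ensemble, c(args, vary = "both"))
  topo <- do.call(wm_ensemble, c(args, vary = "topology"))
  noise <- do.call(wm_ensemble, c(args, vary = "noise"))
  expect_equal(length(unique(both$topology_seed)), 3)
  expect_equal(length(unique(topo$noise_seed)), 1)
  expect_equal(length(unique(noise$topology_seed)), 1)
  expect_equal(length(unique(noise$noise_seed)), 3)
  # reproducible end to end
  both2 <- do.call(wm_ensemble, c(args, vary = "both"))
  expect_identical(both, both2)
  wf <- do.call(wm_ensemble, c(args[names(args) != "n"], n = 2,
                               with_features = TRUE))
  expect_true(all(feature_names() %in% names(wf)))
})
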