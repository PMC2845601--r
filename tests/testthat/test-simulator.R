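test_that("degenerate simulations yield no mutations", {
  amp <- ampliconTarget("A", lengthKb = 1.0)
  zeroRate <- simulationParams(0, amp, families = 1000L, seed = 3L)
  expect_equal(sum(screenTable(simulateScreen(zeroRate))$mutations), 0L)
  blind <- simulationParams(1 / 100, amp, families = 1000L,
                            detectionProb = 0, seed = 3L)
  expect_equal(sum(screenTable(simulateScreen(blind))$mutations), 0L)
})

test_that("detected counts follow the thinned-Poisson expectation", {
  # E[m] = families * L * rate * survival * detection = 4000/300*0.75 = 10
  amp <- ampliconTarget("A", lengthKb = 1.0)
  params <- simulationParams(1 / 300, amp, families = 4000L, seed = 1234L)
  reps <- 200L
  set.seed(1234L)
  counts <- vapply(seq_len(reps), function(i)
    sum(screenTable(tillkit:::.simulateScreenCore(params))$mutations),
    numeric(1))
  expectation <- 4000 * 1.0 * (1 / 300) * 0.75
  mcse <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expectation), 3 * mcse)
})

test_that("simulation is deterministic under a fixed seed", {
  params <- simulationParams(1 / 200, ampliconTarget("A", lengthKb = 1.5),
                             families = 800L, seed = 77L)
  a <- simulateScreen(params)
  b <- simulateScreen(params)
  expect_identical(screenTable(a), screenTable(b))
  expect_identical(mutations(a), mutations(b))
  rec1 <- recoveryExperiment(params, replicates = 20L)
  rec2 <- recoveryExperiment(params, replicates = 20L)
  expect_identical(rec1, rec2)
})

test_that("simulated records are class-consistent and in bounds", {
  seq <- paste(rep("ACGT", 250), collapse = "")  # 1 kb, all bases present
  amp <- ampliconTarget("S", sequence = seq)
  params <- simulationParams(1 / 20, amp, families = 500L, seed = 5L)
  scr <- simulateScreen(params)
  recs <- mutations(scr)
  expect_gt(nrow(recs), 0L)
  expect_true(all(recs$position >= 1 & recs$position <= 1000))
  # ref bases must match the sequence at the sampled positions
  chars <- strsplit(seq, "")[[1]]
  expect_equal(chars[recs$position], recs$ref)
  # per-gene record tallies equal the screen-table counts (class validity)
  expect_equal(nrow(recs), sum(screenTable(scr)$mutations))
})

test_that("empirical class frequencies converge to the spectrum probabilities", {
  probs <- setNames(c(0.4, 0.2, 0.15, 0.15, 0.05, 0.05),
                    substitutionClasses())
  params <- simulationParams(1 / 10, ampliconTarget("A", lengthKb = 2.0),
                             families = 4000L, spectrumProbs = probs,
                             seed = 21L)
  recs <- mutations(simulateScreen(params))
  counts <- table(canonicalClass(recs$ref, recs$alt))
  expect_gt(sum(counts), 400)
  test <- suppressWarnings(chisq.test(as.integer(counts), p = probs))
  expect_gt(test$p.value, 0.01)
})

test_that("corrected estimator recovers truth; uncorrected is 4/3 high", {
  fx <- screenFixture()
  amps <- lapply(seq_along(fx$gene), function(i)
    ampliconTarget(fx$gene[i], lengthKb = fx$kb[i]))
  params <- simulationParams(1 / 322, amps, families = 1284L, seed = 2024L)
  rec <- recoveryExperiment(params, replicates = 200L)
  est <- rec$estimators
  corr <- est[est$estimator == "corrected", ]
  unc <- est[est$estimator == "uncorrected", ]
  expect_lt(abs(corr$bias_kb), 3 * corr$se_kb)
  expect_lt(abs(unc$mean_kb_per_mutation - (4 / 3) * 322), 3 * unc$se_kb)
  expect_true(corr$covers_truth)
})

test_that("imperfect detection biases even the corrected estimator", {
  # detection 0.75 inflates kb-per-mutation by 1/0.75 = 4/3
  params <- simulationParams(1 / 322,
                             ampliconTarget("A", lengthKb = 9.447),
                             families = 1284L, detectionProb = 0.75,
                             seed = 31L)
  rec <- recoveryExperiment(params, replicates = 200L)
  corr <- rec$estimators[rec$estimators$estimator == "corrected", ]
  expect_lt(abs(corr$mean_kb_per_mutation - (4 / 3) * 322), 3 * corr$se_kb)
  expect_gt(abs(corr$bias_kb), 3 * corr$se_kb)  # detectably biased
})

test_that("zero-mutation replicates are excluded and counted", {
  params <- simulationParams(1 / 50, ampliconTarget("A", lengthKb = 0.5),
                             families = 10L, seed = 8L)
  rec <- recoveryExperiment(params, replicates = 50L)
  expect_gt(rec$excluded, 0L)
  expect_true(all(is.finite(rec$estimators$mean_kb_per_mutation)))
})

test_that("simulation parameters are validated", {
  amp <- ampliconTarget("A", lengthKb = 1)
  expect_error(simulationParams(1 / 300, amp, families = 100L,
                                spectrumProbs = c(a = 1)),
               "spectrumProbs")
  expect_error(simulationParams(1 / 300, amp, families = 100L,
                                detectionProb = 1.5),
               "detectionProb")
  expect_error(recoveryExperiment(
    simulationParams(1 / 300, amp, families = 100L), replicates = 1L),
    class = "tillkit_domain_error")
})
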