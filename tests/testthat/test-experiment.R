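# experiment module: design bookkeeping, sentence lists, orchestration

test_that("default design yields 14 combos and 70 cells", {
  cells <- enumerate_conditions(study_design())
  expect_equal(nrow(attr(cells, "combos")), 14)
  expect_equal(nrow(cells), 70)
  expect_equal(anyDuplicated(cells$condition), 0)
})

test_that("condition enumeration matches a brute-force set oracle", {
  d <- study_design()
  tuples <- character(0)
  for (app in c("speech_only", "noise_only", "both")) {
    rts <- if (app == "speech_only") d$rts_speech_only else d$rts_other
    for (rt in rts) for (mod in d$modulations) for (snr in d$snr_grid) {
      a <- if (rt == d$reference_rt) "reference" else app
      tuples <- c(tuples, paste(a, rt, mod, snr))
    }
  }
  oracle <- sort(unique(tuples))
  cells <- enumerate_conditions(d)
  got <- sort(paste(cells$application, cells$rt, cells$modulation, cells$snr))
  expect_identical(got, oracle)
})

test_that("enumeration is stable under input permutation and shrinks right", {
  d1 <- study_design(rts_speech_only = c(1.5, 0.15, 0.8, 0.5, 1.1),
                     snr_grid = c(0, -8, -16, -4, -12))
  c1 <- enumerate_conditions(d1)
  c0 <- enumerate_conditions(study_design())
  expect_identical(sort(c1$condition), sort(c0$condition))
  one <- study_design(applications = "speech_only", rts_speech_only = 0.8,
                      modulations = "stationary", snr_grid = -4,
                      reference_rt = 0.15)
  expect_equal(nrow(enumerate_conditions(one)), 1)
})

test_that("sentence lists use each of the 50 words exactly once", {
  sl <- build_sentence_list(seed = 1)
  expect_length(sl, 10)
  words <- unlist(strsplit(sl, " ", fixed = TRUE))
  expect_equal(sort(as.vector(table(words))), rep(1L, 50))
  # category order: word i of each sentence comes from category i
  vocab <- matrix_vocabulary()
  for (s in strsplit(sl, " ", fixed = TRUE)) {
    expect_length(s, 5)
    for (i in 1:5) expect_true(s[i] %in% vocab[[i]])
  }
  expect_false(identical(build_sentence_list(seed = 1),
                         build_sentence_list(seed = 2)))
  expect_error(build_sentence_list(vocab[, 1:4]), "50 distinct")
  bad <- vocab; bad$name[1] <- bad$name[2]
  expect_error(build_sentence_list(bad), "50 distinct")
})

test_that("session time arithmetic", {
  expect_equal(estimate_session_time(study_design(), 12), 140)
  one <- study_design(applications = "speech_only", rts_speech_only = 0.8,
                      modulations = "stationary", snr_grid = -4)
  expect_equal(estimate_session_time(one, 12), 2)
  zero <- study_design(sentences_per_cell = 0)
  expect_equal(estimate_session_time(zero, 12), 0)
  expect_error(estimate_session_time(study_design(), 0), "positive")
})

test_that("a small replication runs end to end, deterministically", {
  r1 <- run_replication(n_per_group = 5, seed = 42, bf_method = "bic")
  r2 <- run_replication(n_per_group = 5, seed = 42, bf_method = "bic")
  expect_identical(
    jsonlite::toJSON(r1[setdiff(names(r1), c("fits", "trials"))],
                     auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(r2[setdiff(names(r2), c("fits", "trials"))],
                     auto_unbox = TRUE, digits = NA))
  expect_equal(r1$n_combos, 14)
  expect_equal(r1$n_cells, 70)
  expect_equal(r1$session_minutes, 140)
  expect_named(r1$hypotheses,
               c("H1", "H2", "H2_dipmax", "H3_1", "H3_1_dipmax",
                 "H3_2_a", "H3_2_a_dipmax", "H3_2_b", "H3_2_b_dipmax",
                 "H1_1", "H1_2"), ignore.order = TRUE)
  for (h in c("H1", "H2", "H3_1")) {
    expect_gt(r1$hypotheses[[h]]$bf10, 0)
    expect_true(r1$hypotheses[[h]]$category %in%
                c("strong_alt", "moderate_alt", "inconclusive",
                  "moderate_null", "strong_null"))
  }
  # dip benefit always reported at both analysis SNRs
  expect_true(any(grepl("optimal", names(r1$dip_benefit))))
  expect_true(any(grepl("dip_max", names(r1$dip_benefit))))
})

test_that("file outputs are written when requested", {
  out <- tempfile("rep")
  r <- run_replication(n_per_group = 4, seed = 3, bf_method = "bic",
                       out_dir = out)
  expect_true(file.exists(file.path(out, "trials.csv")))
  expect_true(file.exists(file.path(out, "fits.csv")))
  expect_true(file.exists(file.path(out, "report.json")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$n_cells, 70)
  unlink(out, recursive = TRUE)
})

test_that("a zero group-by-RT world leaves H3-1 null-leaning on average", {
  # identical group parameters: the latent group x RT interaction is null
  cfg <- effect_config(baseline_m = c(NH = -6, HI = -6),
                       width = c(NH = 9, HI = 9),
                       smear = c(NH = 2.5, HI = 2.5),
                       dip_benefit = c(NH = 1.2, HI = 1.2))
  bfs <- sapply(1:10, function(s)
    run_replication(n_per_group = 8, seed = 1000 + s, config = cfg,
                    bf_method = "bic")$hypotheses$H3_1$bf10)
  expect_gt(mean(bfs < 3), 0.5) # majority null-leaning or inconclusive
})
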