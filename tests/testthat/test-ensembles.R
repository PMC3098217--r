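# classified records reused across the table tests
local_records <- local({
  cache <- new.env(parent = emptyenv())
  function(sizes, ...) {
    key <- paste(c(sizes, ...), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- classify(build_sheet_assembly(
        sheet_spec(sizes, ...))$assembly)
    cache[[key]]
  }
})

test_that("tabulate reports 100% for a pure ensemble and honors windows", {
  recs <- rep(list(local_records(3)), 10)
  tab <- tabulate_ensemble(recs, rep(235.8, 10), window = c(1, 10))
  expect_equal(unname(tab$populations["3", 1]), 100)
  expect_equal(tab$n_frames, 10L)
  # default window keeps the final half
  tab2 <- tabulate_ensemble(recs, rep(235.8, 10))
  expect_equal(tab2$n_frames, 5L)
  expect_error(tabulate_ensemble(recs, rep(235.8, 10), window = c(11, 12)),
               "empty analysis window")
})

test_that("mixed ensembles split populations that sum to 100", {
  recs <- c(rep(list(local_records(c(2, 1))), 5),
            rep(list(local_records(c(1, 1, 1))), 5))
  tab <- tabulate_ensemble(recs, rep(300, 10), window = c(1, 10))
  expect_equal(sort(unname(tab$populations[, 1])), c(50, 50))
  expect_equal(sum(tab$populations[, 1]), 100, tolerance = 1e-3)
})

test_that("sampled multinomial populations recover generating probabilities", {
  set.seed(31)
  pool <- list(local_records(3), local_records(c(2, 1)),
               local_records(c(1, 1, 1)))
  probs <- c(0.6, 0.3, 0.1)
  draw <- sample.int(3, 2000, replace = TRUE, prob = probs)
  recs <- pool[draw]
  tab <- tabulate_ensemble(recs, rep(283.4, 2000), window = c(1, 2000))
  got <- tab$populations[c("3", "2 1", "1 1 1"), 1]
  expect_true(all(abs(got - 100 * probs) < 3))
})

test_that("ensemble normalization invariants hold across random ensembles", {
  set.seed(37)
  for (trial in 1:5) {
    recs <- lapply(1:30, function(k)
      classify(build_sheet_assembly(random_sheet_spec(12))$assembly))
    temps <- sample(c(250, 283, 300), 30, replace = TRUE)
    tab <- tabulate_ensemble(recs, temps, window = NULL)
    for (col in seq_along(tab$temperatures)) {
      expect_equal(sum(tab$populations[, col]), 100, tolerance = 0.1)
      s <- tab$stats[col, ]
      ori_sum <- s$pct_parallel + s$pct_antiparallel + s$pct_undefined
      if (!is.na(ori_sum)) expect_equal(ori_sum, 100, tolerance = 0.1)
      chr_sum <- s$pct_fully_parallel + s$pct_fully_antiparallel + s$pct_mixed
      if (!is.na(chr_sum)) expect_equal(chr_sum, 100, tolerance = 0.1)
      reg_sum <- s$reg_in_register + s$reg_shift_1 + s$reg_shift_2plus
      if (!is.na(reg_sum)) expect_equal(reg_sum, 100, tolerance = 0.1)
    }
  }
})

test_that("tabulate is invariant to frame order within a window", {
  set.seed(41)
  recs <- lapply(1:20, function(k)
    classify(build_sheet_assembly(random_sheet_spec(8))$assembly))
  temps <- rep(283, 20)
  tab1 <- tabulate_ensemble(recs, temps, window = c(1, 20))
  perm <- sample(20)
  tab2 <- tabulate_ensemble(recs[perm], temps, window = c(1, 20))
  expect_equal(tab1$stats, tab2$stats)
  expect_equal(tab1$populations[tab2$types, , drop = FALSE],
               tab2$populations)
})

test_that("table exports write valid TSV and JSON", {
  recs <- c(rep(list(local_records(3)), 4),
            rep(list(local_records(c(2, 1))), 2))
  tab <- tabulate_ensemble(recs, rep(c(250, 300), each = 3), window = c(1, 3))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_table(tab, tsv)
  parsed <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(ncol(parsed), 3)  # statistic + 2 temperatures
  js <- withr::local_tempfile(fileext = ".json")
  ensemble_to_json(tab, js)
  back <- jsonlite::read_json(js)
  expect_equal(length(back$temperatures), 2)
})

test_that("convergence checker accepts identical windows and flags shifted melting", {
  ladder <- default_ladder()
  sim <- simulate_two_state_remd(two_state_params(283, 50, 3, ladder,
                                                  1200, 10, seed = 5))
  same <- specific_heat_convergence(sim$trace, c(1, 1200), c(1, 1200))
  expect_equal(same$peak_shift, 0)
  expect_equal(same$max_rel_dev, 0)
  expect_true(same$converged)
  # halves of one equilibrium run converge at the default tolerances
  halves <- specific_heat_convergence(sim$trace, c(1, 600), c(601, 1200))
  expect_true(halves$converged)
  # splicing in a window generated at a melting point 20 K higher fails
  shifted <- simulate_two_state_remd(two_state_params(303, 50, 3, ladder,
                                                      600, 10, seed = 6))
  spliced <- remd_trace(ladder, lapply(seq_along(ladder), function(t)
    c(sim$trace$samples[[t]][1:600], shifted$trace$samples[[t]])))
  bad <- specific_heat_convergence(spliced, c(1, 600), c(601, 1200))
  expect_false(bad$converged)
  expect_gt(bad$peak_shift, 3)
  expect_error(specific_heat_convergence(sim$trace, c(1, 5), c(6, 10)),
               "fewer than 10 samples")
})

test_that("demux tracks permutations and matches a brute-force replay", {
  # empty log: identity paths
  empty <- data.frame(step = integer(0), slot_i = integer(0),
                      slot_j = integer(0), accepted = integer(0))
  paths <- demux_replicas(empty, 4, 6)
  expect_true(all(t(paths) == 0:3))
  # single accepted swap of slots 0,1 at step 5
  one <- data.frame(step = 5L, slot_i = 0L, slot_j = 1L, accepted = 1L)
  p1 <- demux_replicas(one, 2, 8)
  expect_equal(p1[, 1], c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(p1[, 2], c(1L, 1L, 1L, 1L, 1L, 0L, 0L, 0L))
  # random log equals step-by-step replay
  set.seed(9)
  steps <- sort(sample(0:999, 300))
  steps <- steps[!duplicated(steps)]
  log <- data.frame(step = steps,
                    slot_i = sample(0:6, length(steps), replace = TRUE),
                    accepted = rbinom(length(steps), 1, 0.6))
  log$slot_j <- log$slot_i + 1L
  paths <- demux_replicas(log, 8, 1000)
  slot <- 0:7
  ev <- log[log$accepted == 1, ]
  for (s in 0:999) {
    for (k in which(ev$step == s)) {
      wi <- which(slot == ev$slot_i[k]); wj <- which(slot == ev$slot_j[k])
      slot[c(wi, wj)] <- slot[c(wj, wi)]
    }
    expect_equal(paths[s + 1, ], slot)
  }
  # demux then remux is the identity on assignments
  expect_equal(remux_replicas(remux_replicas(paths)), paths)
  # inconsistent log: one slot in two swaps at the same step
  bad <- data.frame(step = c(3L, 3L), slot_i = c(0L, 1L),
                    slot_j = c(1L, 2L), accepted = c(1L, 1L))
  expect_error(demux_replicas(bad, 4, 10), "inconsistent")
})

test_that("nucleation events report the first seed sheet per walker", {
  r111 <- local_records(c(1, 1, 1))
  r21 <- local_records(c(2, 1))
  r3 <- local_records(3)
  # never nucleates
  expect_equal(nrow(detect_nucleation(list(rep(list(r111), 5)))), 0)
  ev <- detect_nucleation(list(list(r111, r21, r3)), seed_threshold = 2)
  expect_equal(ev$walker_id, 0L)
  expect_equal(ev$frame_index, 1L)
  expect_equal(ev$seed_size, 2L)
  # threshold 3 skips the dimer
  ev3 <- detect_nucleation(list(list(r111, r21, r3)), seed_threshold = 3)
  expect_equal(ev3$frame_index, 2L)
  expect_equal(ev3$seed_size, 3L)
  # generator-driven: dimer inserted at a known frame
  set.seed(13)
  series <- c(rep(list(r111), 7), list(r21), rep(list(r3), 2))
  ev4 <- detect_nucleation(list(rep(list(r111), 10), series))
  expect_equal(ev4$walker_id, 1L)
  expect_equal(ev4$frame_index, 7L)
})

test_that("representative selection returns per-type medoids matching brute force", {
  # all frames identical: earliest frame wins the tie
  recs <- rep(list(local_records(3)), 6)
  sel <- select_representatives(recs, k = 1)
  expect_equal(sel$frame_index, 1L)
  # two types, k = 2: one representative each
  recs2 <- c(rep(list(local_records(3)), 7),
             rep(list(local_records(c(2, 1))), 3))
  sel2 <- select_representatives(recs2, k = 2)
  expect_setequal(sel2$config_type, c("3", "2 1"))
  expect_equal(sel2$population_pct[sel2$config_type == "3"], 70)
  # k beyond the number of observed types returns all types
  expect_equal(nrow(select_representatives(recs2, k = 10)), 2)
  # 100-frame randomized fixture equals the O(n^2) brute-force medoid
  set.seed(43)
  recs3 <- lapply(1:100, function(k) {
    sizes <- if (k %% 2) c(2, 1) else 3
    classify(build_sheet_assembly(sheet_spec(
      sizes, registers = sample(-1:1, 1)))$assembly)
  })
  sel3 <- select_representatives(recs3, k = 2)
  for (r in seq_len(nrow(sel3)))
    expect_equal(sel3$frame_index[r],
                 brute_force_medoid(recs3, sel3$config_type[r]))
  expect_error(select_representatives(recs3, mode = "temperature"), "freq")
})
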