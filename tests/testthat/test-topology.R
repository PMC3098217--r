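test_that("strand_pair_graph applies the glycine exclusion and counts both directions", {
  # trimer: A-B share a 4-bond ladder, C isolated
  hb <- data.frame(
    donor_chain = c("B", "B", "A", "A"),
    donor_res = c(1L, 2L, 3L, 4L),
    acceptor_chain = c("A", "A", "B", "B"),
    acceptor_res = c(1L, 2L, 3L, 4L),
    energy = rep(-2, 4), stringsAsFactors = FALSE)
  built <- build_sheet_assembly(sheet_spec(c(1, 1, 1), inter_sheet_offset = 60))
  pairs <- strand_pair_graph(built$assembly, hb)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$a, "A"); expect_equal(pairs$b, "B")
  expect_equal(pairs$n_hbonds, 4L)
  sheets <- build_sheets(pairs, c("A", "B", "C"))
  expect_equal(sort(vapply(sheets, `[[`, 0L, "size"), decreasing = TRUE),
               c(2L, 1L))
  # a lone bond through the N-terminal glycine attaches nothing
  hb0 <- data.frame(donor_chain = "B", donor_res = 0L,
                    acceptor_chain = "A", acceptor_res = 3L,
                    energy = -2, stringsAsFactors = FALSE)
  expect_equal(nrow(strand_pair_graph(built$assembly, hb0)), 0)
})

test_that("generated multi-sheet assemblies give the designed pair count", {
  built <- build_sheet_assembly(sheet_spec(c(7, 5)))
  rec <- classify(built$assembly)
  expect_equal(nrow(rec$pairs), (7 - 1) + (5 - 1))
})

test_that("pair_orientation resolves slope sign and degenerate cases", {
  expect_equal(pair_orientation(cbind(c(1, 3, 5), c(2, 4, 6))), "parallel")
  expect_equal(pair_orientation(cbind(c(1, 3, 5), c(5, 3, 1))), "antiparallel")
  expect_equal(pair_orientation(cbind(3, 3)), "undefined")
  # duplicated single pair still counts as one distinct pair
  expect_equal(pair_orientation(cbind(c(3, 3), c(3, 3))), "undefined")
  # flat fit (slope zero) is a tie
  expect_equal(pair_orientation(cbind(c(1, 2, 3), c(4, 4, 4))), "undefined")
})

test_that("pair_register computes rounded-median shifts per orientation", {
  expect_equal(pair_register("parallel", cbind(c(1, 3), c(1, 3)), 7), 0L)
  expect_equal(pair_register("parallel", cbind(c(1, 3), c(2, 4)), 7), 1L)
  expect_equal(pair_register("antiparallel", cbind(c(1, 3, 5), c(5, 3, 1)), 7),
               0L)
  # median ties round toward zero
  expect_equal(pair_register("parallel", cbind(c(1, 2), c(2, 4)), 7), 1L)
  expect_equal(pair_register("parallel", cbind(c(2, 4), c(1, 1)), 7), -2L)
})

test_that("build_sheets assigns sheet character from pair orientations", {
  mkpairs <- function(ori) {
    df <- data.frame(a = c("A", "B"), b = c("B", "C"), n_hbonds = c(4L, 4L),
                     orientation = ori, register = c(0L, 0L),
                     stringsAsFactors = FALSE)
    class(df) <- c("strand_pairs", "data.frame")
    df
  }
  s1 <- build_sheets(mkpairs(c("antiparallel", "antiparallel")),
                     c("A", "B", "C"))
  expect_equal(s1[[1]]$size, 3L)
  expect_equal(s1[[1]]$character, "fully_antiparallel")
  s2 <- build_sheets(mkpairs(c("parallel", "antiparallel")), c("A", "B", "C"))
  expect_equal(s2[[1]]$character, "mixed")
  s3 <- build_sheets(mkpairs(c("undefined", "undefined")), c("A", "B", "C"))
  expect_equal(s3[[1]]$character, "mixed")
  # no pairs: three singleton sheets
  empty <- mkpairs(c("parallel", "parallel"))[0, ]
  s4 <- build_sheets(empty, c("A", "B", "C"))
  expect_length(s4, 3)
  expect_true(all(vapply(s4, `[[`, 0L, "size") == 1L))
  expect_true(all(is.na(vapply(s4, `[[`, "", "character"))))
})

test_that("classify recovers designed configuration types", {
  b1 <- build_sheet_assembly(sheet_spec(c(8, 7, 5)))
  expect_equal(classify(b1$assembly)$config_type, "8 7 5")
  b2 <- build_sheet_assembly(sheet_spec(c(1, 1, 1)))
  r2 <- classify(b2$assembly)
  expect_equal(r2$config_type, "1 1 1")
  expect_equal(r2$beta_content, 0)
})

test_that("configuration-type integers always sum to the chain count", {
  set.seed(7)
  for (k in 1:12) {
    built <- build_sheet_assembly(random_sheet_spec())
    rec <- classify(built$assembly)
    expect_equal(sum(as.integer(strsplit(rec$config_type, " ")[[1]])),
                 n_chains(built$assembly))
  }
})

test_that("classify is invariant under rigid-body motion and chain relabeling", {
  built <- build_sheet_assembly(sheet_spec(c(3, 2),
                                           orientations = list(
                                             c("parallel", "antiparallel"),
                                             "antiparallel"),
                                           registers = list(c(1L, 0L), -1L)))
  rec <- classify(built$assembly)
  moved <- transform_assembly(built$assembly, rot_xyz(1, 2, 3), c(-40, 8, 15))
  rec2 <- classify(moved)
  expect_equal(rec2$config_type, rec$config_type)
  expect_equal(rec2$beta_content, rec$beta_content)
  expect_equal(as.data.frame(rec2$pairs), as.data.frame(rec$pairs))
  # relabeled chains: same sheet-size multiset and pair statistics
  relab <- built$assembly
  names(relab$chains) <- c("V", "W", "X", "Y", "Z")
  rec3 <- classify(relab)
  expect_equal(rec3$config_type, rec$config_type)
  expect_equal(sort(rec3$pairs$orientation), sort(rec$pairs$orientation))
})

test_that("sheet decomposition equals brute-force transitive closure on small assemblies", {
  set.seed(11)
  for (k in 1:20) {
    repeat {
      spec <- random_sheet_spec(max_chains = 5L)
      if (sum(spec$sheet_sizes) <= 5L) break
    }
    built <- build_sheet_assembly(spec)
    rec <- classify(built$assembly)
    got <- sort(vapply(rec$sheets, function(s)
      paste(sort(s$strands), collapse = " "), ""))
    want <- brute_force_components(rec$pairs, names(built$assembly$chains))
    expect_equal(got, want)
  }
})

test_that("generator round-trip recovers type, orientations and registers exactly", {
  set.seed(23)
  for (k in 1:25) {
    built <- build_sheet_assembly(random_sheet_spec())
    rec <- classify(built$assembly)
    bk <- built$bookkeeping
    expect_equal(rec$config_type, bk$config_type)
    got <- plain_df(rec$pairs[order(rec$pairs$a, rec$pairs$b), ])
    want <- plain_df(bk$pairs[order(bk$pairs$a, bk$pairs$b), ])
    expect_equal(got, want)
    expect_equal(rec$beta_content, bk$beta_content)
  }
})

test_that("topology JSON and TSV exports round-trip the key fields", {
  built <- build_sheet_assembly(sheet_spec(c(2, 1)))
  rec <- classify(built$assembly)
  tf <- withr::local_tempfile(fileext = ".json")
  topology_to_json(rec, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$config_type, "2 1")
  expect_equal(back$n_chains, 3L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_strand_pairs(rec$pairs, tsv)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$orientation, "antiparallel")
})
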