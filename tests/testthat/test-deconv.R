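make_table <- function(counts_list, conds = names(counts_list[[1]])) {
  # counts_list: named per-compound vectors keyed by "a|b" style ids
  lib <- gen_library(2, c(3, 3))
  counts <- matrix(0L, nrow(lib$bb), length(conds),
                   dimnames = list(NULL, conds))
  for (id in names(counts_list))
    counts[match(id, lib$compound_id), ] <- counts_list[[id]]
  count_table(lib$bb, counts)
}

test_that("count TSV round-trips exactly, including unmapped reads", {
  sc <- demo_screen()
  ct <- simulate_selection(sc$lib, sc$truth, sc$config, seed = 2)
  ct$unmapped <- c(MTA = 123L, SIN = 45L)
  ct$totals <- ct$totals + ct$unmapped
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, path)
  back <- read_count_table(path)
  expect_identical(back$counts, ct$counts)
  expect_identical(back$bb, ct$bb)
  expect_equal(back$unmapped, ct$unmapped)
  expect_equal(back$totals, ct$totals)
})

test_that("empty table with header only loads as zero compounds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("pos1\tpos2\tMTA\tSIN", path)
  ct <- read_count_table(path)
  expect_equal(nrow(ct$counts), 0)
  expect_equal(ct$conditions, c("MTA", "SIN"))
})

test_that("malformed rows are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos1\tpos2\tMTA", "P1.B001\tP2.B001\t5",
               "P1.B002\tP2.B001\tfour"), path)
  expect_error(read_count_table(path), "line 3")
})

test_that("duplicate compound rows are rejected", {
  bb <- data.frame(pos1 = c("A", "A"), pos2 = c("B", "B"))
  cm <- matrix(1L, 2, 1, dimnames = list(NULL, "MTA"))
  expect_error(count_table(bb, cm), "duplicate")
})

test_that("tag decoding matches a direct tally and buckets unknown tags", {
  lib <- gen_library(2, c(5, 5))
  set.seed(31)
  reads <- c(sample(lib$compound_id, 950, replace = TRUE),
             rep("P1.B099|P2.B001", 50))
  ct <- decode_tags(list(MTA = reads), lib)
  expect_equal(as.integer(ct$counts[, "MTA"]),
               oracle_tally(reads, lib$compound_id))
  expect_equal(unname(ct$unmapped[["MTA"]]), 50)
  expect_equal(unname(ct$totals[["MTA"]]), 1000)
})

test_that("minimum-count filter keeps the boundary and matches a scan", {
  ct <- make_table(list("P1.B001|P2.B001" = c(MTA = 2L, SIN = 0L),
                        "P1.B002|P2.B001" = c(MTA = 3L, SIN = 0L),
                        "P1.B003|P2.B002" = c(MTA = 10L, SIN = 1L)))
  kept <- filter_min_count(ct, 3)
  expect_setequal(kept$compound_id,
                  c("P1.B002|P2.B001", "P1.B003|P2.B002"))
  expect_equal(kept$totals, ct$totals)   # totals never renormalised
  # k = 0 is the identity
  expect_identical(filter_min_count(ct, 0)$counts, ct$counts)
  # random table against a brute-force scan
  sc <- demo_screen()
  big <- simulate_selection(sc$lib, sc$truth, sc$config, seed = 7)
  for (k in c(1, 3, 10)) {
    keep_oracle <- logical(nrow(big$counts))
    for (i in seq_len(nrow(big$counts)))
      keep_oracle[i] <- max(big$counts[i, ]) >= k
    expect_identical(filter_min_count(big, k)$compound_id,
                     big$compound_id[keep_oracle])
  }
})

test_that("CPM normalisation is exact and conserves a million per condition", {
  bb <- data.frame(pos1 = c("A", "B"))
  cm <- matrix(c(5L, 0L, 1L, 2L), 2, 2, dimnames = list(NULL, c("x", "y")))
  ct <- count_table(bb, cm, totals = c(x = 1e6, y = 3))
  enr <- cpm_normalize(ct)
  expect_equal(unname(enr$cpm[1, "x"]), 5)
  # x's totals exceed its mapped reads, so its CPM does not sum to 1e6
  expect_equal(unname(colSums(enr$cpm) + enr$unmapped_cpm), c(5, 1e6))
  # full accounting when totals = mapped + unmapped
  sc <- demo_screen()
  big <- simulate_selection(sc$lib, sc$truth, sc$config, seed = 9)
  e2 <- cpm_normalize(big)
  expect_equal(unname(colSums(e2$cpm) + e2$unmapped_cpm), c(1e6, 1e6))
  expect_equal(e2$cpm, sweep(big$counts, 2, big$totals, "/") * 1e6,
               tolerance = 1e-12)
  # count == total -> 1e6 CPM
  one <- count_table(data.frame(pos1 = "A"),
                     matrix(7L, 1, 1, dimnames = list(NULL, "z")))
  expect_equal(unname(cpm_normalize(one)$cpm[1, 1]), 1e6)
})

test_that("zero totals are rejected by name", {
  bb <- data.frame(pos1 = "A")
  ct <- count_table(bb, matrix(0L, 1, 1, dimnames = list(NULL, "empty")))
  expect_error(cpm_normalize(ct), "empty")
})

test_that("selectivity score: arithmetic, antisymmetry, depth invariance", {
  bb <- data.frame(pos1 = c("A", "B", "C"))
  cm <- matrix(c(80L, 0L, 5L, 0L, 80L, 5L), 3, 2,
               dimnames = list(NULL, c("a", "b")))
  ct <- count_table(bb, cm, totals = c(a = 1e5, b = 1e5))
  enr <- selectivity_score(cpm_normalize(ct), "a", "b")
  expect_equal(as.numeric(enr$selectivity[1]), log2(801))  # 800 vs 0 CPM
  expect_equal(as.numeric(enr$selectivity[3]), 0)          # equal CPM
  swapped <- selectivity_score(cpm_normalize(ct), "b", "a")
  expect_equal(as.numeric(swapped$selectivity),
               as.numeric(-enr$selectivity))
  # scaling both depths by a common factor leaves the score unchanged
  ct10 <- count_table(bb, cm * 10L, totals = c(a = 1e6, b = 1e6))
  e10 <- selectivity_score(cpm_normalize(ct10), "a", "b")
  expect_equal(as.numeric(e10$selectivity), as.numeric(enr$selectivity))
  expect_error(selectivity_score(cpm_normalize(ct), "a", "zz"), "zz")
})

test_that("synthon aggregation equals brute-force group-and-sum", {
  sc <- demo_screen()
  enr <- cpm_normalize(simulate_selection(sc$lib, sc$truth, sc$config,
                                          seed = 13))
  agg <- synthon_aggregate(enr, "pos2")
  for (i in seq_len(nrow(agg))) {
    m <- enr$bb$pos2 == agg$pos2[i]
    expect_equal(agg$`cpm.MTA`[i], sum(enr$cpm[m, "MTA"]))
    expect_equal(agg$`cpm.SIN`[i], sum(enr$cpm[m, "SIN"]))
    expect_equal(agg$n_members[i], sum(m))
  }
  # aggregating over all positions is the identity table
  full <- synthon_aggregate(enr, c("pos1", "pos2", "pos3"))
  expect_equal(nrow(full), nrow(enr$bb))
  key <- paste(full$pos1, full$pos2, full$pos3, sep = "|")
  expect_equal(full$`cpm.MTA`[match(enr$compound_id, key)],
               unname(enr$cpm[, "MTA"]))
  expect_error(synthon_aggregate(enr, character(0)), "empty")
})

test_that("series detection recovers the planted building block", {
  sc <- demo_screen()
  ct <- simulate_selection(sc$lib, sc$truth, sc$config, seed = 21)
  enr <- selectivity_score(cpm_normalize(filter_min_count(ct)), "MTA", "SIN")
  ser <- detect_series(enr, min_members = 10, min_cpm = 100,
                       min_selectivity = 1)
  expect_gt(nrow(ser), 0)
  expect_equal(ser$position[1], "pos2")
  expect_equal(ser$building_block[1], "P2.B007")
  expect_true(all(grepl("P2.B007", attr(ser, "members")[[1]])))
})

test_that("a cond_b-only series surfaces with negative median selectivity", {
  lib <- gen_library(3, c(12, 15, 14))
  truth <- ground_truth(planted_series(c(pos3 = "P3.B003"), kd_apo = 6e6,
                                       alpha = c(MTA = 1, SIN = 20)))
  cfg <- selection_config(conditions = c("MTA", "SIN"), depth = 1e5)
  ct <- simulate_selection(lib, truth, cfg, seed = 17)
  enr <- selectivity_score(cpm_normalize(filter_min_count(ct)), "MTA", "SIN")
  ser <- detect_series(enr, min_members = 10, min_cpm = 100,
                       min_selectivity = 1)
  expect_gt(nrow(ser), 0)
  last <- nrow(ser)   # ranking is descending, so the SIN series is last
  expect_equal(ser$building_block[last], "P3.B003")
  expect_lt(ser$median_selectivity[last], 0)
})

test_that("empty tables give an empty series list", {
  bb <- data.frame(pos1 = character(0))
  ct <- count_table(bb, matrix(integer(0), 0, 1,
                               dimnames = list(NULL, "a")),
                    totals = c(a = 10))
  enr <- selectivity_score(
    structure(c(unclass(ct), list(cpm = ct$counts + 0,
                                  unmapped_cpm = 0)),
              class = c("enrichment_table", "count_table")), "a", "a")
  expect_equal(nrow(detect_series(enr)), 0)
})

test_that("qPCR double-delta fold enrichment", {
  ref <- qpcr_measurement(ct_eluate = 20, ct_input = 18)
  same <- qpcr_measurement(ct_eluate = 22, ct_input = 20)
  expect_equal(qpcr_fold_enrichment(same, ref), 1)
  cmp <- qpcr_measurement(ct_eluate = 17, ct_input = 18)   # dCt 3 smaller
  expect_equal(qpcr_fold_enrichment(cmp, ref), 8)
  e19a <- qpcr_measurement(10, 10, efficiency = 1.9)
  e19b <- qpcr_measurement(12, 10, efficiency = 1.9)
  expect_equal(qpcr_fold_enrichment(e19a, e19b), 1.9^2)
  expect_equal(qpcr_fold_enrichment(e19a, e19b), 3.61)
  mismatched <- qpcr_measurement(10, 10, efficiency = 1.8)
  expect_error(qpcr_fold_enrichment(mismatched, ref), "efficienc")
})

test_that("filtering commutes with CPM thresholding at fixed totals", {
  sc <- demo_screen()
  ct <- simulate_selection(sc$lib, sc$truth, sc$config, seed = 23)
  k <- 5
  a <- cpm_normalize(filter_min_count(ct, k))
  b <- cpm_normalize(ct)
  keep_b <- apply(b$cpm, 1, max) >= (k / ct$totals[1] * 1e6) * (1 - 1e-12)
  expect_identical(a$compound_id, b$compound_id[keep_b])
})
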