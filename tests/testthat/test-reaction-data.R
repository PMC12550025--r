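# Curation pipeline: table parsing, deduplication, IQR filtering,
# clipping, downsampling, splitting.

write_fixture_table <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("table parsing drops bad rows with logged reasons", {
  tab <- data.frame(
    reactant_1 = c("CCO", "CCN", "CCC", "C$Z", "CCO"),
    reactant_2 = c("", "", "", "", ""),
    product = c("CC=O", "CC=O", "CCC=O", "CC", "CC"),
    catalyst = c("[Pd]", "CP(C)C", "[Pd]", "[Pd]", ""),
    reagent_1 = c("O", "", "", "", ""),
    time_h = c(1.5, 0, 2, 1, 1),
    yield = c(85, 50, NA, 20, 30),
    stringsAsFactors = FALSE)
  rec <- parse_reaction_table(write_fixture_table(tab))
  expect_equal(nrow(rec), 1L)                 # rows 2-5 all fail a rule
  expect_equal(rec$target[1], 85)
  expect_identical(rec$target_kind[1], "yield")
  expect_equal(rec$time_h[1], 1.5)
  log <- attr(rec, "drop_log")
  expect_setequal(log$reason,
                  c("nonpositive_time", "missing_target",
                    "unparseable_smiles", "missing_catalyst"))
  expect_equal(nrow(tab), nrow(rec) + nrow(log))

  expect_error(parse_reaction_table(write_fixture_table(tab[, -3])),
               "missing mandatory")
})

test_that("parsing a generated table recovers the dataset", {
  ds <- fixture_records_small()
  path <- tempfile(fileext = ".csv")
  catvae:::.write_records_csv(ds, path)
  rec <- parse_reaction_table(path)
  expect_equal(nrow(rec), nrow(ds))
  expect_identical(rec$catalyst, ds$catalyst)
  expect_equal(rec$target, ds$target, tolerance = 1e-6)
})

test_that("duplicate averaging matches a brute-force grouping oracle", {
  ds <- make_planted_duplicates(fixture_spec(n_records = 40L, seed = 13L),
                                k_groups = 6L)
  mf <- attr(ds, "manifest")
  dd <- deduplicate_average(ds)
  expect_equal(nrow(dd), mf$n_after_dedup)
  keys <- catvae:::.record_keys(dd)
  expect_equal(dd$target[match(mf$group_keys, keys)], mf$expected_means)

  # brute-force oracle over all keys
  allkeys <- catvae:::.record_keys(ds)
  oracle <- tapply(ds$target, allkeys, mean)
  expect_equal(dd$target, as.numeric(oracle[keys]))

  # identity when no duplicates
  base <- make_reaction_dataset(fixture_spec(n_records = 15L, seed = 4L))
  dd2 <- deduplicate_average(base)
  expect_equal(dd2$target, base$target)
  expect_identical(dd2$catalyst, base$catalyst)

  # two identical reactions with yields 40/60 average to 50
  two <- rbind(base[1, ], base[1, ])
  two$target <- c(40, 60)
  expect_equal(deduplicate_average(two)$target, 50)
})

test_that("IQR filter matches the quartile oracle per field", {
  ds <- fixture_records_small()[1:20, ]
  ds$target <- c(1, 2, 3, 4, 100, ds$target[6:20] * 0 + 2.5)
  surv <- iqr_filter(ds, fields = "target", k = 1.5)
  q <- stats::quantile(ds$target, c(.25, .75), type = 7, names = FALSE)
  lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
  expect_setequal(surv$target, ds$target[ds$target >= lo & ds$target <= hi])
  expect_false(100 %in% surv$target)

  # all-identical values: IQR 0 keeps everything
  ds2 <- ds; ds2$target <- 7
  expect_equal(nrow(iqr_filter(ds2, fields = "target")), nrow(ds2))

  # multi-field survivors equal the intersection of per-field survivors
  ds3 <- fixture_records_1000()[1:200, ]
  all3 <- iqr_filter(ds3)
  per_field <- Reduce(intersect, lapply(
    c("catalyst_mw", "catalyst_atom_count", "target"),
    function(f) catvae:::.record_keys(iqr_filter(ds3, fields = f))))
  expect_setequal(catvae:::.record_keys(all3), per_field)

  expect_warning(iqr_filter(ds[1:3, ]), "fewer than 4")
})

test_that("yield clipping maps into [0, 100] and spares other targets", {
  ds <- fixture_records_small()[1:4, ]
  ds$target <- c(120, -3, 50, 100.0001)
  out <- clip_target(ds)
  expect_equal(out$target, c(100, 0, 50, 100))

  ds$target_kind <- "binding_energy"
  ds$target <- c(-40, -10, -27, -5)
  expect_equal(clip_target(ds)$target, c(-40, -10, -27, -5))
})

test_that("downsampling caps per-catalyst counts reproducibly", {
  ds <- fixture_records_small()
  big <- rbind(ds, ds[rep(1, 10), ])           # catalyst 1 now has 11 records
  out <- downsample_overrepresented(big, max_per_catalyst = 3L, seed = 1L)
  counts <- table(out$catalyst)
  expect_true(all(counts <= 3L))
  expect_equal(max(table(big$catalyst)[names(counts)]) > 3, TRUE)

  # below-cap catalysts untouched
  out2 <- downsample_overrepresented(ds, max_per_catalyst = 50L, seed = 1L)
  expect_equal(nrow(out2), nrow(ds))

  # different seeds: possibly different picks, identical per-catalyst counts
  o1 <- downsample_overrepresented(big, 3L, seed = 1L)
  o2 <- downsample_overrepresented(big, 3L, seed = 2L)
  expect_equal(table(o1$catalyst), table(o2$catalyst))
})

test_that("dataset splitting is an exact reproducible partition", {
  ds <- fixture_records_1000()
  sp <- split_dataset(ds, c(90, 5, 5), seed = 7L)
  expect_equal(nrow(sp$train), 900L)
  expect_equal(nrow(sp$validation), 50L)
  expect_equal(nrow(sp$test), 50L)
  keys <- catvae:::.record_keys(ds)
  got <- c(catvae:::.record_keys(sp$train), catvae:::.record_keys(sp$validation),
           catvae:::.record_keys(sp$test))
  expect_setequal(got, keys)
  expect_equal(length(got), length(keys))

  sp2 <- split_dataset(ds, c(90, 5, 5), seed = 7L)
  expect_identical(sp2$train$catalyst, sp$train$catalyst)

  all_train <- split_dataset(ds[1:20, ], c(100, 0, 0), seed = 1L)
  expect_equal(nrow(all_train$train), 20L)
  expect_equal(nrow(all_train$test), 0L)

  expect_error(split_dataset(ds, c(80, 10, 5), seed = 1L), "sum")

  # random-ratio partitions stay exact
  rng <- catvae:::.seeded_rng(3L)
  for (rep in 1:5) {
    r1 <- rng$sample(60, 1); r2 <- rng$sample(100 - r1 - 1, 1)
    sp3 <- split_dataset(ds[1:97, ], c(r1, r2, 100 - r1 - r2), seed = rep)
    expect_equal(nrow(sp3$train) + nrow(sp3$validation) + nrow(sp3$test), 97L)
  }
})

test_that("re-running earlier curation stages is a no-op", {
  ds <- make_planted_duplicates(fixture_spec(n_records = 60L, seed = 19L),
                                k_groups = 5L)
  cur <- curate_reactions(ds, seed = 3L)
  again <- deduplicate_average(cur)
  expect_equal(nrow(again), nrow(cur))
  expect_equal(again$target, cur$target)
  clipped <- clip_target(cur)
  expect_equal(clipped$target, cur$target)
  log <- attr(cur, "drop_log")
  expect_equal(nrow(ds), nrow(cur) + nrow(log))
})
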