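test_that("spread tables round-trip through TSV unchanged", {
  spreads <- simulate_spreads(independence_model(c(0.36, 0.235, 0.14)),
                              n_spreads = 30, n_replicates = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spread_table(spreads, path)
  back <- read_spread_table(path)
  expect_equal(as.data.frame(back), as.data.frame(spreads))
})

test_that("malformed spread tables raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "spread_id\tcondition\treplicate\tEAD_C\tEAD_V1\tEAD_V2",
    "s1\tcontrol\t1\t1\t0\t1",
    "s2\tcontrol\t1\t1\t2\t0",
    "s3\tcontrol\t1\t1\t1\t1"
  ), path)
  expect_error(read_spread_table(path), "must be 0 or 1.*line 3")

  writeLines(c(
    "spread_id\tcondition\treplicate\tEAD_C\tEAD_V1",
    "s1\tcontrol\t0\t1\t0"
  ), path)
  expect_error(read_spread_table(path), "positive integer")

  writeLines(c("spread_id\tcondition\tEAD_V1", "s1\tcontrol\t1"), path)
  expect_error(read_spread_table(path), "missing required column")

  writeLines(c(
    "spread_id\tcondition\treplicate\tEAD_C",
    "s1\tcontrol\t1\t1"
  ), path)
  expect_error(read_spread_table(path), "no variable domain columns")
})

test_that("a small fixture file parses with rows preserved", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "spread_id\tcondition\treplicate\tEAD_C\tEAD_V1\tEAD_V2\tEAD_V3",
    "s1\tcontrol\t1\t1\t1\t0\t0",
    "s2\tcontrol\t1\t1\t0\t0\t0",
    "s3\tcontrol\t2\t1\t1\t1\t1"
  ), path)
  spreads <- read_spread_table(path)
  expect_equal(nrow(spreads), 3L)
  expect_s3_class(spreads, "tbl_df")
})

test_that("aggregation conserves spreads and fills empty cells", {
  spreads <- simulate_spreads(independence_model(c(0.5, 0.2)),
                              n_spreads = 40, n_replicates = 3, seed = 2)
  counts <- aggregate_patterns(spreads)
  expect_equal(sum(counts$count), nrow(spreads))
  expect_equal(nrow(counts), 3 * 4)
  by_rep <- dplyr::count(counts, .data$replicate, wt = .data$count)
  expect_equal(by_rep$n, rep(40L, 3))
  # constant domain reported separately, not folded into the pattern
  const <- attr(counts, "constant_domains")
  expect_equal(unique(const$domain), "EAD_C")
  expect_equal(const$frequency, rep(1, 3))
})

test_that("aggregation handles degenerate selections", {
  all_un <- tiny_spreads()
  all_un$EAD_V1 <- 0L
  all_un$EAD_V2 <- 0L
  counts <- aggregate_patterns(all_un)
  expect_equal(sum(counts$count[counts$pattern_id == 0]), 12L)
  expect_equal(sum(counts$count[counts$pattern_id != 0]), 0L)

  one <- tiny_spreads()[1, ]
  counts1 <- aggregate_patterns(one)
  expect_equal(sum(counts1$count), 1L)

  expect_error(aggregate_patterns(tiny_spreads(), condition = "missing"),
               "no spreads match")
})

test_that("counts reconstructed from the published frequencies match hand-scaled values", {
  # 600 annotations drawn to match the published control distribution
  freq <- published_freq
  spreads <- purrr::map_dfr(0:7, function(id) {
    n <- round(600 * freq[id + 1])
    if (n == 0) return(NULL)
    st <- pattern_states(rep(id, n), 3)
    dplyr::bind_cols(
      tibble::tibble(spread_id = sprintf("p%d_%03d", id, seq_len(n)),
                     condition = "control",
                     replicate = rep_len(1:3, n), EAD_C = 1L),
      tibble::as_tibble(st)
    )
  })
  counts <- pool_patterns(aggregate_patterns(spreads))
  expect_equal(counts$value[counts$pattern_id == 1], 120)  # V1 only
  expect_equal(counts$value[counts$pattern_id == 3], 48)   # V1+V2
  expect_equal(counts$value[counts$pattern_id == 6], 18)   # V2+V3
  expect_equal(counts$value[counts$pattern_id == 7], 36)   # all labeled
  expect_equal(sum(counts$value), 600)
})

test_that("condition summaries report means, SEM and pooled frequencies", {
  spreads <- tiny_spreads()
  cm <- condition_marginals(spreads)
  v1 <- cm[cm$domain == "EAD_V1", ]
  expect_equal(v1$mean_freq, 0.5)
  expect_equal(v1$sem, 0)            # identical replicates
  expect_equal(v1$pooled_freq, 0.5)
  expect_true(cm$is_constant[cm$domain == "EAD_C"])
  expect_equal(cm$mean_freq[cm$domain == "EAD_C"], 1)

  # replicate frequencies (0.30, 0.34, 0.38): mean 0.34, SEM = sd/sqrt(3)
  spreads50 <- purrr::map_dfr(1:3, function(r) {
    k <- c(15, 17, 19)[r]
    tibble::tibble(
      spread_id = sprintf("r%d_%02d", r, 1:50), condition = "c",
      replicate = r, EAD_V1 = rep(c(1L, 0L), c(k, 50 - k))
    )
  })
  cm50 <- condition_marginals(spreads50)
  expect_equal(cm50$mean_freq, 0.34)
  expect_equal(cm50$sem, sd(c(0.30, 0.34, 0.38)) / sqrt(3), tolerance = 1e-12)

  # single replicate: SEM not available
  cm1 <- condition_marginals(spreads50[spreads50$replicate == 1, ])
  expect_true(is.na(cm1$sem))
})

test_that("condition marginals agree with pattern marginals on pooled data", {
  spreads <- simulate_spreads(independence_model(c(0.4, 0.25, 0.1)),
                              n_spreads = 150, n_replicates = 3, seed = 31)
  cm <- condition_marginals(spreads)
  pm <- marginals_from_patterns(aggregate_patterns(spreads))
  for (i in 1:3) {
    expect_equal(cm$pooled_freq[cm$domain == paste0("EAD_V", i)],
                 pm$p[i], tolerance = 1e-12)
  }
})

test_that("constant-domain inference flags always-associated columns", {
  spreads <- tiny_spreads()
  expect_equal(infer_constant_domains(spreads), "EAD_C")
  spreads$EAD_V2 <- 1L
  expect_setequal(infer_constant_domains(spreads), c("EAD_C", "EAD_V2"))
})

test_that("pattern count tables round-trip through TSV", {
  counts <- aggregate_patterns(tiny_spreads())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_counts(counts, path)
  back <- read_pattern_counts(path)
  expect_equal(back$count, counts$count)
  expect_error(read_pattern_counts(write_spread_table(tiny_spreads(), path)),
               "missing column")
})
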