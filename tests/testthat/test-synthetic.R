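test_that("guild trajectories follow the logistic closed form", {
  stable <- guild_spec("s", "o1", "G", "stable", baseline_fraction = 0.1)
  expect_equal(guild_trajectory(stable, c(1, 5, 100)), rep(0.1, 3))
  # step limit of an infinitely steep decliner
  drop <- guild_spec("d", "o1", "G", "decliner", growth_rate = Inf,
                     midpoint_day = 5, baseline_fraction = 0.3)
  expect_equal(guild_trajectory(drop, c(2, 10)), c(0.3, 0))
  # logistic midpoint: baseline 0.01 rising to 0.5 passes through 0.255
  rise <- guild_spec("r", "o1", "G", "early_riser", growth_rate = 1,
                     midpoint_day = 5, baseline_fraction = 0.01,
                     asymptote = 0.5)
  expect_equal(guild_trajectory(rise, 5), 0.255)
  expect_equal(guild_trajectory(rise, c(5 - 2, 5, 5 + 2)),
               0.01 + 0.49 / (1 + exp(-(c(-2, 0, 2)))))
  expect_error(guild_trajectory(rise, numeric(0)),
               class = "indigoferm_input_error")
  expect_error(guild_trajectory(rise, c(3, 3)),
               class = "indigoferm_input_error")
})

test_that("a single-taxon community gets every read", {
  g <- guild_spec("only", "otu_x", "X", "stable", baseline_fraction = 1)
  cfg <- synthetic_config("fast_drop", days = c(1, 4), depth = 500,
                          n_functions = 10, n_signal_functions = 2,
                          guilds = list(g), seed = 4)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$counts == 500))
})

test_that("counts hit the configured depth and the dataset is seed-stable", {
  ds1 <- simulate_dataset(small_fast_config(seed = 6))
  ds2 <- simulate_dataset(small_fast_config(seed = 6))
  ds3 <- simulate_dataset(small_fast_config(seed = 7))
  expect_true(all(colSums(ds1$counts) == ds1$config$depth))
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$stratified, ds2$stratified)
  expect_identical(ds1$metadata, ds2$metadata)
  expect_false(identical(ds1$counts, ds3$counts))
  # every sample has a metadata row; truth references real functions
  expect_setequal(colnames(ds1$counts), ds1$metadata$sample_id)
  expect_true(all(ds1$truth$signal_functions %in% rownames(ds1$functions)))
})

test_that("ORP scenarios respect the design invariants", {
  for (seed in c(1, 8, 20)) {
    fast <- simulate_dataset(small_fast_config(seed = seed))
    later <- fast$metadata$day > min(fast$metadata$day)
    expect_true(all(fast$metadata$orp_mV[later] <= -600))
    slow <- simulate_dataset(synthetic_config("slow_drop", depth = 4000,
                                              n_functions = 40,
                                              n_signal_functions = 5,
                                              seed = seed))
    first <- slow$metadata$day == min(slow$metadata$day)
    expect_true(all(slow$metadata$orp_mV[first] > -400))
    expect_true(any(slow$metadata$orp_mV[slow$metadata$day >= 5] <= -598))
  }
})

test_that("planted signal families carry elevated reducer copy numbers", {
  ds <- simulate_dataset(small_fast_config())
  red <- rownames(ds$genome_content) %in% ds$truth$reducer_otus
  sig <- colnames(ds$genome_content) %in% ds$truth$signal_functions
  expect_gt(mean(ds$genome_content[red, sig]),
            mean(ds$genome_content[, !sig]))
  # stratified rows are the exact product of abundance and copy number
  s <- ds$stratified
  expect_equal(s$CountContributedByOTU,
               s$GeneCountPerGenome * s$OTUAbundanceInSample)
  expect_equal(s$OTUAbundanceInSample,
               ds$counts[cbind(s$OTU, s$Sample)])
})

test_that("disabling compositional noise recovers the latent composition", {
  g1 <- guild_spec("a", "o1", "A", "stable", baseline_fraction = 0.3)
  g2 <- guild_spec("b", "o2", "B", "stable", baseline_fraction = 0.7)
  cfg <- synthetic_config("fast_drop", days = 1, replicates_per_day = 1000,
                          depth = 500, n_functions = 4,
                          n_signal_functions = 1, noise_dispersion = Inf,
                          guilds = list(g1, g2), seed = 2)
  ds <- simulate_dataset(cfg)
  props <- ds$counts["o1", ] / 500
  se <- sqrt(0.3 * 0.7 / 500 / 1000)      # multinomial SE of the mean
  expect_lt(abs(mean(props) - 0.3), 3 * se)
})

test_that("datasets serialize to a directory of plain tables", {
  ds <- simulate_dataset(small_fast_config())
  dir <- file.path(tempdir(), "synthdata")
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("counts.tsv", "metadata.tsv", "taxonomy.tsv", "functions.tsv",
      "stratified.tsv", "hierarchy.tsv", "truth.tsv")))))
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_equal(sum(back), sum(ds$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config("fast_drop", depth = 0),
               class = "indigoferm_input_error")
  expect_error(synthetic_config("fast_drop", n_functions = 5,
                                n_signal_functions = 10),
               class = "indigoferm_input_error")
  expect_error(synthetic_config("fast_drop", days = c(3, 2)),
               class = "indigoferm_input_error")
  g <- guild_spec("big", "o1", "G", "stable", baseline_fraction = 0.9)
  expect_error(synthetic_config("fast_drop", guilds = list(g, g)),
               class = "indigoferm_invariant_error")
  expect_error(guild_spec("g", "o1", "G", "stable", baseline_fraction = 1.2),
               class = "indigoferm_invariant_error")
})
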