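# Batch orchestration: directory screening, resilience, reporting,
# configuration.

test_that("run_screen scores a fixture directory and flags planted hits", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  manifest <- make_screen_fixture(sdir, n_pairs = 6, n_strong = 2, seed = 21)
  scores <- run_screen(sdir)
  expect_s3_class(scores, "spry_screen")
  expect_equal(nrow(scores), 6L)
  expect_equal(sum(scores$high_confidence), 2L)
  joined <- dplyr::left_join(scores, manifest, by = "pair_id")
  expect_equal(joined$score, joined$score_star, tolerance = 1e-9)
  expect_identical(joined$high_confidence, joined$high_confidence_star)
  expect_equal(attr(scores, "n_failed"), 0L)
})

test_that("two runs over the same inputs produce byte-identical outputs", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  make_screen_fixture(sdir, n_pairs = 4, n_strong = 1, seed = 3)
  o1 <- file.path(td, "out1"); o2 <- file.path(td, "out2")
  run_screen(sdir, output_dir = o1)
  run_screen(sdir, output_dir = o2)
  for (f in c("interactions.tsv", "high_confidence.tsv", "run_log.tsv",
              "resolved_config.yaml")) {
    b1 <- readBin(file.path(o1, f), raw(), file.size(file.path(o1, f)))
    b2 <- readBin(file.path(o2, f), raw(), file.size(file.path(o2, f)))
    expect_identical(b1, b2)
  }
})

test_that("a corrupt file among many is logged, counted and survived", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  make_screen_fixture(sdir, n_pairs = 5, n_strong = 1, seed = 13)
  writeLines("{broken", file.path(sdir, "SENSOR03__SPRY03", "pae_rank_0.json"))
  expect_message(scores <- run_screen(sdir), "Skipping")
  expect_equal(nrow(scores), 4L)
  expect_equal(attr(scores, "n_failed"), 1L)
  expect_match(attr(scores, "failures")$pair, "SENSOR03__SPRY03")
  # an input set with nothing parseable is an error
  empty <- file.path(td, "empty"); dir.create(empty)
  expect_error(run_screen(empty), class = "spryscreen_empty_input_error")
})

test_that("only the top-ranked model of a pair is scored", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  fx <- make_pae_fixture(20, 20, interface_fraction = 1, pae_interface = 1,
                         dir = sdir, bait_name = "S", prey_name = "P")
  # a rank-1 decoy with a different matrix must be ignored
  decoy <- make_pae_fixture(20, 20, interface_fraction = 0,
                            pae_background = 31)
  write_pae_json(decoy$prediction$pae,
                 file.path(sdir, "S__P", "pae_rank_1.json"),
                 dialect = "af3_full_data",
                 partition = decoy$prediction$partition)
  expect_message(scores <- run_screen(sdir), "rank 0")
  expect_equal(nrow(scores), 1L)
  expect_equal(scores$score, fx$score_star, tolerance = 1e-9)
})

test_that("AF2-dialect pair directories are screened via partition sidecars", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  fx <- make_pae_fixture(15, 25, interface_fraction = 0.5, pae_interface = 2,
                         seed = 4, dir = sdir, dialect = "af2_nested_array",
                         bait_name = "SENSOR", prey_name = "PREY")
  scores <- run_screen(sdir)
  expect_equal(scores$length_bait, 15L)
  expect_equal(scores$length_prey, 25L)
  expect_equal(scores$oc, fx$oc_star, tolerance = 1e-9)
})

test_that("run_report aggregates interface, profile and concordance outputs", {
  td <- withr::local_tempdir()
  # a crossed score table supplied twice: every prey must have rho = 1
  profiles <- make_profile_fixture(n_prey = 8, n_bait = 6, seed = 17)
  long <- tibble::as_tibble(unclass(profiles), rownames = "prey") |>
    tidyr::pivot_longer(-prey, names_to = "bait", values_to = "score")
  rep1 <- run_report(long, spry_scores = long,
                     output_dir = file.path(td, "rep"))
  expect_equal(rep1$concordance$per_prey$rho, rep(1, 8),
               tolerance = 1e-12)
  expect_equal(nrow(rep1$profile_pairs), choose(8, 2))
  expect_true(file.exists(file.path(td, "rep", "profile_pairs.tsv")))
  expect_true(file.exists(file.path(td, "rep", "concordance_per_prey.tsv")))
  # no structures supplied: no interface table, no error
  expect_null(rep1$interface_summaries)
  expect_false(file.exists(file.path(td, "rep", "interface_summaries.tsv")))
})

test_that("run_report summarizes structures against generator declarations", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  pair_dir <- file.path(sdir, "BAITX__PREYX")
  sf <- make_structure_fixture(planted_contacts_spec(), dir = pair_dir,
                               n_decoys_a = 0, n_decoys_b = 0)
  lens <- chain_lengths(sf$model)
  part <- chain_partition(lens, bait = "A", prey = "B")
  pae <- pae_matrix(matrix(1, sum(lens$length), sum(lens$length)))
  write_pae_json(pae, file.path(pair_dir, "pae_rank_0.json"),
                 dialect = "af3_full_data", partition = part)
  scores <- run_screen(sdir)
  ann <- tibble::tibble(protein = "PREYX", domain = "SPRY",
                        start = 1L, end = 2L)
  # one extra pair directory without a structure draws a warning message
  make_pae_fixture(4, 4, dir = sdir, bait_name = "NOSTRUCT",
                   prey_name = "PREYY")
  scores <- run_screen(sdir)
  expect_message(
    rep <- run_report(scores, annotations = ann, predictions_dir = sdir),
    "without structures")
  expect_equal(nrow(rep$interface_summaries), 1L)
  expect_equal(rep$interface_summaries$n_contacts, 3L)
  expect_equal(rep$interface_summaries$n_salt_bridges, 1L)
  expect_equal(rep$interface_summaries$spry_fraction, 2 / 3)
})

test_that("config files merge over defaults and reject unknown keys", {
  td <- withr::local_tempdir()
  cfgf <- file.path(td, "cfg.yaml")
  yaml::write_yaml(list(threshold = 3.0, ec_slope = 100), cfgf)
  cfg <- load_config(cfgf)
  expect_equal(cfg$threshold, 3.0)
  expect_equal(cfg$ec_slope, 100)
  expect_equal(cfg$ec_intercept, default_config()$ec_intercept)
  yaml::write_yaml(list(not_a_key = 1), cfgf)
  expect_error(load_config(cfgf), class = "spryscreen_config_error")
})

test_that("the resolved-config echo re-runs to identical outputs", {
  td <- withr::local_tempdir()
  sdir <- file.path(td, "preds")
  make_screen_fixture(sdir, n_pairs = 3, n_strong = 1, seed = 77)
  o1 <- file.path(td, "o1")
  run_screen(sdir, threshold = 3.2, output_dir = o1)
  echoed <- load_config(file.path(o1, "resolved_config.yaml"))
  o2 <- file.path(td, "o2")
  run_screen(sdir, config = echoed, output_dir = o2)
  b <- function(p) readBin(p, raw(), file.size(p))
  expect_identical(b(file.path(o1, "interactions.tsv")),
                   b(file.path(o2, "interactions.tsv")))
})
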