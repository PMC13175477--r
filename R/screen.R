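# Batch orchestration: directory conventions, config resolution,
# end-to-end screen and report runs.

#' Default run configuration
#'
#' Every tunable of the pipeline, fully materialized. `load_config()`
#' merges a YAML file over these defaults; direct arguments to
#' [run_screen()]/[run_report()] take precedence over both.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    max_pae_default = 31.75,
    score_orientation = "oc_over_ec",
    ec_length_definition = "combined",
    ec_slope = 243.9,
    ec_intercept = 279484,
    threshold = 2.5,
    contact_cutoff = 5.0,
    salt_bridge_cutoff = 4.0,
    polar_cutoff = 3.5,
    identity_denominator = "alignment",
    min_common_baits = 3L,
    spry_domain = "SPRY"
  )
}

#' @rdname default_config
#' @param path YAML file of configuration overrides.
#' @export
load_config <- function(path) {
  overrides <- yaml::read_yaml(path)
  cfg <- modifyList(default_config(), overrides)
  unknown <- setdiff(names(overrides), names(default_config()))
  if (length(unknown))
    stop_spry(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
              "config_error")
  cfg
}

config_calibration <- function(config) {
  calibration_model(config$ec_slope, config$ec_intercept,
                    length_definition = config$ec_length_definition)
}

#' Load one prediction directory
#'
#' A pair directory is named `<bait>__<prey>` and holds one PAE JSON
#' per ranked model (`pae_rank_<k>.json`, or a single `*.json`);
#' only the top-ranked model (`rank 0`, or the lowest rank present) is
#' loaded -- others are noted in a log line. Chain partitions come from
#' the AF3 file itself (`token_chain_ids`), from a `partition.tsv`
#' (columns `chain`, `length`, `role`), or from an accompanying
#' structure (`*.pdb`/`*.cif`), in that order of preference; a conflict
#' between sources is an error.
#'
#' @param pair_dir Path to the pair directory.
#' @param config Configuration list (see [default_config()]).
#' @return A [complex_prediction()].
#' @export
load_prediction <- function(pair_dir, config = default_config()) {
  base <- basename(normalizePath(pair_dir, mustWork = FALSE))
  parts <- strsplit(base, "__", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop_spry(sprintf(
      "Pair directory '%s' is not named '<bait>__<prey>'.", base),
      "format_error")
  jsons <- list.files(pair_dir, pattern = "\\.json$", full.names = TRUE)
  if (length(jsons) == 0L)
    stop_spry(sprintf("No PAE JSON in '%s'.", pair_dir), "io_error")
  ranks <- suppressWarnings(
    as.integer(sub("^.*rank[_-]?(\\d+).*$", "\\1", basename(jsons))))
  ranks[is.na(ranks)] <- 0L
  keep <- which(ranks == min(ranks))[1L]
  if (length(jsons) > 1L)
    spry_log("INFO", sprintf(
      "%s: %d ranked models; scoring only rank %d (%s).",
      base, length(jsons), ranks[keep], basename(jsons[keep])))
  pae_path <- jsons[keep]

  struct_files <- list.files(pair_dir, pattern = "\\.(pdb|cif)$",
                             full.names = TRUE)
  model <- if (length(struct_files)) read_structure(struct_files[1L]) else NULL

  hint <- NULL
  part_tsv <- file.path(pair_dir, "partition.tsv")
  if (file.exists(part_tsv)) {
    hint <- read_partition_tsv(part_tsv)
  } else if (!is.null(model)) {
    lens <- chain_lengths(model)
    if (nrow(lens) >= 2L)
      hint <- chain_partition(lens, bait = lens$chain[1L],
                              prey = lens$chain[2L])
  }
  parsed <- read_pae_json(pae_path, partition = hint,
                          max_pae_default = config$max_pae_default)
  complex_prediction(base, parts[1L], parts[2L], parsed$pae,
                     parsed$partition, model = model,
                     model_rank = min(ranks))
}

#' Run the batch interaction screen over a prediction directory
#'
#' Scores every pair directory under `input_dir` (top-ranked model
#' only), classifies against the cutoff, and returns the sorted score
#' table. Individual unparseable pairs are logged and counted, never
#' silently dropped; an input directory yielding zero scorable pairs is
#' an error.
#'
#' @param input_dir Directory of pair subdirectories (see
#'   [load_prediction()] for the layout).
#' @param config Configuration list; `calibration` and `threshold`
#'   override its scoring entries when given.
#' @param calibration Optional `spry_calibration`.
#' @param threshold Optional cutoff override.
#' @param output_dir If non-`NULL`, writes `interactions.tsv`, a
#'   `high_confidence.tsv` filtered view, `resolved_config.yaml` and a
#'   per-pair `run_log.tsv` there.
#' @return Tibble of class `spry_screen`, one row per scored pair,
#'   sorted by (bait, prey); attributes `n_failed` and `failures`
#'   record skipped pairs.
#' @export
run_screen <- function(input_dir, config = default_config(),
                       calibration = NULL, threshold = NULL,
                       output_dir = NULL) {
  if (!dir.exists(input_dir))
    stop_spry(sprintf("Input directory not found: %s", input_dir), "io_error")
  calibration <- calibration %||% config_calibration(config)
  threshold <- threshold %||% config$threshold
  pair_dirs <- list.dirs(input_dir, recursive = FALSE)
  if (length(pair_dirs) == 0L)
    stop_spry(sprintf("No pair directories under '%s'.", input_dir),
              "empty_input_error")
  status <- vector("list", length(pair_dirs))
  records <- vector("list", length(pair_dirs))
  for (i in seq_along(pair_dirs)) {
    pd <- pair_dirs[i]
    res <- tryCatch({
      pred <- load_prediction(pd, config)
      rec <- score_complex(pred, calibration, threshold,
                           orientation = config$score_orientation)
      list(record = rec, status = "ok", message = "")
    }, error = function(e) {
      spry_log("WARN", sprintf("Skipping '%s': %s", basename(pd),
                               conditionMessage(e)))
      list(record = NULL, status = "failed", message = conditionMessage(e))
    })
    records[[i]] <- res$record
    status[[i]] <- tibble(pair = basename(pd), status = res$status,
                          message = res$message)
  }
  failures <- bind_rows(status) |> filter(.data$status == "failed")
  scores <- bind_rows(records)
  if (nrow(scores) == 0L)
    stop_spry(sprintf("No parseable predictions under '%s'.", input_dir),
              "empty_input_error")
  scores <- scores[order(scores$bait, scores$prey, method = "radix"), ]
  attr(scores, "n_failed") <- nrow(failures)
  attr(scores, "failures") <- failures
  attr(scores, "threshold") <- threshold
  class(scores) <- c("spry_screen", class(scores))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_interaction_table(scores, file.path(output_dir, "interactions.tsv"))
    hc <- scores[scores$high_confidence, , drop = FALSE]
    hc_path <- file.path(output_dir, "high_confidence.tsv")
    if (nrow(hc) > 0L) write_interaction_table(hc, hc_path)
    else writeLines(paste(c("bait", "prey", "length_bait", "length_prey",
                            "oc", "ec", "score", "high_confidence"),
                          collapse = "\t"), hc_path)
    resolved <- modifyList(config, list(
      threshold = threshold, ec_slope = calibration$slope,
      ec_intercept = calibration$intercept,
      ec_length_definition = calibration$length_definition))
    yaml::write_yaml(resolved, file.path(output_dir, "resolved_config.yaml"))
    readr::write_tsv(bind_rows(status), file.path(output_dir, "run_log.tsv"))
  }
  scores
}

#' Residue-level and profile analytics over a finished screen
#'
#' Aggregates the downstream analyses: interface summaries for pairs
#' whose prediction directories carry a structure, prey-by-prey
#' binding-profile correlations (with percent identity when sequences
#' are supplied), and full-length vs SPRY-only concordance when a
#' second score table is given.
#'
#' @param scores Score table (a `spry_screen` or anything
#'   [binding_profile()] accepts).
#' @param annotations Optional domain-annotation tibble.
#' @param predictions_dir Optional directory of pair subdirectories with
#'   structures; pairs referenced by `scores` but lacking a structure
#'   get a warning and no summary row.
#' @param spry_scores Optional SPRY-only score table for concordance.
#' @param sequences Optional named character vector of prey sequences
#'   for percent-identity statistics.
#' @param config Configuration list.
#' @param output_dir If non-`NULL`, writes the result tables as TSV.
#' @return List of class `spry_report`: `interface_summaries`,
#'   `profile_pairs`, `identity_profile_correlation`, `concordance`
#'   (any of which may be `NULL` when inputs were not supplied).
#' @export
run_report <- function(scores, annotations = NULL, predictions_dir = NULL,
                       spry_scores = NULL, sequences = NULL,
                       config = default_config(), output_dir = NULL) {
  profiles <- binding_profile(if (is.matrix(scores)) scores else
    as_tibble(scores)[, c("bait", "prey", "score")])

  interface_summaries <- NULL
  if (!is.null(predictions_dir)) {
    pair_dirs <- list.dirs(predictions_dir, recursive = FALSE)
    has_struct <- vapply(pair_dirs, function(pd)
      length(list.files(pd, pattern = "\\.(pdb|cif)$")) > 0, logical(1))
    if (any(!has_struct))
      spry_log("WARN", sprintf(
        "%d pair(s) without structures; interface summaries omitted for them.",
        sum(!has_struct)))
    interface_summaries <- bind_rows(lapply(pair_dirs[has_struct], function(pd)
      summarize_interface(load_prediction(pd, config), annotations,
                          cutoff = config$contact_cutoff,
                          salt_bridge_cutoff = config$salt_bridge_cutoff,
                          polar_cutoff = config$polar_cutoff,
                          spry_domain = config$spry_domain)))
  }

  cormat <- profile_correlation_matrix(profiles,
                                       min_common = config$min_common_baits)
  preys <- rownames(cormat)
  idx <- which(upper.tri(cormat), arr.ind = TRUE)
  profile_pairs <- tibble(
    prey_a = preys[idx[, 1L]], prey_b = preys[idx[, 2L]],
    pearson_r = cormat[idx],
    n_common_baits = apply(idx, 1L, function(ij)
      sum(is.finite(profiles[ij[1L], ]) & is.finite(profiles[ij[2L], ]))))
  identity_profile_correlation <- NULL
  if (!is.null(sequences)) {
    known <- profile_pairs$prey_a %in% names(sequences) &
      profile_pairs$prey_b %in% names(sequences)
    profile_pairs$percent_identity <- NA_real_
    profile_pairs$percent_identity[known] <- purrr::map2_dbl(
      profile_pairs$prey_a[known], profile_pairs$prey_b[known],
      function(a, b) pairwise_identity(
        sequences[[a]], sequences[[b]],
        denominator = config$identity_denominator))
    ivp <- tryCatch(identity_vs_profile(profile_pairs),
                    spryscreen_insufficient_data_error = function(e) NULL)
    identity_profile_correlation <- ivp$correlation
  }

  concordance <- NULL
  if (!is.null(spry_scores)) {
    spry_profiles <- binding_profile(if (is.matrix(spry_scores)) spry_scores
                                     else as_tibble(spry_scores)[, c("bait", "prey", "score")])
    concordance <- fullspry_concordance(profiles, spry_profiles,
                                        min_common = config$min_common_baits)
  }

  out <- list(interface_summaries = interface_summaries,
              profile_pairs = profile_pairs,
              identity_profile_correlation = identity_profile_correlation,
              concordance = concordance)
  class(out) <- "spry_report"
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(interface_summaries))
      readr::write_tsv(
        interface_summaries |> select(-"domain_counts"),
        file.path(output_dir, "interface_summaries.tsv"))
    readr::write_tsv(profile_pairs, file.path(output_dir, "profile_pairs.tsv"))
    if (!is.null(concordance)) {
      readr::write_tsv(concordance$per_prey,
                       file.path(output_dir, "concordance_per_prey.tsv"))
      readr::write_tsv(concordance$histogram,
                       file.path(output_dir, "concordance_histogram.tsv"))
    }
  }
  out
}

#' @export
print.spry_report <- function(x, ...) {
  cat("<spry_report>\n")
  if (!is.null(x$interface_summaries))
    cat(sprintf("  interface summaries: %d pair(s)\n",
                nrow(x$interface_summaries)))
  cat(sprintf("  profile pairs: %d\n", nrow(x$profile_pairs)))
  if (!is.null(x$identity_profile_correlation))
    cat(sprintf("  identity vs profile correlation: %.3f\n",
                x$identity_profile_correlation))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance: %d prey(s)\n", nrow(x$concordance$per_prey)))
  invisible(x)
}
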