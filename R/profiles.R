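# Binding-profile analytics: sequence identity, profile correlations,
# full-length vs SPRY-only concordance.

#' Build a binding-profile matrix
#'
#' A binding profile is the vector of interaction scores of one prey
#' across all baits; the matrix stacks these as prey rows x bait
#' columns. Missing entries (pairs never predicted) are `NA`.
#'
#' @param scores Either a numeric matrix with prey rownames and bait
#'   colnames, or a long-format data frame with columns `bait`, `prey`,
#'   `score` (e.g. a [run_screen()] result or an ingested supplementary
#'   score table).
#' @return A numeric matrix of class `binding_profile`.
#' @export
binding_profile <- function(scores) {
  if (is.matrix(scores)) {
    m <- scores
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop_spry("Profile matrix needs prey rownames and bait colnames.",
                "format_error")
  } else {
    scores <- as_tibble(scores)
    if (!all(c("bait", "prey", "score") %in% names(scores)))
      stop_spry("Long-format scores need columns bait, prey, score.",
                "format_error")
    if (anyDuplicated(scores[, c("bait", "prey")]))
      stop_spry("Duplicate bait/prey pairs in score table.", "format_error")
    wide <- tidyr::pivot_wider(scores[, c("bait", "prey", "score")],
                               names_from = "bait", values_from = "score")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$prey
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_spry("Prey and bait labels must be unique.", "format_error")
  if (any(m < 0, na.rm = TRUE))
    stop_spry("Interaction scores must be >= 0.", "range_error")
  class(m) <- c("binding_profile", class(m))
  m
}

#' Read a binding-profile matrix from TSV/CSV
#'
#' Accepts wide format (first column prey names, remaining columns one
#' bait each) or long format (columns `bait`, `prey`, `score`; extra
#' columns ignored). Column-name mapping for third-party tables is
#' handled via `col_map`.
#'
#' @param path Path to a `.tsv` or `.csv` file.
#' @param format `"auto"` (long when the bait/prey/score columns are all
#'   present after mapping), `"wide"` or `"long"`.
#' @param col_map Named character vector mapping file column names onto
#'   `bait`, `prey`, `score`, e.g.
#'   `c(bait = "Sensor", prey = "SPRY_protein", score = "Interaction_score")`.
#' @return A `binding_profile` matrix.
#' @export
read_profile_table <- function(path, format = c("auto", "wide", "long"),
                               col_map = NULL) {
  format <- match.arg(format)
  reader <- if (tolower(tools::file_ext(path)) == "csv")
    readr::read_csv else readr::read_tsv
  tab <- reader(path, col_types = readr::cols(), progress = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map))
      names(tab)[names(tab) == col_map[[std]]] <- std
  is_long <- all(c("bait", "prey", "score") %in% names(tab))
  if (format == "long" && !is_long)
    stop_spry("Long format requires columns bait, prey, score.",
              "format_error")
  if (format == "auto") format <- if (is_long) "long" else "wide"
  if (format == "long") return(binding_profile(tab))
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(tab[[1]])
  binding_profile(m)
}

#' Pairwise percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with a standard protein
#' substitution matrix and affine gaps, via \pkg{Biostrings}. Identity
#' is `100 * matches / alignment_length` by default, so gap columns
#' count against identity; the `shorter_sequence` denominator is
#' available because conventions differ between tools.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty strings).
#' @param denominator `"alignment"` (alignment length including gaps) or
#'   `"shorter_sequence"`.
#' @param substitution_matrix Name of a \pkg{Biostrings} scoring matrix.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              denominator = c("alignment", "shorter_sequence"),
                              substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5) {
  denominator <- match.arg(denominator)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_spry("Sequences must be non-empty.", "empty_input_error")
  mat <- get(data(list = substitution_matrix, package = "Biostrings",
                  envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  type <- if (denominator == "alignment") "PID1" else "PID3"
  Biostrings::pid(aln, type = type)
}

pearson_or_na <- function(x, y, min_common = 3L) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_common) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Prey-by-prey correlation matrix of binding profiles
#'
#' Pearson correlation between every pair of prey rows, computed over
#' baits present in both profiles. Entries with fewer than `min_common`
#' shared baits, or where either profile is constant, are undefined and
#' reported `NA` (never 0).
#'
#' @param profiles A `binding_profile` matrix with `>= 2` prey rows.
#' @param min_common Minimum number of shared baits.
#' @return Symmetric numeric matrix (prey x prey) with unit diagonal
#'   where defined.
#' @export
profile_correlation_matrix <- function(profiles, min_common = 3L) {
  if (nrow(profiles) < 2L)
    stop_spry("Need >= 2 prey rows.", "format_error")
  preys <- rownames(profiles)
  n <- length(preys)
  out <- matrix(NA_real_, n, n, dimnames = list(preys, preys))
  for (i in seq_len(n)) for (j in i:n) {
    r <- if (i == j) {
      xi <- profiles[i, ]
      if (sum(is.finite(xi)) >= min_common && stats::sd(xi[is.finite(xi)]) > 0)
        1.0 else NA_real_
    } else {
      pearson_or_na(profiles[i, ], profiles[j, ], min_common)
    }
    out[i, j] <- out[j, i] <- r
  }
  out
}

#' Relate SPRY sequence identity to binding-profile similarity
#'
#' Takes per-pair statistics (percent identity and profile Pearson r)
#' and computes the single overall correlation between the two across
#' pairs -- the screen-level test of whether similar SPRY sequences
#' imply similar target preferences.
#'
#' @param stats Data frame with columns `prey_a`, `prey_b`,
#'   `percent_identity`, `pearson_r` (rows with `NA` `pearson_r` are
#'   dropped as undefined).
#' @return List with `pairs` (the defined rows) and `correlation`
#'   (scalar Pearson correlation of identity vs profile r).
#' @export
identity_vs_profile <- function(stats) {
  stats <- as_tibble(stats)
  need <- c("prey_a", "prey_b", "percent_identity", "pearson_r")
  if (!all(need %in% names(stats)))
    stop_spry(paste("`stats` needs columns", paste(need, collapse = ", ")),
              "format_error")
  defined <- stats[is.finite(stats$pearson_r) &
                     is.finite(stats$percent_identity), , drop = FALSE]
  if (nrow(defined) < 3L)
    stop_spry(sprintf("Only %d defined pairs; need >= 3.", nrow(defined)),
              "insufficient_data_error")
  list(pairs = defined,
       correlation = cor(defined$percent_identity, defined$pearson_r))
}

#' Concordance between full-length and SPRY-only screens
#'
#' For every prey present in both score matrices, the Spearman rank
#' correlation (average ranks for ties) between its full-length and
#' SPRY-only score vectors over shared baits, plus a frequency histogram
#' of the coefficients over `[-1, 1]` in bins of 0.1.
#'
#' @param full,spry_only `binding_profile` matrices.
#' @param min_common Minimum shared baits per compared prey.
#' @return Object of class `spry_concordance`: list with `per_prey`
#'   (tibble `prey`, `rho`, `n_common`) and `histogram` (tibble
#'   `bin_low`, `bin_high`, `count`).
#' @export
fullspry_concordance <- function(full, spry_only, min_common = 3L) {
  preys <- intersect(rownames(full), rownames(spry_only))
  baits <- intersect(colnames(full), colnames(spry_only))
  if (length(preys) == 0L)
    stop_spry("No prey shared between the two score matrices.",
              "no_overlap_error")
  per_prey <- purrr::map(preys, function(p) {
    x <- full[p, baits]; y <- spry_only[p, baits]
    ok <- is.finite(x) & is.finite(y)
    rho <- if (sum(ok) >= min_common)
      cor(x[ok], y[ok], method = "spearman") else NA_real_
    tibble(prey = p, rho = rho, n_common = sum(ok))
  }) |> bind_rows()
  breaks <- seq(-1, 1, by = 0.1)
  counts <- graphics::hist(per_prey$rho[is.finite(per_prey$rho)],
                           breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  out <- list(per_prey = per_prey,
              histogram = tibble(bin_low = head(breaks, -1),
                                 bin_high = breaks[-1],
                                 count = counts))
  class(out) <- "spry_concordance"
  out
}

#' @export
print.spry_concordance <- function(x, ...) {
  rho <- x$per_prey$rho
  cat(sprintf(
    "<spry_concordance> %d preys; median rho = %.3f (%d undefined)\n",
    nrow(x$per_prey), stats::median(rho, na.rm = TRUE), sum(!is.finite(rho))))
  invisible(x)
}

#' @export
tidy.spry_concordance <- function(x, ...) x$per_prey

#' @export
glance.spry_concordance <- function(x, ...) {
  rho <- x$per_prey$rho[is.finite(x$per_prey$rho)]
  tibble(n_prey = nrow(x$per_prey), n_defined = length(rho),
         median_rho = stats::median(rho), mean_rho = mean(rho))
}
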