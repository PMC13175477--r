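#' Reverse a PAE matrix
#'
#' Turns aligned error into "contact mass": every entry becomes
#' `max_pae - value`, so a perfectly confident residue pair (PAE 0)
#' contributes the full ceiling and a pair at the ceiling contributes
#' nothing. Keeping the subtraction (rather than a reciprocal) preserves
#' units and bounds: all reversed entries lie in `[0, max_pae]`.
#'
#' @param pae A [pae_matrix()].
#' @return A numeric matrix of reversed values.
#' @export
reverse_pae <- function(pae) {
  stopifnot(inherits(pae, "pae_matrix"))
  pae$max_pae - pae$values
}

#' Observed contacts: grand sum of reversed PAE over inter-chain blocks
#'
#' Sums the reversed PAE over BOTH rectangular off-diagonal blocks
#' (bait rows x prey columns and prey rows x bait columns). PAE is
#' asymmetric, and summing both blocks makes the result invariant to
#' which chain is labeled bait. Intra-chain entries never contribute.
#'
#' @param reversed Square numeric matrix from [reverse_pae()].
#' @param partition A [chain_partition()] consistent with the matrix
#'   dimension.
#' @return Scalar observed contacts (reversed-PAE units), `>= 0`.
#' @export
observed_contacts <- function(reversed, partition) {
  if (!is.matrix(reversed) || nrow(reversed) != ncol(reversed))
    stop_spry("`reversed` must be a square matrix.", "dimension_error")
  if (nrow(reversed) != partition_total_length(partition))
    stop_spry(sprintf(
      "Partition lengths sum to %d but matrix is %d x %d.",
      partition_total_length(partition), nrow(reversed), ncol(reversed)),
      "dimension_error")
  bi <- partition_range(partition, partition$bait)
  pi <- partition_range(partition, partition$prey)
  sum(reversed[bi, pi, drop = FALSE]) + sum(reversed[pi, bi, drop = FALSE])
}

#' Calibration of expected contacts against protein length
#'
#' `calibration_model()` builds one from known coefficients;
#' [fit_calibration()] estimates one from (length, observed-contacts)
#' pairs. `default_calibration()` returns the line fitted on the
#' proteome-wide single-bait (ZAP) screen, EC = 243.9 x length + 279,484.
#'
#' @param slope Reversed-PAE units per residue.
#' @param intercept Reversed-PAE units.
#' @param n_points Number of points behind the fit (0 for a fixed line).
#' @param r_squared Coefficient of determination of the fit, if any.
#' @param length_definition `"combined"` (bait + prey residues, the
#'   default, which generalizes across baits) or `"prey_only"`.
#' @return An object of class `spry_calibration`.
#' @export
calibration_model <- function(slope, intercept, n_points = 0L,
                              r_squared = NA_real_,
                              length_definition = c("combined", "prey_only")) {
  length_definition <- match.arg(length_definition)
  if (!is_scalar_number(slope) || !is_scalar_number(intercept))
    stop_spry("Calibration slope and intercept must be finite scalars.",
              "format_error")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_spry("r_squared must lie in [0, 1].", "range_error")
  structure(
    list(slope = slope, intercept = intercept, n_points = as.integer(n_points),
         r_squared = r_squared, length_definition = length_definition),
    class = "spry_calibration")
}

#' @rdname calibration_model
#' @export
default_calibration <- function(length_definition = c("combined", "prey_only")) {
  calibration_model(243.9, 279484, length_definition = match.arg(length_definition))
}

#' @export
print.spry_calibration <- function(x, ...) {
  cat(sprintf("<spry_calibration> EC = %g x length + %g (%s length%s)\n",
              x$slope, x$intercept, x$length_definition,
              if (x$n_points > 0)
                sprintf("; fit on %d points, R^2 = %.4f", x$n_points, x$r_squared)
              else ""))
  invisible(x)
}

#' Fit the expected-contacts calibration line
#'
#' Ordinary least squares of observed contacts on protein length. Large
#' proteins yield large observed-contacts sums simply because their
#' inter-chain blocks are big, so the screen normalizes by this fitted
#' expectation.
#'
#' @param points Data frame with columns `length` and `oc`.
#' @param length_definition Recorded on the model (see
#'   [calibration_model()]); does not change the fit.
#' @return An object of class `spry_calibration`.
#' @export
fit_calibration <- function(points,
                            length_definition = c("combined", "prey_only")) {
  length_definition <- match.arg(length_definition)
  points <- as_tibble(points)
  if (!all(c("length", "oc") %in% names(points)))
    stop_spry("`points` needs columns `length` and `oc`.", "format_error")
  points <- points[complete.cases(points[, c("length", "oc")]), ]
  if (nrow(points) < 2L || length(unique(points$length)) < 2L)
    stop_spry("Need >= 2 points with >= 2 distinct lengths to fit.",
              "degenerate_fit_error")
  fit <- lm(oc ~ length, data = points)
  cs <- coef(fit)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- calibration_model(unname(cs["length"]), unname(cs["(Intercept)"]),
                           n_points = nrow(points), r_squared = r2,
                           length_definition = length_definition)
  out$data <- points
  out
}

#' @export
tidy.spry_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.spry_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, n_points = x$n_points,
         length_definition = x$length_definition)
}

#' Expected contacts for a protein length
#'
#' Evaluates the calibration line. A non-positive expectation means the
#' calibration is unfit for this length (e.g. extrapolating a noisy fit
#' far below its data) and is an error rather than a silent negative
#' score denominator.
#'
#' @param length Residue count (per the model's `length_definition`).
#' @param model A `spry_calibration`.
#' @return Scalar expected contacts, `> 0`.
#' @export
expected_contacts <- function(length, model = default_calibration()) {
  stopifnot(inherits(model, "spry_calibration"))
  if (any(length < 1))
    stop_spry("`length` must be >= 1.", "range_error")
  ec <- model$slope * length + model$intercept
  if (any(ec <= 0))
    stop_spry(sprintf(
      "Expected contacts <= 0 at length %s; calibration unfit for this length.",
      paste(length[ec <= 0], collapse = ", ")), "calibration_domain_error")
  ec
}

#' Interaction score
#'
#' Ratio of observed to expected contacts. Background pairs sit near 1
#' (their interface mass is what length alone predicts); confident
#' interfaces push the score well above 1. The default orientation is
#' OC/EC so that high score means strong interface; `"ec_over_oc"` is
#' available for the inverted convention.
#'
#' @param oc Observed contacts (`>= 0`).
#' @param ec Expected contacts (`> 0`).
#' @param orientation `"oc_over_ec"` (default) or `"ec_over_oc"`.
#' @return Scalar score, `>= 0`.
#' @export
interaction_score <- function(oc, ec, orientation = c("oc_over_ec", "ec_over_oc")) {
  orientation <- match.arg(orientation)
  if (any(ec <= 0))
    stop_spry("`ec` must be > 0.", "calibration_domain_error")
  if (any(oc < 0))
    stop_spry("`oc` must be >= 0.", "range_error")
  if (orientation == "oc_over_ec") oc / ec else ec / oc
}

#' Classify a score against the high-confidence cutoff
#'
#' Strictly-greater-than comparison against the screen's cutoff
#' (default 2.5, the level above which known SPRY-sensor interactions
#' scored). Raw floating values are compared; no rounding.
#'
#' @param score Numeric score(s), `>= 0`.
#' @param threshold Positive cutoff.
#' @return Logical, `TRUE` iff `score > threshold`.
#' @export
classify <- function(score, threshold = 2.5) {
  if (!is_scalar_number(threshold) || threshold <= 0)
    stop_spry("`threshold` must be a positive scalar.", "range_error")
  if (any(score < 0)) stop_spry("`score` must be >= 0.", "range_error")
  score > threshold
}

#' Score one complex prediction
#'
#' Full per-pair pipeline: reverse the PAE, sum the inter-chain blocks
#' (OC), evaluate the length calibration (EC), take the ratio and
#' classify.
#'
#' @param pred A [complex_prediction()].
#' @param model A `spry_calibration`.
#' @param threshold High-confidence cutoff.
#' @param orientation Score orientation, see [interaction_score()].
#' @return One-row tibble with columns `pair_id`, `bait`, `prey`,
#'   `length_bait`, `length_prey`, `oc`, `ec`, `score`,
#'   `high_confidence`, `threshold_used`.
#' @export
score_complex <- function(pred, model = default_calibration(), threshold = 2.5,
                          orientation = c("oc_over_ec", "ec_over_oc")) {
  stopifnot(inherits(pred, "complex_prediction"))
  orientation <- match.arg(orientation)
  part <- pred$partition
  oc <- observed_contacts(reverse_pae(pred$pae), part)
  len_bait <- part$chains$length[match(part$bait, part$chains$chain)]
  len_prey <- part$chains$length[match(part$prey, part$chains$chain)]
  len <- switch(model$length_definition,
                combined = len_bait + len_prey,
                prey_only = len_prey)
  ec <- expected_contacts(len, model)
  score <- interaction_score(oc, ec, orientation)
  tibble(
    pair_id = pred$pair_id, bait = pred$bait_name, prey = pred$prey_name,
    length_bait = as.integer(len_bait), length_prey = as.integer(len_prey),
    oc = oc, ec = ec, score = score,
    high_confidence = classify(score, threshold),
    threshold_used = threshold)
}
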