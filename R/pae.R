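#' Construct a PAE matrix object
#'
#' A `pae_matrix` holds the square predicted-aligned-error matrix of a
#' complex prediction together with the ceiling of the error scale
#' (`max_pae`). Values are in Angstroms; entry `[i, j]` is the expected
#' positional error of residue i when the model is aligned on residue j.
#'
#' @param values Square numeric matrix of aligned-error values (Angstrom).
#' @param max_pae Maximum representable error of the dialect (Angstrom).
#'   The conventional AlphaFold ceiling 31.75 is the default.
#' @param source_dialect One of `"af2_pairwise_list"`, `"af2_nested_array"`,
#'   `"af3_full_data"`, or `"synthetic"` for generated fixtures.
#'
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(values, max_pae = 31.75,
                       source_dialect = c("synthetic", "af2_pairwise_list",
                                          "af2_nested_array", "af3_full_data")) {
  source_dialect <- match.arg(source_dialect)
  if (!is.matrix(values) || !is.numeric(values))
    stop_spry("`values` must be a numeric matrix.", "format_error")
  if (nrow(values) != ncol(values))
    stop_spry(sprintf("PAE matrix must be square, got %d x %d.",
                      nrow(values), ncol(values)), "dimension_error")
  if (!is_scalar_number(max_pae) || max_pae <= 0)
    stop_spry("`max_pae` must be a single positive number.", "range_error")
  if (anyNA(values) || any(values < 0) || any(values > max_pae))
    stop_spry(sprintf("PAE values must lie in [0, %g].", max_pae), "range_error")
  structure(
    list(values = unname(values), max_pae = max_pae,
         source_dialect = source_dialect),
    class = "pae_matrix"
  )
}

#' @export
print.pae_matrix <- function(x, ...) {
  cat(sprintf("<pae_matrix> %d x %d, max_pae = %g (%s)\n",
              nrow(x$values), ncol(x$values), x$max_pae, x$source_dialect))
  invisible(x)
}

#' @export
dim.pae_matrix <- function(x) dim(x$values)

#' Construct a chain partition
#'
#' Records how the rows/columns of a PAE matrix split into chains, and
#' which chain plays the bait (sensor) versus prey (SPRY protein) role.
#'
#' @param chains A data frame with columns `chain` (character) and
#'   `length` (integer residue counts), in matrix order.
#' @param bait,prey Chain identifiers of the bait and prey chains.
#'
#' @return An object of class `chain_partition`.
#' @export
chain_partition <- function(chains, bait, prey) {
  chains <- as_tibble(chains)
  if (!all(c("chain", "length") %in% names(chains)))
    stop_spry("`chains` needs columns `chain` and `length`.", "format_error")
  chains$chain <- as.character(chains$chain)
  chains$length <- as.integer(chains$length)
  if (any(chains$length < 1L))
    stop_spry("Chain lengths must be >= 1.", "format_error")
  if (anyDuplicated(chains$chain))
    stop_spry("Chain identifiers must be unique.", "format_error")
  bait <- as.character(bait); prey <- as.character(prey)
  if (identical(bait, prey))
    stop_spry("Bait and prey chains must differ.", "format_error")
  if (!all(c(bait, prey) %in% chains$chain))
    stop_spry("Bait and prey chains must appear in `chains`.", "format_error")
  structure(list(chains = chains, bait = bait, prey = prey),
            class = "chain_partition")
}

#' @export
print.chain_partition <- function(x, ...) {
  cat(sprintf("<chain_partition> %s (bait = %s, prey = %s)\n",
              paste(sprintf("%s:%d", x$chains$chain, x$chains$length),
                    collapse = " + "),
              x$bait, x$prey))
  invisible(x)
}

partition_total_length <- function(partition) sum(partition$chains$length)

# 1-based index range of a chain within the PAE matrix
partition_range <- function(partition, chain) {
  i <- match(chain, partition$chains$chain)
  if (is.na(i))
    stop_spry(sprintf("Chain '%s' not in partition.", chain), "chain_error")
  ends <- cumsum(partition$chains$length)
  starts <- c(1L, head(ends, -1L) + 1L)
  seq.int(starts[i], ends[i])
}

check_partition_dim <- function(pae, partition) {
  n <- nrow(pae$values)
  total <- partition_total_length(partition)
  if (n != total)
    stop_spry(sprintf(
      "Partition lengths sum to %d but PAE matrix is %d x %d.", total, n, n),
      "dimension_error")
  invisible(TRUE)
}

#' Read a PAE matrix from an AlphaFold-style JSON file
#'
#' Supports the three JSON dialects emitted by common prediction
#' pipelines: the AF2 pairwise record list (`residue1`/`residue2`/
#' `distance` parallel arrays), the AF2 nested array under
#' `predicted_aligned_error`, and the AF3 full-data file with a `pae`
#' array (and, when present, `token_chain_ids` encoding the chain
#' partition). Anything else is rejected rather than guessed, because a
#' wrong partition silently corrupts the observed-contacts sum.
#'
#' @param path Path to the JSON file.
#' @param partition A [chain_partition()] hint. Required for the two AF2
#'   dialects (they carry no chain boundaries) and for AF3 files lacking
#'   `token_chain_ids`. When the file itself encodes chain lengths, a
#'   conflicting hint is an error, not a warning.
#' @param bait,prey Chain roles used when the partition is derived from
#'   the file; defaults: first chain is bait, second is prey.
#' @param max_pae_default Ceiling assumed when the file does not state
#'   `max_predicted_aligned_error`.
#'
#' @return A list with elements `pae` ([pae_matrix()]) and `partition`
#'   ([chain_partition()]).
#' @export
read_pae_json <- function(path, partition = NULL, bait = NULL, prey = NULL,
                          max_pae_default = 31.75) {
  if (!file.exists(path))
    stop_spry(sprintf("PAE file not found: %s", path), "io_error")
  parsed <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop_spry(
      sprintf("Unparseable JSON in '%s': %s", path, conditionMessage(e)),
      "format_error")
  )
  # Some emitters wrap the object in a length-1 array
  if (is.data.frame(parsed) && nrow(parsed) == 1L) parsed <- as.list(parsed[1L, ])
  if (is.list(parsed) && is.null(names(parsed)) && length(parsed) == 1L)
    parsed <- parsed[[1L]]
  unwrap <- function(x) if (is.list(x) && length(x) == 1L && is.null(dim(x))) x[[1L]] else x

  if (!is.null(parsed$pae)) {
    dialect <- "af3_full_data"
    mat <- as.matrix(parsed$pae)
    max_pae <- unwrap(parsed$max_predicted_aligned_error) %||% max_pae_default
    file_partition <- NULL
    ids <- unlist(parsed$token_chain_ids)
    if (!is.null(ids)) {
      r <- rle(as.character(ids))
      if (anyDuplicated(r$values))
        stop_spry(sprintf("Non-contiguous chain ids in '%s'.", path),
                  "format_error")
      file_partition <- tibble(chain = r$values, length = r$lengths)
    }
  } else if (!is.null(parsed$predicted_aligned_error)) {
    dialect <- "af2_nested_array"
    mat <- as.matrix(parsed$predicted_aligned_error)
    max_pae <- unwrap(parsed$max_predicted_aligned_error) %||% max_pae_default
    file_partition <- NULL
  } else if (all(c("residue1", "residue2", "distance") %in% names(parsed))) {
    dialect <- "af2_pairwise_list"
    r1 <- unlist(parsed$residue1); r2 <- unlist(parsed$residue2)
    d <- unlist(parsed$distance)
    n <- max(r1, r2)
    if (length(d) != n * n)
      stop_spry(sprintf(
        "Pairwise PAE list in '%s' has %d entries; expected a full %d x %d grid.",
        path, length(d), n, n), "dimension_error")
    mat <- matrix(NA_real_, n, n)
    mat[cbind(r1, r2)] <- d
    if (anyNA(mat))
      stop_spry(sprintf("Pairwise PAE list in '%s' leaves entries missing.",
                        path), "dimension_error")
    max_pae <- unwrap(parsed$max_predicted_aligned_error) %||% max_pae_default
    file_partition <- NULL
  } else {
    stop_spry(sprintf(
      "Unrecognized PAE dialect in '%s' (expected af2_pairwise_list, af2_nested_array or af3_full_data).",
      path), "format_error")
  }

  if (nrow(mat) != ncol(mat))
    stop_spry(sprintf("PAE matrix in '%s' is %d x %d; must be square.",
                      path, nrow(mat), ncol(mat)), "dimension_error")
  mode(mat) <- "double"

  if (!is.null(file_partition)) {
    if (!is.null(partition)) {
      same <- identical(as.integer(file_partition$length),
                        as.integer(partition$chains$length)) &&
        identical(file_partition$chain, partition$chains$chain)
      if (!same)
        stop_spry(sprintf(
          "Partition hint conflicts with chain ids encoded in '%s'.", path),
          "partition_conflict_error")
    } else {
      if (nrow(file_partition) < 2L)
        stop_spry(sprintf("File '%s' encodes fewer than 2 chains.", path),
                  "chain_count_error")
      partition <- chain_partition(
        file_partition,
        bait = bait %||% file_partition$chain[1L],
        prey = prey %||% file_partition$chain[2L])
    }
  }
  if (is.null(partition))
    stop_spry(sprintf(
      "Dialect '%s' does not encode chain boundaries; supply `partition`.",
      dialect), "missing_partition_error")

  pae <- pae_matrix(mat, max_pae = max_pae, source_dialect = dialect)
  check_partition_dim(pae, partition)
  list(pae = pae, partition = partition)
}

#' Write a PAE matrix to JSON in a chosen dialect
#'
#' Emits the same formats [read_pae_json()] accepts; used by the fixture
#' generator and available for interconversion.
#'
#' @param pae A [pae_matrix()].
#' @param path Output path.
#' @param dialect Target dialect.
#' @param partition A [chain_partition()]; required for
#'   `"af3_full_data"`, which stores chain ids per residue.
#' @return `path`, invisibly.
#' @export
write_pae_json <- function(pae, path,
                           dialect = c("af3_full_data", "af2_nested_array",
                                       "af2_pairwise_list"),
                           partition = NULL) {
  dialect <- match.arg(dialect)
  m <- pae$values
  n <- nrow(m)
  obj <- switch(dialect,
    af3_full_data = {
      if (is.null(partition))
        stop_spry("af3_full_data dialect needs a `partition`.",
                  "missing_partition_error")
      check_partition_dim(pae, partition)
      list(
        pae = m,
        token_chain_ids = rep(partition$chains$chain, partition$chains$length),
        max_predicted_aligned_error = pae$max_pae
      )
    },
    af2_nested_array = list(
      predicted_aligned_error = m,
      max_predicted_aligned_error = pae$max_pae
    ),
    af2_pairwise_list = {
      idx <- expand.grid(residue2 = seq_len(n), residue1 = seq_len(n))
      list(list(
        residue1 = idx$residue1,
        residue2 = idx$residue2,
        distance = m[cbind(idx$residue1, idx$residue2)],
        max_predicted_aligned_error = pae$max_pae
      ))
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
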