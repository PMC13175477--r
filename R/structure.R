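# Structure I/O: thin tidy wrapper over bio3d's PDB/mmCIF parsers.

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # common modified residues mapped to their parent
  MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S", TPO = "T", PTR = "Y"
)

#' Read a predicted structure (PDB or mmCIF) into a tidy atom table
#'
#' Parses all polymer ATOM/HETATM records via \pkg{bio3d} and returns one
#' row per heavy or hydrogen atom with chain, residue and coordinate
#' columns. Residue indices are renumbered 1-based within each chain,
#' preserving file order, so they align with PAE matrix positions.
#'
#' @param path Path to a `.pdb` or `.cif` file (extension decides the
#'   parser).
#' @return A `structure_model`: a tibble with columns `chain`, `resno`
#'   (1-based within chain), `resno_auth` (as in the file), `resid`
#'   (3-letter name), `elety` (atom name), `elesy` (element), `x`, `y`,
#'   `z`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path))
    stop_spry(sprintf("Structure file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    switch(ext,
      cif = suppressWarnings(bio3d::read.cif(path)),
      pdb = bio3d::read.pdb(path),
      stop_spry(sprintf("Unsupported structure extension '.%s' (%s).",
                        ext, path), "format_error")),
    error = function(e) {
      if (inherits(e, "spryscreen_error")) stop(e)
      stop_spry(sprintf("Failed to parse structure '%s': %s",
                        path, conditionMessage(e)), "format_error")
    })
  atoms <- as_tibble(parsed$atom)
  atoms <- atoms[, c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")]
  names(atoms)[names(atoms) == "resno"] <- "resno_auth"
  structure_model(atoms)
}

#' Build a structure model from an atom table
#'
#' Validates and normalizes an atom table into the `structure_model`
#' shape used by the contact routines. Chains must number at least two
#' (the pipeline only handles complexes) and residue indices are
#' renumbered 1-based within each chain.
#'
#' @param atoms Data frame with columns `chain`, `resno_auth` (or
#'   `resno`), `resid`, `elety`, `elesy`, `x`, `y`, `z`.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (!"resno_auth" %in% names(atoms) && "resno" %in% names(atoms))
    names(atoms)[names(atoms) == "resno"] <- "resno_auth"
  need <- c("chain", "resno_auth", "resid", "elety", "elesy", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop_spry(paste0("Atom table lacks columns: ",
                     paste(missing_cols, collapse = ", ")), "format_error")
  atoms <- atoms[, need]
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_spry("Atom coordinates must be finite.", "format_error")
  chains <- unique(atoms$chain)
  if (length(chains) < 2L)
    stop_spry(sprintf("Structure has %d chain(s); a complex needs >= 2.",
                      length(chains)), "chain_count_error")
  # 1-based residue index within each chain, in file order
  atoms <- atoms |>
    group_by(.data$chain) |>
    mutate(resno = match(.data$resno_auth, unique(.data$resno_auth))) |>
    ungroup()
  for (ch in chains) {
    auth <- unique(atoms$resno_auth[atoms$chain == ch])
    if (is.unsorted(auth, strictly = TRUE))
      stop_spry(sprintf(
        "Residue numbers in chain %s are not strictly increasing.", ch),
        "format_error")
  }
  out <- atoms[, c("chain", "resno", "resno_auth", "resid", "elety",
                   "elesy", "x", "y", "z")]
  class(out) <- c("structure_model", class(out))
  out
}

#' Residue counts per chain of a structure model
#'
#' @param model A `structure_model`.
#' @return Tibble with columns `chain`, `length`, in file chain order.
#' @export
chain_lengths <- function(model) {
  model |>
    group_by(.data$chain) |>
    summarise(length = dplyr::n_distinct(.data$resno), .groups = "drop") |>
    dplyr::slice(match(unique(model$chain), .data$chain))
}

#' Extract one-letter sequences per chain
#'
#' Maps 3-letter residue names to 1-letter codes (standard table plus
#' common modified residues such as MSE -> M); unknown names become `X`
#' with a warning.
#'
#' @param model A `structure_model`.
#' @return Named character vector, one sequence per chain.
#' @export
extract_chain_sequences <- function(model) {
  res <- distinct(model, .data$chain, .data$resno, .data$resid)
  letters1 <- AA_3TO1[res$resid]
  if (anyNA(letters1)) {
    unknown <- unique(res$resid[is.na(letters1)])
    warn(paste0("Unknown residue name(s) mapped to 'X': ",
                paste(unknown, collapse = ", ")),
         class = "spryscreen_unknown_residue")
    letters1[is.na(letters1)] <- "X"
  }
  res$letter <- unname(letters1)
  out <- res |>
    arrange(.data$chain, .data$resno) |>
    group_by(.data$chain) |>
    summarise(seq = paste(.data$letter, collapse = ""), .groups = "drop")
  setNames(out$seq, out$chain)
}

#' Bundle one bait-prey prediction
#'
#' Carrier for everything known about one predicted complex: the PAE
#' matrix, the chain partition, and optionally the predicted structure.
#' When a structure is present its per-chain residue counts must match
#' the partition.
#'
#' @param pair_id Identifier, conventionally `"<bait>__<prey>"`.
#' @param bait_name,prey_name Protein names.
#' @param pae A [pae_matrix()].
#' @param partition A [chain_partition()].
#' @param model Optional `structure_model`.
#' @param model_rank Integer rank of the prediction (0 = top-ranked).
#' @return An object of class `complex_prediction`.
#' @export
complex_prediction <- function(pair_id, bait_name, prey_name, pae, partition,
                               model = NULL, model_rank = 0L) {
  check_partition_dim(pae, partition)
  if (!is.null(model)) {
    got <- chain_lengths(model)
    want <- partition$chains
    m <- match(want$chain, got$chain)
    if (anyNA(m) || !identical(as.integer(got$length[m]),
                               as.integer(want$length)))
      stop_spry("Structure chain lengths disagree with the chain partition.",
                "partition_conflict_error")
  }
  structure(
    list(pair_id = pair_id, bait_name = bait_name, prey_name = prey_name,
         pae = pae, partition = partition, model = model,
         model_rank = as.integer(model_rank)),
    class = "complex_prediction")
}

#' @export
print.complex_prediction <- function(x, ...) {
  cat(sprintf("<complex_prediction> %s: %s (bait) x %s (prey), n = %d%s\n",
              x$pair_id, x$bait_name, x$prey_name,
              nrow(x$pae$values),
              if (is.null(x$model)) "" else ", with structure"))
  invisible(x)
}
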