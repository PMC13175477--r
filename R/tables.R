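# Tabular output: the screen's score table, read back for downstream
# analytics.

#' Write an interaction score table
#'
#' Tab-separated, one row per scored pair, sorted lexicographically by
#' (bait, prey) so that equal record sets always produce byte-identical
#' files regardless of input order. Floats are written with 6
#' significant digits.
#'
#' @param records Tibble of score records as produced by
#'   [score_complex()] / [run_screen()] (columns `bait`, `prey`,
#'   `length_bait`, `length_prey`, `oc`, `ec`, `score`,
#'   `high_confidence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path) {
  records <- as_tibble(records)
  need <- c("bait", "prey", "length_bait", "length_prey", "oc", "ec",
            "score", "high_confidence")
  if (nrow(records) == 0L)
    stop_spry("Refusing to write an empty score table.", "format_error")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop_spry(paste0("Records lack columns: ",
                     paste(missing_cols, collapse = ", ")), "format_error")
  records <- records[order(records$bait, records$prey, method = "radix"), need]
  out <- records |>
    mutate(oc = fmt_sig6(.data$oc), ec = fmt_sig6(.data$ec),
           score = fmt_sig6(.data$score),
           high_confidence = ifelse(.data$high_confidence, "TRUE", "FALSE"))
  lines <- c(paste(need, collapse = "\t"),
             do.call(paste, c(unname(as.list(out)), sep = "\t")))
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_spry(
                    sprintf("Cannot write '%s': %s", path,
                            conditionMessage(e)), "io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read an interaction score table
#'
#' @param path TSV written by [write_interaction_table()].
#' @return Tibble with the table's columns (`high_confidence` logical).
#' @export
read_interaction_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    bait = readr::col_character(), prey = readr::col_character(),
    length_bait = readr::col_integer(), length_prey = readr::col_integer(),
    oc = readr::col_double(), ec = readr::col_double(),
    score = readr::col_double(), high_confidence = readr::col_logical()))
}
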