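# Internal helpers: classed conditions, stderr logging, numeric formatting.

stop_spry <- function(msg, class, ...) {
  abort(msg, class = c(paste0("spryscreen_", class), "spryscreen_error"), ...)
}

#' @noRd
spry_log <- function(level = c("INFO", "WARN", "ERROR"), ...) {
  level <- match.arg(level)
  message(sprintf("[%s] %s", level, paste0(...)))
}

# 6 significant digits, no scientific notation drift between platforms
fmt_sig6 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6), scientific = FALSE, trim = TRUE)
  }, character(1))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
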