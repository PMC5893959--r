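# Internal helpers: typed error conditions and small sequence utilities.

pm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "micrantha_error"), call = call))
}

#' @noRd
pm_domain_error <- function(msg) pm_stop(msg, "pm_domain_error", sys.call(-1))

#' @noRd
pm_format_error <- function(msg) pm_stop(msg, "pm_format_error", sys.call(-1))

#' @noRd
pm_schema_error <- function(msg) pm_stop(msg, c("pm_schema_error", "pm_format_error"), sys.call(-1))

#' @noRd
pm_usage_error <- function(msg) pm_stop(msg, "pm_usage_error", sys.call(-1))

pm_saturation_error <- function(msg) pm_stop(msg, "pm_saturation_error", sys.call(-1))

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pm_domain_error(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    pm_domain_error(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}

# Reverse complement of a plain character string (ACGTN, case preserved as upper).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Substring by 1-based closed interval, guarded.
substr1 <- function(x, start, end) {
  if (start < 1L || end > nchar(x) || start > end)
    pm_domain_error(sprintf("interval [%d,%d] outside sequence of length %d",
                            start, end, nchar(x)))
  substr(x, start, end)
}

# Deterministic seed derivation: keep child seeds within 32-bit integer range.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}

is_purine <- function(v) v == "A" | v == "G"

# Transition lookup: A<->G, C<->T.
is_transition_pair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
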