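# Condition helpers: every user-facing failure carries a subclass so callers
# (and the CLI exit-code mapping) can distinguish validation from usage errors.

endoref_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "endoref_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) endoref_stop(msg, "endoref_validation_error")
stop_format     <- function(msg) endoref_stop(msg, "endoref_format_error")
stop_parameter  <- function(msg) endoref_stop(msg, "endoref_parameter_error")
stop_scale      <- function(msg) endoref_stop(msg, "endoref_scale_error")
stop_consistency <- function(msg) endoref_stop(msg, "endoref_consistency_error")
stop_insufficient <- function(msg) endoref_stop(msg, "endoref_insufficient_data_error")

# Sample standard deviation with the n-1 denominator, defined as 0 for n = 1
# (a single technical replicate has no dispersion estimate).
sd1 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) return(0)
  stats::sd(x)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

geometric_mean <- function(x) exp(mean(log(x)))

# Drop samples (columns) containing any NA, warning with the retained size.
# Stability estimators require complete cases across the candidate panel.
complete_case_columns <- function(x, context) {
  bad <- apply(x, 2L, anyNA)
  if (any(bad)) {
    x <- x[, !bad, drop = FALSE]
    warning(sprintf(
      "%s: %d sample(s) with missing values dropped; %d complete sample(s) retained",
      context, sum(bad), ncol(x)
    ), call. = FALSE)
  }
  x
}
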