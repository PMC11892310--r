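# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_arg <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
    stop_arg(sprintf("'%s' must be a single integer >= %d", name, min))
}

assert_prob <- function(x, name, max = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > max)
    stop_arg(sprintf("'%s' must be a single number in [0, %g]", name, max))
}

assert_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
    stop_arg(sprintf("'%s' must be a single number >= %g", name, min))
}

#' Parse a "CHR:START-END" region string
#'
#' @param region character scalar like `"A07:60000000-99000000"`.
#' @return list with elements `chrom`, `start`, `end` (1-based inclusive).
#' @keywords internal
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop_arg("region must look like 'CHR:START-END'")
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}
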