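# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so library functions never
#' clobber a user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("nest_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("nest_io_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_validation(name, " must lie in ",
                    if (strict_lower) "(" else "[", lower, ", ", upper, "]")
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(name, " must be TRUE or FALSE")
  }
  invisible(x)
}

# Named numeric vector from various "gene -> value" inputs (named vector,
# two-column data frame, or single-column matrix with rownames).
as_gene_values <- function(values, arg = "values") {
  if (is.matrix(values)) {
    if (ncol(values) != 1L || is.null(rownames(values))) {
      stop_validation(arg, ": a matrix input must have one column and rownames")
    }
    values <- stats::setNames(as.numeric(values[, 1L]), rownames(values))
  } else if (is.data.frame(values)) {
    if (ncol(values) < 2L) {
      stop_validation(arg, ": a data-frame input needs gene and value columns")
    }
    values <- stats::setNames(as.numeric(values[[2L]]), as.character(values[[1L]]))
  }
  if (!is.numeric(values) || is.null(names(values)) || any(names(values) == "")) {
    stop_validation(arg, " must be a named numeric vector keyed by gene")
  }
  if (anyDuplicated(names(values))) {
    stop_validation(arg, " has duplicated gene identifiers")
  }
  values
}
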