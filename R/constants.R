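# Physical constants (2019 SI exact values)
AVOGADRO <- 6.02214076e23 # /mol
BOLTZMANN <- 1.380649e-23 # J/K

# unit helpers
NM_TO_M <- 1e-9
NM_TO_ANGSTROM <- 10

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

abort_domain <- function(msg) abort(msg, class = "nanocount_domain_error")

check_positive <- function(x, name, strict = TRUE) {
  if (any(!is.finite(x)) || (strict && any(x <= 0)) || (!strict && any(x < 0))) {
    abort_domain(sprintf(
      "`%s` must be %s and finite (got %s).",
      name, if (strict) "> 0" else ">= 0",
      paste(utils::head(format(x), 3), collapse = ", ")
    ))
  }
  invisible(x)
}

# run expr under a reproducible RNG state when seed is given, otherwise
# consume the global stream
with_seed_or_stream <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}
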