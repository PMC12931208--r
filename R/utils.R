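# Physical constants (CODATA 2018, exact SI values where defined)
.kB <- 1.380649e-23      # Boltzmann constant, J K^-1
.h  <- 6.62607015e-34    # Planck constant, J s
.R  <- 8.314462618       # molar gas constant, J mol^-1 K^-1

#' Physical constants used by the Eyring analysis
#'
#' Returns the CODATA values of the Boltzmann constant (J/K), Planck constant
#' (J s) and molar gas constant (J/mol/K) used throughout the package.
#'
#' @return Named numeric vector with elements `kB`, `h`, `R`.
#' @export
#' @examples
#' physical_constants()
physical_constants <- function() {
  c(kB = .kB, h = .h, R = .R)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_param(sprintf("`%s` must be a single finite positive number", name))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_param(sprintf("`%s` must be a single finite non-negative number", name))
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_param(sprintf("`%s` must be in [0, 1]", name))
  invisible(x)
}
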