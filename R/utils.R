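#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published threshold tables round
#' half up, so displayed percentages use this rule. All computation keeps
#' full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive reproducible sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' module (patient-level draws, per-scan voxel noise, summary measurement
#' jitter) consumes its own derived sub-seed so that generating scans in
#' any order, or skipping some, yields identical values.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483645L, n, replace = FALSE)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Canonical treatment stages
#'
#' Scan stages are named `baseline` (pre-treatment), `iPET` (interim, after
#' 2-3 chemotherapy cycles) and `fPET` (end of treatment) in all I/O.
#'
#' @return character vector of the three stage names in order.
#' @export
flt_stages <- function() c("baseline", "iPET", "fPET")

assert_stage <- function(stage) {
  assert_that(length(stage) == 1 && stage %in% flt_stages(),
              "unknown stage '%s' (expected one of: %s)",
              as.character(stage)[1], paste(flt_stages(), collapse = ", "))
}
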