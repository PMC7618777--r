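# broom-style tidy()/glance() methods for the package's fitted objects.

#' Tidy a single-exponential fit
#'
#' @param x An `exp_fit` from [fit_exponential()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("A", "k", "initial_rate"),
    estimate = c(x$A, x$k, x$initial_rate),
    std.error = c(x$se_A, x$se_k, x$se_initial_rate)
  )
}

#' One-row summary of a single-exponential fit
#'
#' @inheritParams tidy.exp_fit
#' @return Tibble with `r.squared`, `nobs`, `A`, `k`, `initial_rate`.
#' @exportS3Method generics::glance
glance.exp_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, nobs = x$n,
    A = x$A, k = x$k, initial_rate = x$initial_rate
  )
}

#' Tidy a fidelity profile into per-position rows
#'
#' @param x A `fidelity_profile`.
#' @param ... Unused.
#' @return The positional tibble (`position`, `n_reads`, `fidelity`).
#' @exportS3Method generics::tidy
tidy.fidelity_profile <- function(x, ...) x$positional

#' One-row summary of a fidelity profile
#'
#' @inheritParams tidy.fidelity_profile
#' @return Tibble with `average_fidelity`, `perfect_full_length_fraction`,
#'   `n_full_length`, `method`.
#' @exportS3Method generics::glance
glance.fidelity_profile <- function(x, ...) {
  tibble::tibble(
    average_fidelity = x$average_fidelity,
    perfect_full_length_fraction = x$perfect_full_length_fraction,
    n_full_length = x$n_full_length,
    method = x$method
  )
}

#' Tidy an error spectrum into substitution rows
#'
#' @param x An `error_spectrum`.
#' @param ... Unused.
#' @return Tibble with `expected`, `observed`, `count` for every off-diagonal
#'   substitution type.
#' @exportS3Method generics::tidy
tidy.error_spectrum <- function(x, ...) {
  m <- x$matrix
  out <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(out) <- c("expected", "observed", "count")
  out <- out[out$expected != out$observed, ]
  out$count <- as.integer(out$count)
  dplyr::arrange(out, .data$expected, .data$observed)
}

#' One-row summary of an error spectrum
#'
#' @inheritParams tidy.error_spectrum
#' @return Tibble with `n_substitutions`, `wobble_fraction`,
#'   `overall_wobble_share`.
#' @exportS3Method generics::glance
glance.error_spectrum <- function(x, ...) {
  tibble::tibble(
    n_substitutions = x$n_substitutions,
    wobble_fraction = x$wobble_fraction,
    overall_wobble_share = x$overall_wobble_share
  )
}

#' Tidy a quasispecies stationary state
#'
#' @param x A `qs_state`.
#' @param ... Unused.
#' @return The frequencies tibble (`genotype`, `class`, `fitness`,
#'   `frequency`).
#' @exportS3Method generics::tidy
tidy.qs_state <- function(x, ...) x$frequencies

#' One-row summary of a quasispecies stationary state
#'
#' @inheritParams tidy.qs_state
#' @return Tibble with `active_fraction`, `mean_fitness`, `n_iter`.
#' @exportS3Method generics::glance
glance.qs_state <- function(x, ...) {
  tibble::tibble(
    active_fraction = x$active_fraction,
    mean_fitness = x$mean_fitness,
    n_iter = x$n_iter
  )
}
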