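# Age-specific vital rates and their Leslie-matrix representation.
#
# The population has 9 age classes. Reproduction is concentrated in ages 1-2
# (rates 0.53 and 0.50; 0.01 thereafter) and natural mortality is 0.10 for
# ages 1-2, 0.40 for ages 3-8 and 1 for age 9, which yields an unfished
# asymptotic growth rate of ~0.999 and a right-skewed stable age structure.
# Fishing adds a constant extra mortality F to the exploited ages 4-8, so the
# six fishing scenarios 0-50% give total exploited-age mortalities 40-90%.

EXPLOITED_AGES <- 4:8
FISHING_SCHEDULE <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Age-specific vital rates under a fishing scenario
#'
#' Builds the vital-rate set of the nine-age-class population: annual
#' reproductive probabilities `R = (0.53, 0.50, 0.01, ..., 0.01)`, natural
#' mortalities `M = (0.10, 0.10, 0.40, ..., 0.40, 1.00)`, and fishing
#' mortality `F` added to the exploited age classes 4-8 only. Newborn
#' survival is 1, so reproduction equals recruitment. All age-9 fish die
#' (`M[9] = 1`).
#'
#' @param F Fishing mortality applied annually to ages 4-8, usually one of
#'   the schedule `0, 0.1, ..., 0.5`; values off the schedule are allowed
#'   with a warning, values making any total mortality exceed 1 are an
#'   error.
#' @return A `vital_rates` object: list with `n_ages`, `R`, `M`, `F`
#'   (scalar) and `Fvec` (per-age fishing mortality).
#' @examples
#' vr <- make_vital_rates(F = 0.2)
#' vr$M + vr$Fvec # total mortality by age
#' @export
make_vital_rates <- function(F = 0) {
  if (!is.numeric(F) || length(F) != 1L || is.na(F) || F < 0) {
    stop("`F` must be a single non-negative number", call. = FALSE)
  }
  R <- c(0.53, 0.50, rep(0.01, 7))
  M <- c(0.10, 0.10, rep(0.40, 6), 1.00)
  Fvec <- numeric(9)
  Fvec[EXPLOITED_AGES] <- F
  if (any(M + Fvec > 1 + 1e-12)) {
    stop("total mortality M + F exceeds 1 for an exploited age class",
         call. = FALSE)
  }
  if (!isTRUE(any(abs(F - FISHING_SCHEDULE) < 1e-12))) {
    warning(sprintf(
      "F = %g is outside the standard fishing schedule (0, 0.1, ..., 0.5)", F
    ), call. = FALSE)
  }
  structure(
    list(n_ages = 9L, R = R, M = M, F = F, Fvec = Fvec),
    class = "vital_rates"
  )
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("<vital_rates> 9 age classes, F = %g on ages 4-8\n", x$F))
  print(data.frame(age = 1:9, R = x$R, M = x$M, F = x$Fvec,
                   survival = pmax(0, 1 - x$M - x$Fvec)))
  invisible(x)
}

#' Leslie projection matrix
#'
#' Builds the 9 x 9 Leslie matrix of the vital rates: fecundities `R_i` on
#' the first row (newborn survival is 1) and survival probabilities
#' `1 - M_i - F_i` on the subdiagonal. The deterministic projection
#' `N(t+1) = A N(t)` is the expectation of the stochastic annual update.
#'
#' @param vr A `vital_rates` object.
#' @return A 9 x 9 numeric matrix.
#' @export
build_leslie <- function(vr) {
  stopifnot(inherits(vr, "vital_rates"))
  n <- vr$n_ages
  A <- matrix(0, n, n)
  A[1, ] <- vr$R
  surv <- pmax(0, 1 - vr$M - vr$Fvec)
  A[cbind(2:n, 1:(n - 1))] <- surv[1:(n - 1)]
  A
}

#' Asymptotic population growth rate
#'
#' Leading eigenvalue modulus of the Leslie matrix: the factor by which the
#' population multiplies per year once the age structure has converged.
#' The unfished rates give a growth rate just below 1 (approximately
#' 0.9998), and fishing at 50% lowers it to approximately 0.9956.
#'
#' @param A A Leslie matrix (from [build_leslie()]).
#' @return A single non-negative number.
#' @export
growth_rate <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Stable age distribution
#'
#' Normalised dominant right eigenvector of the Leslie matrix: the
#' proportions of each age class once transients have died out. Under the
#' default rates the distribution is right-skewed (strictly decreasing with
#' age).
#'
#' @param A A Leslie matrix.
#' @return Numeric vector of 9 non-negative proportions summing to 1.
#' @export
stable_age_distribution <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  e <- eigen(A)
  i <- which.max(Mod(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}
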