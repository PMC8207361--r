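# Age-specific habitat-preference niche curves.
#
# Each of the 9 age classes prefers habitat values drawn from a symmetric
# Beta(1.2, 1.2) rescaled onto an age-specific interval. The two modes differ
# only in geometry: "strong" preference uses narrow niches (width 0.4) whose
# centers sweep 0.2 -> 0.8 with age, "weak" uses wide niches (width 0.8) with
# centers 0.4 -> 0.6. In both modes the union of the 9 intervals is exactly
# [0, 1], so the population can spread over the whole habitat range.

#' Age-specific habitat-preference model
#'
#' Defines the niche curves of the nine age classes under strong or weak
#' ontogenetic habitat preference. Every age class has a symmetric
#' Beta(`alpha` = 1.2, `beta` = 1.2) niche curve rescaled to an interval of
#' fixed width centred on an age-specific niche centre; centres are evenly
#' spaced between the first and last age class.
#'
#' Strong preference: centres 0.2 to 0.8, width 0.4 (narrow niches, little
#' overlap between distant ages). Weak preference: centres 0.4 to 0.6, width
#' 0.8 (broad, heavily overlapping niches). Under both modes the union of
#' niche intervals is the full habitat range \[0, 1\].
#'
#' @param mode `"strong"` or `"weak"`.
#' @return A `niche_model` object with fields `mode`, `n_ages`, `alpha`,
#'   `beta`, `center_lo`, `center_hi`, `width`.
#' @examples
#' m <- niche_model("strong")
#' niche_centers(m)
#' niche_interval(m, age = 1)
#' @export
niche_model <- function(mode = c("strong", "weak")) {
  mode <- match.arg(mode)
  geom <- switch(mode,
    strong = list(center_lo = 0.2, center_hi = 0.8, width = 0.4),
    weak   = list(center_lo = 0.4, center_hi = 0.6, width = 0.8)
  )
  structure(
    c(list(mode = mode, n_ages = 9L, alpha = 1.2, beta = 1.2), geom),
    class = "niche_model"
  )
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf(
    "<niche_model> %s preference: 9 ages, centers %.2f-%.2f, width %.2f, Beta(%.1f, %.1f)\n",
    x$mode, x$center_lo, x$center_hi, x$width, x$alpha, x$beta
  ))
  invisible(x)
}

#' Niche centres of the nine age classes
#'
#' @param model A `niche_model`.
#' @return Numeric vector of 9 evenly spaced niche centres, ascending with
#'   age class.
#' @export
niche_centers <- function(model) {
  stopifnot(inherits(model, "niche_model"))
  seq(model$center_lo, model$center_hi, length.out = model$n_ages)
}

check_age <- function(model, age) {
  if (!all(age %in% seq_len(model$n_ages))) {
    stop(sprintf("`age` must be an age class in 1..%d", model$n_ages),
         call. = FALSE)
  }
  as.integer(age)
}

#' Niche interval of an age class
#'
#' @param model A `niche_model`.
#' @param age Age class, 1 to 9 (vectorised).
#' @return For a single age, `c(lo, hi)`; for several ages a two-column
#'   matrix. Always inside \[0, 1\].
#' @export
niche_interval <- function(model, age) {
  age <- check_age(model, age)
  ctr <- niche_centers(model)[age]
  out <- cbind(lo = ctr - model$width / 2, hi = ctr + model$width / 2)
  if (length(age) == 1L) out[1, ] else out
}

#' Draw individual habitat-preference values
#'
#' Draws preference values `Z` for individuals of the given age class(es):
#' `Z = lo + width * X` with `X ~ Beta(1.2, 1.2)`, where `[lo, lo + width]`
#' is the age's niche interval. Consumes the current R random stream.
#'
#' @param model A `niche_model`.
#' @param age Age class per draw; recycled against `n` if scalar.
#' @param n Number of draws (defaults to `length(age)`).
#' @return Numeric vector of preference values, each inside its age's niche
#'   interval.
#' @export
draw_preference <- function(model, age, n = length(age)) {
  age <- check_age(model, age)
  if (length(age) == 1L && n > 1L) age <- rep(age, n)
  stopifnot(length(age) == n)
  lo <- niche_centers(model)[age] - model$width / 2
  lo + model$width * stats::rbeta(n, model$alpha, model$beta)
}
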