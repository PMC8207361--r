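# Population-level summary indices.
#
# Age truncation is measured inversely by the Shannon index of landscape-wide
# age-class abundances; spatial variability by the coefficient of variation
# of per-cell total abundance. Both are computed on the annual snapshots
# (taken after the year's last movement step) and averaged over the analysis
# window, by default years 5-15 (11 years), which excludes the transient.

#' Shannon age diversity
#'
#' `H' = -sum(p_i log p_i)` over the age classes with positive abundance,
#' where `p_i` is the proportion of age class `i` in the landscape-wide
#' population, using the natural logarithm. Ranges from 0 (a single age
#' class) to `log(9)` (all nine classes equally abundant); lower values mean
#' stronger age truncation.
#'
#' @param age_counts Non-negative vector of per-age-class abundances.
#' @return A single number, or `NA` if all counts are zero.
#' @examples
#' shannon_age_diversity(rep(100, 9)) # log(9)
#' @export
shannon_age_diversity <- function(age_counts) {
  if (any(age_counts < 0)) stop("`age_counts` must be non-negative", call. = FALSE)
  total <- sum(age_counts)
  if (total == 0) return(NA_real_)
  p <- age_counts[age_counts > 0] / total
  -sum(p * log(p))
}

#' Spatial coefficient of variation
#'
#' Standard deviation of the per-cell total abundances divided by their
#' mean, across all cells of the landscape. Higher values mean a more
#' aggregated (spatially heterogeneous) population. The default uses the
#' sample (n - 1) standard deviation; `type = "population"` divides by n.
#'
#' @param cell_counts Non-negative vector of per-cell total abundances
#'   (length 121 on the standard landscape).
#' @param type `"sample"` (default) or `"population"` standard deviation.
#' @return A single non-negative number, or `NA` if the mean is zero.
#' @examples
#' spatial_cv(c(10, 0, 0, 0)) # sd 5 / mean 2.5 = 2
#' @export
spatial_cv <- function(cell_counts, type = c("sample", "population")) {
  type <- match.arg(type)
  if (any(cell_counts < 0)) stop("`cell_counts` must be non-negative", call. = FALSE)
  m <- mean(cell_counts)
  if (m == 0) return(NA_real_)
  s <- stats::sd(cell_counts)
  if (type == "population") {
    n <- length(cell_counts)
    s <- s * sqrt((n - 1) / n)
  }
  s / m
}

#' Summarise one replicate over the analysis window
#'
#' Computes, for each year of the window, the Shannon age diversity of the
#' landscape-wide age totals and the spatial CV of the per-cell totals, and
#' averages them (together with total population size) over the window.
#' Years in which the population is extinct contribute missing indices and
#' are dropped from the means.
#'
#' @param output A `sim_output`.
#' @param window Integer vector of years to average over; default 5 to 15
#'   (11 years).
#' @param cv_type Passed to [spatial_cv()].
#' @return A one-row data frame (`replicate_summary`) with `mean_shannon`,
#'   `mean_cv`, `mean_popsize` and `n_years`.
#' @export
summarize_replicate <- function(output, window = 5:15,
                                cv_type = c("sample", "population")) {
  stopifnot(inherits(output, "sim_output"))
  cv_type <- match.arg(cv_type)
  years <- dim(output$abund)[3]
  if (length(window) == 0L) stop("`window` must be non-empty", call. = FALSE)
  if (any(window < 1L) || any(window > years)) {
    stop(sprintf("`window` must lie within the simulated years 1..%d", years),
         call. = FALSE)
  }
  sh <- cv <- pop <- numeric(length(window))
  for (i in seq_along(window)) {
    snap <- output$abund[, , window[i]]
    age_totals <- colSums(snap)
    cell_totals <- rowSums(snap)
    sh[i] <- shannon_age_diversity(age_totals)
    cv[i] <- spatial_cv(cell_totals, type = cv_type)
    pop[i] <- sum(age_totals)
  }
  data.frame(
    mean_shannon = mean(sh, na.rm = TRUE),
    mean_cv = mean(cv, na.rm = TRUE),
    mean_popsize = mean(pop),
    n_years = length(window)
  )
}
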