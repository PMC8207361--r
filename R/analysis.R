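# Regression analyses of the replicate summaries.
#
# The headline quantity is the OLS slope of spatial CV on Shannon age
# diversity within each (preference, landscape, K) combination, pooling all
# fishing levels: a negative slope means age truncation (lower diversity)
# elevates spatial variability. The full model adds the three-way
# interaction diversity x preference x carrying capacity per landscape.

#' Regress spatial CV on age diversity for one combination
#'
#' Ordinary least squares of `mean_cv` on `mean_shannon` across the
#' replicate summaries of one (preference, landscape, K) combination,
#' pooled over all fishing levels. The slope measures the response of
#' spatial variability to age truncation (negative = truncation elevates
#' variability).
#'
#' @param points Data frame with columns `mean_shannon` and `mean_cv` (rows
#'   with missing values are dropped).
#' @return A one-row data frame with `slope`, `se`, `intercept`, `r_squared`
#'   and `n`.
#' @examples
#' fit_cv_vs_shannon(data.frame(mean_shannon = 1:3, mean_cv = c(2, 1, 0)))
#' @export
fit_cv_vs_shannon <- function(points) {
  stopifnot(all(c("mean_shannon", "mean_cv") %in% names(points)))
  pts <- points[stats::complete.cases(points[, c("mean_shannon", "mean_cv")]), ]
  if (nrow(pts) < 3L) {
    stop("need at least 3 points with non-missing indices", call. = FALSE)
  }
  if (stats::var(pts$mean_shannon) == 0) {
    stop("singular fit: `mean_shannon` has zero variance", call. = FALSE)
  }
  fit <- stats::lm(mean_cv ~ mean_shannon, data = pts)
  co <- summary(fit)$coefficients
  data.frame(
    slope = co["mean_shannon", "Estimate"],
    se = co["mean_shannon", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    r_squared = summary(fit)$r.squared,
    n = nrow(pts)
  )
}

#' Slope table across all combinations
#'
#' Fits [fit_cv_vs_shannon()] within every (preference, landscape, K)
#' combination present in the summaries and returns one slope (with
#' standard error) per combination, ordered for display by landscape,
#' preference and carrying capacity. Singular or undersized combinations
#' are kept with `NA` estimates and flagged.
#'
#' @param summaries Replicate-summary table from [run_scenario_grid()].
#' @return Data frame with `preference`, `landscape`, `K`, `slope`, `se`,
#'   `intercept`, `r_squared`, `n`, `ok`.
#' @export
slope_table <- function(summaries) {
  stopifnot(all(c("preference", "landscape", "K", "mean_shannon", "mean_cv")
                %in% names(summaries)))
  combos <- unique(summaries[, c("preference", "landscape", "K")])
  combos <- combos[order(combos$landscape, combos$preference, combos$K), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    pts <- summaries[summaries$preference == cb$preference &
                       summaries$landscape == cb$landscape &
                       summaries$K == cb$K, ]
    fit <- tryCatch(fit_cv_vs_shannon(pts), error = function(e) NULL)
    if (is.null(fit)) {
      fit <- data.frame(slope = NA_real_, se = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        n = nrow(pts))
    }
    cbind(cb, fit, ok = !is.na(fit$slope), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full factorial model with the three-way interaction
#'
#' Fits, for one landscape, the OLS model
#' `mean_cv ~ mean_shannon * preference * K` with all lower-order terms,
#' where preference is a two-level indicator and carrying capacity enters
#' either as a continuous covariate on the log2 scale (the schedule
#' 5, 10, ..., 160 is geometric) or as a categorical factor. The term of
#' interest is the three-way interaction: it asks whether carrying capacity
#' modifies how preference strength changes the diversity-variability slope.
#'
#' @param summaries Replicate-summary table restricted to one landscape (an
#'   error if two landscapes are mixed).
#' @param K_coding `"log2"` (default) or `"factor"`.
#' @return A `factorial_model` object: list with the fitted `lm` (`fit`),
#'   the coefficient table (`coefficients`), and `three_way` — a one-row
#'   data frame with the estimate, t and p of the three-way term (for
#'   `"factor"` coding, the smallest p among the three-way contrasts).
#' @export
factorial_model <- function(summaries, K_coding = c("log2", "factor")) {
  K_coding <- match.arg(K_coding)
  stopifnot(all(c("preference", "K", "mean_shannon", "mean_cv")
                %in% names(summaries)))
  if ("landscape" %in% names(summaries) &&
      length(unique(summaries$landscape)) > 1L) {
    stop("`summaries` mixes landscapes; fit one model per landscape",
         call. = FALSE)
  }
  if (length(unique(summaries$preference)) < 2L ||
      length(unique(summaries$K)) < 2L) {
    stop("need at least 2 levels of preference and of K", call. = FALSE)
  }
  d <- summaries[stats::complete.cases(
    summaries[, c("mean_shannon", "mean_cv")]), ]
  d$preference <- factor(d$preference)
  d$Kc <- if (K_coding == "log2") log2(d$K) else factor(d$K)
  fit <- stats::lm(mean_cv ~ mean_shannon * preference * Kc, data = d)
  co <- summary(fit)$coefficients
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank-deficient fit; aliased terms: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  tw <- grep("^mean_shannon:preference.*:Kc", rownames(co))
  tw_tab <- co[tw, , drop = FALSE]
  best <- which.min(tw_tab[, "Pr(>|t|)"])
  structure(
    list(
      fit = fit,
      K_coding = K_coding,
      coefficients = co,
      three_way = data.frame(
        term = rownames(tw_tab)[best],
        estimate = tw_tab[best, "Estimate"],
        t = tw_tab[best, "t value"],
        p = tw_tab[best, "Pr(>|t|)"]
      )
    ),
    class = "factorial_model"
  )
}

#' @export
print.factorial_model <- function(x, ...) {
  cat(sprintf(
    "<factorial_model> mean_cv ~ mean_shannon * preference * K (%s coding)\n",
    x$K_coding
  ))
  cat(sprintf("three-way interaction: %s = %.4g (t = %.2f, p = %.3g)\n",
              x$three_way$term, x$three_way$estimate, x$three_way$t,
              x$three_way$p))
  invisible(x)
}
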