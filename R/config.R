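# YAML configuration and miniature fixture worlds.
#
# A configuration file mirrors the factorial design; an empty file (or empty
# list) means the full default design. Unknown keys are an error so typos
# cannot silently fall back to defaults.

CONFIG_KEYS <- c("preference", "F", "landscape", "K", "years",
                 "steps_per_year", "n_per_age", "replicates", "window",
                 "allow_offschedule")

#' Load a scenario configuration from YAML
#'
#' Reads a YAML file whose keys mirror [sim_config()] plus `replicates` and
#' `window`. Scalar entries select a single scenario; vector entries (e.g.
#' `K: [5, 40, 160]`) define a factorial grid. Missing keys take the full
#' default design (all preference modes, fishing levels, landscapes and
#' carrying capacities; 15 years, 40 steps, 100 fish per age class, 60
#' replicates, window years 5-15). Unknown keys and invalid levels raise a
#' validation error naming the offending fields; off-schedule `F` or `K`
#' warn unless `allow_offschedule: true` is set.
#'
#' @param path Path to a YAML file.
#' @return A list with `scenarios` (a scenario table as from
#'   [scenario_grid()]), `years`, `steps_per_year`, `n_per_age`,
#'   `replicates` and `window`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  # YAML sequences of mixed int/real arrive as lists; flatten to vectors
  for (key in c("F", "K", "window", "preference", "landscape")) {
    if (!is.null(cfg[[key]])) cfg[[key]] <- unlist(cfg[[key]])
  }
  preference <- cfg$preference %||% c("strong", "weak")
  if (!all(preference %in% c("strong", "weak"))) {
    stop("`preference` must be 'strong' or 'weak'", call. = FALSE)
  }
  Flev <- cfg$F %||% fishing_mortality_schedule()
  Klev <- cfg$K %||% carrying_capacity_schedule()
  if (any(!is.finite(Klev)) || any(Klev <= 0)) {
    stop("`K` must be positive", call. = FALSE)
  }
  if (any(!is.finite(Flev)) || any(Flev < 0) || any(Flev > 0.5)) {
    stop("`F` must lie in [0, 0.5]", call. = FALSE)
  }
  allow <- isTRUE(cfg$allow_offschedule)
  if (!allow) {
    offF <- Flev[!Flev %in% fishing_mortality_schedule()]
    offK <- Klev[!Klev %in% carrying_capacity_schedule()]
    if (length(offF) > 0L) {
      warning(sprintf(
        "fishing level(s) %s outside the standard schedule (%s)",
        paste(offF, collapse = ", "),
        paste(fishing_mortality_schedule(), collapse = ", ")), call. = FALSE)
    }
    if (length(offK) > 0L) {
      warning(sprintf(
        "carrying capacity level(s) %s outside the standard schedule (%s)",
        paste(offK, collapse = ", "),
        paste(carrying_capacity_schedule(), collapse = ", ")), call. = FALSE)
    }
  }
  landscape <- cfg$landscape %||% c("gradient", "fragmented")
  if (!all(landscape %in% c("gradient", "fragmented"))) {
    stop("`landscape` must be 'gradient' or 'fragmented'", call. = FALSE)
  }
  window <- cfg$window %||% 5:15
  if (!is.null(cfg$window) && length(window) == 2L) {
    window <- seq(window[1], window[2])  # [start, end] shorthand
  }
  list(
    scenarios = scenario_grid(preference = preference, F = Flev,
                              landscape = landscape, K = Klev),
    years = as.integer(cfg$years %||% 15L),
    steps_per_year = as.integer(cfg$steps_per_year %||% 40L),
    n_per_age = as.integer(cfg$n_per_age %||% 100L),
    replicates = as.integer(cfg$replicates %||% 60L),
    window = as.integer(window)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Build a deterministic miniature world for rule-level checks
#'
#' Constructs a tiny landscape, population and vital-rate set with fully
#' specified values, so movement and demographic rules can be exercised
#' without stochasticity (e.g. a 1 x 2 grid with a single fish whose
#' preferred cell is forced, or degenerate rates 0/1 that make the annual
#' update deterministic).
#'
#' @param width,height Grid dimensions (at least 1 x 2 cells in total).
#' @param H Habitat indices, row-major over 0-based `(row, col)`; length
#'   `width * height`.
#' @param K Carrying capacity.
#' @param age,Z,row,col Per-fish vectors (equal lengths): age class,
#'   preference value, 0-based coordinates.
#' @param R,M Optional length-9 overrides of the reproductive and natural
#'   mortality rates; defaults are the standard rates at `F = 0`.
#' @param F Fishing mortality on ages 4-8.
#' @return List with `grid` (a `landscape_grid`, structure `"custom"`),
#'   `state` (an `agent_state`) and `vr` (a `vital_rates`).
#' @export
make_fixture_world <- function(width, height, H, K = 1e6,
                               age = integer(0), Z = numeric(0),
                               row = integer(0), col = integer(0),
                               R = NULL, M = NULL, F = 0) {
  stopifnot(width * height >= 2L, length(H) == width * height,
            length(age) == length(Z), length(age) == length(row),
            length(age) == length(col))
  grid <- new_landscape(H, width, height, K, "custom")
  state <- new_agent_state(age, Z, cell_id(as.integer(row), as.integer(col),
                                           grid$width),
                           width * height)
  vr <- make_vital_rates(F)
  if (!is.null(R)) { stopifnot(length(R) == 9L); vr$R <- as.numeric(R) }
  if (!is.null(M)) {
    stopifnot(length(M) == 9L)
    vr$M <- as.numeric(M)
    if (any(vr$M + vr$Fvec > 1 + 1e-12)) {
      stop("total mortality M + F exceeds 1", call. = FALSE)
    }
  }
  list(grid = grid, state = state, vr = vr)
}
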