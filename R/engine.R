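# Individual-based simulation engine.
#
# One simulated year = 40 synchronous movement steps followed by one
# demographic update (reproduction, then survival + ageing). The annual
# snapshot of abundance by (cell, age) is taken after the year's final
# movement step, before reproduction and survival, which is the state the
# summary indices are computed from.
#
# The population is stored struct-of-arrays (age, Z, cell id) so every
# per-step rule is a handful of vectorised operations; a full 15-year run of
# ~900 fish takes a fraction of a second.

#' Realized habitat suitability
#'
#' The basin-model habitat selection rule: `R = 1 - |H - Z| - N/K`, composed
#' of a habitat-preference term (mismatch between the cell's intrinsic
#' habitat index `H` and the fish's preference `Z`) and a density-dependence
#' term (local abundance `N` over carrying capacity `K`). The value can be
#' negative; only its ordering between cells matters for movement decisions.
#'
#' @param H Intrinsic habitat index of the cell, in \[0, 1\].
#' @param Z Habitat preference of the individual, in \[0, 1\].
#' @param N Local abundance of the cell (non-negative count).
#' @param K Carrying capacity, positive.
#' @return Numeric, vectorised over its arguments.
#' @examples
#' realized_suitability(H = 0.3, Z = 0.5, N = 20, K = 40) # 0.3
#' @export
realized_suitability <- function(H, Z, N, K) {
  if (any(K <= 0)) stop("`K` must be positive", call. = FALSE)
  1 - abs(H - Z) - N / K
}

#' Simulation configuration
#'
#' Bundles one scenario's parameters. Defaults reproduce the standard study
#' design: 15 years of 40 movement steps, 100 fish per age class at start,
#' and factor levels drawn from the factorial schedule (fishing mortality
#' 0-0.5 in steps of 0.1; carrying capacity 5, 10, 20, 40, 80, 160).
#'
#' @param preference `"strong"` or `"weak"` age-specific habitat preference.
#' @param F Fishing mortality on ages 4-8.
#' @param landscape `"gradient"` or `"fragmented"`.
#' @param K Carrying capacity; off-schedule values are allowed with a
#'   warning unless `allow_offschedule = TRUE`.
#' @param years Number of simulated years.
#' @param steps_per_year Movement steps per year.
#' @param n_per_age Initial individuals per age class.
#' @param seed Integer seed for this run's random stream.
#' @param replicate Replicate index (bookkeeping only).
#' @param allow_offschedule Suppress the off-schedule warnings for `F`
#'   and `K`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(preference = c("strong", "weak"),
                       F = 0,
                       landscape = c("gradient", "fragmented"),
                       K = 40,
                       years = 15L,
                       steps_per_year = 40L,
                       n_per_age = 100L,
                       seed = 1L,
                       replicate = 1L,
                       allow_offschedule = FALSE) {
  preference <- match.arg(preference)
  landscape <- match.arg(landscape)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0) {
    stop("`K` must be a single positive number", call. = FALSE)
  }
  if (!allow_offschedule && !K %in% carrying_capacity_schedule()) {
    warning(sprintf("K = %g is outside the standard schedule (%s)",
                    K, paste(carrying_capacity_schedule(), collapse = ", ")),
            call. = FALSE)
  }
  if (F < 0 || F > 0.5) {
    stop("`F` must lie in [0, 0.5]", call. = FALSE)
  }
  if (!allow_offschedule && !isTRUE(any(abs(F - FISHING_SCHEDULE) < 1e-12))) {
    warning(sprintf("F = %g is outside the standard fishing schedule (%s)",
                    F, paste(FISHING_SCHEDULE, collapse = ", ")),
            call. = FALSE)
  }
  stopifnot(years >= 1, steps_per_year >= 1, n_per_age >= 1)
  structure(
    list(
      preference = preference, F = F, landscape = landscape, K = K,
      years = as.integer(years), steps_per_year = as.integer(steps_per_year),
      n_per_age = as.integer(n_per_age), seed = as.integer(seed),
      replicate = as.integer(replicate)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s preference, F = %g, %s landscape, K = %g, %d years x %d steps, seed %d (rep %d)\n",
    x$preference, x$F, x$landscape, x$K, x$years, x$steps_per_year,
    x$seed, x$replicate
  ))
  invisible(x)
}

#' Factor schedules of the factorial design
#'
#' @return Numeric vector of the standard carrying capacities or fishing
#'   mortalities.
#' @export
carrying_capacity_schedule <- function() c(5, 10, 20, 40, 80, 160)

#' @rdname carrying_capacity_schedule
#' @export
fishing_mortality_schedule <- function() FISHING_SCHEDULE

new_agent_state <- function(age, Z, cell, n_cells) {
  structure(
    list(age = as.integer(age), Z = as.numeric(Z), cell = as.integer(cell),
         n_cells = as.integer(n_cells)),
    class = "agent_state"
  )
}

#' @export
print.agent_state <- function(x, ...) {
  cat(sprintf("<agent_state> %d fish on %d cells; ages %s\n",
              length(x$age), x$n_cells,
              paste(utils::head(sort(unique(x$age)), 9), collapse = ",")))
  invisible(x)
}

#' Number of fish per cell
#'
#' @param state An `agent_state`.
#' @return Integer vector of length `n_cells` (row-major cell order).
#' @export
occupancy <- function(state) {
  tabulate(state$cell, nbins = state$n_cells)
}

#' Convert an agent state to a data frame
#'
#' @param x An `agent_state`.
#' @param width Grid width used to decode cell ids into 0-based
#'   `(row, col)`; defaults to a square grid.
#' @param ... Unused.
#' @return Data frame with columns `age`, `Z`, `row`, `col`.
#' @export
as.data.frame.agent_state <- function(x, width = as.integer(sqrt(x$n_cells)), ...) {
  co <- cell_coords(x$cell, width)
  data.frame(age = x$age, Z = x$Z, row = co[, "row"], col = co[, "col"])
}

#' Initialise the population
#'
#' Places `n_per_age` fish of every age class 1-9 uniformly at random on the
#' landscape (default 100 per class, 900 fish) and draws each fish's habitat
#' preference from its age's niche curve.
#'
#' @param config A `sim_config`.
#' @param model A `niche_model`.
#' @param grid A `landscape_grid`.
#' @return An `agent_state`.
#' @export
initialize_population <- function(config, model, grid) {
  n_ages <- model$n_ages
  n <- config$n_per_age * n_ages
  age <- rep(seq_len(n_ages), each = config$n_per_age)
  n_cells <- grid$width * grid$height
  cell <- sample.int(n_cells, n, replace = TRUE)
  Z <- draw_preference(model, age)
  new_agent_state(age, Z, cell, n_cells)
}

# Low-level synchronous movement kernel over raw vectors. Each fish draws one
# uniform candidate among its Moore neighbours; both suitabilities use the
# occupancy snapshot taken at step start. The fish counts itself in its
# current cell but evaluates the candidate from the crowding already present
# there (no self-count): a fish deciding whether to relocate perceives the
# destination's existing occupants. Counting itself at both locations would
# instead penalise every move by 1/K, which at small K freezes the population
# into equal-density configurations and suppresses density-driven churn. The
# fish moves iff the candidate is strictly better; all moves apply
# simultaneously.
step_cells <- function(cell, Z, H, nb_ids, nb_n, K, n_cells) {
  n <- length(cell)
  N <- tabulate(cell, nbins = n_cells)
  k <- nb_n[cell]
  pick <- as.integer(stats::runif(n) * k) + 1L  # runif < 1, so pick <= k
  cand <- nb_ids[cbind(cell, pick)]
  r_cur <- 1 - abs(H[cell] - Z) - N[cell] / K
  r_cand <- 1 - abs(H[cand] - Z) - N[cand] / K
  move <- r_cand > r_cur
  cell[move] <- cand[move]
  cell
}

#' One synchronous movement step
#'
#' Every fish draws one candidate cell uniformly among its available Moore
#' neighbours (8 in the interior, 5 on an edge, 3 in a corner) and moves
#' there iff the candidate's realized suitability strictly exceeds that of
#' its current cell; otherwise it stays. Both suitabilities are evaluated on
#' the occupancy snapshot taken at the start of the step, the fish counting
#' itself in its current cell but not in the candidate cell, and all moves
#' are applied simultaneously. Movement never changes the number of fish,
#' their ages or their preference values.
#'
#' @param state An `agent_state`.
#' @param grid A `landscape_grid`.
#' @return The updated `agent_state`.
#' @export
movement_step <- function(state, grid) {
  stopifnot(inherits(state, "agent_state"), inherits(grid, "landscape_grid"))
  n_cells <- grid$width * grid$height
  stopifnot(state$n_cells == n_cells)
  if (length(state$cell) == 0L) return(state)
  state$cell <- step_cells(state$cell, state$Z, grid$H,
                           grid$nb_ids, grid$nb_n, grid$K, n_cells)
  state
}

#' Annual demographic update
#'
#' Applies the end-of-year demography: every fish of age `i` first spawns
#' one newborn with probability `R_i` (the newborn is placed in the mother's
#' cell and survives with probability 1); each existing fish then survives
#' with probability `1 - M_i - F_i`; survivors increment their age and
#' redraw their habitat preference from the new age's niche curve; all age-9
#' fish die. Newborns enter as age 1 with a preference drawn from the age-1
#' curve.
#'
#' @param state An `agent_state`.
#' @param vr A `vital_rates` object.
#' @param model A `niche_model`.
#' @return The next year's `agent_state`.
#' @export
annual_demographic_update <- function(state, vr, model) {
  stopifnot(inherits(state, "agent_state"), inherits(vr, "vital_rates"),
            inherits(model, "niche_model"))
  n <- length(state$age)
  if (n == 0L) return(state)
  # reproduction: Bernoulli(R_i) per mother, newborn at the mother's cell
  spawned <- stats::runif(n) < vr$R[state$age]
  newborn_cell <- state$cell[spawned]
  n_new <- length(newborn_cell)
  newborn_Z <- if (n_new > 0L) draw_preference(model, 1L, n_new) else numeric(0)
  # survival + ageing: age 9 has survival 0 by construction (M9 = 1)
  surv_p <- pmax(0, 1 - vr$M - vr$Fvec)
  alive <- stats::runif(n) < surv_p[state$age]
  age_next <- state$age[alive] + 1L
  cell_next <- state$cell[alive]
  Z_next <- if (length(age_next) > 0L) draw_preference(model, age_next) else numeric(0)
  new_agent_state(
    age = c(rep(1L, n_new), age_next),
    Z = c(newborn_Z, Z_next),
    cell = c(newborn_cell, cell_next),
    n_cells = state$n_cells
  )
}

#' Run one simulation
#'
#' Runs the full annual cycle for one scenario: `years` years of
#' `steps_per_year` synchronous movement steps each, followed by the
#' demographic update. The per-year snapshot of abundance by (cell, age) is
#' recorded after the year's final movement step and before reproduction and
#' survival. The run is fully reproducible from `config$seed`: the seed is
#' set on entry and, for a fragmented landscape, the layout is drawn from
#' the same stream (so each run gets its own random layout).
#'
#' If the population goes extinct the remaining years are recorded as zeros
#' and the output is flagged (`extinct_year`).
#'
#' @param config A `sim_config`.
#' @param grid Optionally a pre-built `landscape_grid`; by default the grid
#'   is built from `config` (deterministic for `"gradient"`, drawn from the
#'   run's random stream for `"fragmented"`).
#' @return A `sim_output` object: list with `abund` (a `n_cells x 9 x years`
#'   integer array of annual snapshots), `config`, `grid_H` (the landscape's
#'   habitat indices), and `extinct_year` (`NA` if never extinct).
#' @export
run_simulation <- function(config, grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- niche_model(config$preference)
  vr <- make_vital_rates(config$F)
  if (is.null(grid)) {
    grid <- if (config$landscape == "gradient") {
      make_gradient_landscape(config$K)
    } else {
      make_fragmented_landscape(config$K)
    }
  }
  n_cells <- grid$width * grid$height
  state <- initialize_population(config, model, grid)

  abund <- array(0L, dim = c(n_cells, model$n_ages, config$years))
  extinct_year <- NA_integer_
  for (year in seq_len(config$years)) {
    if (length(state$age) == 0L) {
      if (is.na(extinct_year)) extinct_year <- year
      next
    }
    for (step in seq_len(config$steps_per_year)) {
      state$cell <- step_cells(state$cell, state$Z, grid$H,
                               grid$nb_ids, grid$nb_n, grid$K, n_cells)
    }
    # snapshot after the last movement step, before demography
    counts <- table_cells_ages(state$cell, state$age, n_cells, model$n_ages)
    abund[, , year] <- counts
    state <- annual_demographic_update(state, vr, model)
  }
  structure(
    list(abund = abund, config = config, grid_H = grid$H,
         grid_width = grid$width, extinct_year = extinct_year),
    class = "sim_output"
  )
}

# (cell, age) cross-tabulation without the factor machinery of table()
table_cells_ages <- function(cell, age, n_cells, n_ages) {
  m <- tabulate((age - 1L) * n_cells + cell, nbins = n_cells * n_ages)
  matrix(m, nrow = n_cells, ncol = n_ages)
}

#' @export
print.sim_output <- function(x, ...) {
  tot <- apply(x$abund, 3, sum)
  cat(sprintf(
    "<sim_output> %d years; population %d -> %d%s\n",
    dim(x$abund)[3], tot[1], tot[length(tot)],
    if (!is.na(x$extinct_year)) sprintf(" (extinct in year %d)", x$extinct_year) else ""
  ))
  invisible(x)
}

#' Tidy a simulation output
#'
#' @param x A `sim_output`.
#' @param drop_zero Drop zero-abundance rows (default `TRUE`).
#' @param ... Unused.
#' @return A long data frame with columns `year`, `row`, `col` (0-based),
#'   `age_class`, `abundance`.
#' @export
as.data.frame.sim_output <- function(x, drop_zero = TRUE, ...) {
  d <- dim(x$abund)
  n_cells <- d[1]; n_ages <- d[2]; years <- d[3]
  co <- cell_coords(seq_len(n_cells), x$grid_width)
  df <- data.frame(
    year = rep(seq_len(years), each = n_cells * n_ages),
    row = rep(co[, "row"], times = n_ages * years),
    col = rep(co[, "col"], times = n_ages * years),
    age_class = rep(rep(seq_len(n_ages), each = n_cells), times = years),
    abundance = as.integer(x$abund)
  )
  if (drop_zero) df <- df[df$abundance > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Derive a child seed for a (scenario, replicate) pair
#'
#' Deterministic 32-bit stream splitting: each run of a factorial grid gets
#' its own seed computed from the master seed, the scenario index and the
#' replicate index, so any single replicate can be rerun in isolation and
#' match the grid run bit for bit.
#'
#' @param master_seed Integer master seed.
#' @param scenario_id Integer scenario index (1-based row of the scenario
#'   table).
#' @param replicate Integer replicate index.
#' @return A single integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master_seed, scenario_id, replicate) {
  m <- 2147483647  # 2^31 - 1 (prime); products stay exact in doubles
  h <- as.numeric(master_seed) %% m
  h <- (h * 69069 + 1 + as.numeric(scenario_id)) %% m
  h <- (h * 69069 + 1 + as.numeric(replicate)) %% m
  as.integer(h) + 1L
}

#' Enumerate the factorial scenario grid
#'
#' Full factorial of the study design: 2 preference modes x 6 fishing
#' mortalities x 2 landscape structures x 6 carrying capacities = 144
#' scenarios by default.
#'
#' @param preference,F,landscape,K Factor levels; defaults are the full
#'   schedules.
#' @return Data frame with one row per scenario and a `scenario_id` column.
#' @export
scenario_grid <- function(preference = c("strong", "weak"),
                          F = fishing_mortality_schedule(),
                          landscape = c("gradient", "fragmented"),
                          K = carrying_capacity_schedule()) {
  g <- expand.grid(
    preference = preference, F = F, landscape = landscape, K = K,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g$scenario_id <- seq_len(nrow(g))
  g[, c("scenario_id", "preference", "F", "landscape", "K")]
}

#' Run a factorial scenario grid
#'
#' Runs every scenario of a factorial design for the requested number of
#' replicates and (by default) reduces each run to its replicate summary
#' (window means of Shannon age diversity, spatial CV and population size).
#' Every run's seed is derived from `master_seed` via [derive_seed()], and a
#' fragmented layout is redrawn per replicate from that run's stream.
#'
#' @param scenarios A scenario table from [scenario_grid()] (or any data
#'   frame with columns `scenario_id`, `preference`, `F`, `landscape`, `K`).
#' @param replicates Replicates per scenario.
#' @param master_seed Integer master seed.
#' @param window Year range of the analysis window (default 5 to 15).
#' @param years,steps_per_year,n_per_age Passed to [sim_config()].
#' @param summarize If `TRUE` (default) return the replicate-summary table;
#'   otherwise return the list of `sim_output` objects.
#' @param verbose Print one progress line per scenario.
#' @return A data frame with one row per (scenario, replicate) holding the
#'   scenario factors, `replicate`, `seed`, `mean_shannon`, `mean_cv`,
#'   `mean_popsize` and `extinct` — or a list of `sim_output`s if
#'   `summarize = FALSE`.
#' @export
run_scenario_grid <- function(scenarios = scenario_grid(),
                              replicates = 60L,
                              master_seed = 1L,
                              window = 5:15,
                              years = 15L,
                              steps_per_year = 40L,
                              n_per_age = 100L,
                              summarize = TRUE,
                              verbose = FALSE) {
  stopifnot(replicates >= 1L,
            all(c("scenario_id", "preference", "F", "landscape", "K")
                %in% names(scenarios)))
  rows <- vector("list", nrow(scenarios) * replicates)
  outs <- if (!summarize) vector("list", length(rows)) else NULL
  k <- 0L
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    if (verbose) {
      message(sprintf("scenario %d/%d: %s, F=%g, %s, K=%g",
                      s, nrow(scenarios), sc$preference, sc$F,
                      sc$landscape, sc$K))
    }
    for (r in seq_len(replicates)) {
      k <- k + 1L
      seed <- derive_seed(master_seed, sc$scenario_id, r)
      cfg <- sim_config(
        preference = sc$preference, F = sc$F, landscape = sc$landscape,
        K = sc$K, years = years, steps_per_year = steps_per_year,
        n_per_age = n_per_age, seed = seed, replicate = r
      )
      out <- run_simulation(cfg)
      if (summarize) {
        sm <- summarize_replicate(out, window = window)
        rows[[k]] <- data.frame(
          scenario_id = sc$scenario_id, preference = sc$preference,
          F = sc$F, landscape = sc$landscape, K = sc$K,
          replicate = r, seed = seed,
          mean_shannon = sm$mean_shannon, mean_cv = sm$mean_cv,
          mean_popsize = sm$mean_popsize,
          extinct = !is.na(out$extinct_year)
        )
      } else {
        outs[[k]] <- out
      }
    }
  }
  if (summarize) do.call(rbind, rows) else outs
}
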