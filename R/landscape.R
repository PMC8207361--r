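# Internal cell ids are 1..(width*height) in row-major order with 0-based
# (row, col) user-facing coordinates: id = row * width + col + 1.

cell_id <- function(row, col, width) row * width + col + 1L

cell_coords <- function(id, width) {
  id0 <- id - 1L
  cbind(row = id0 %/% width, col = id0 %% width)
}

# Precompute Moore neighbourhoods under a closed boundary: an n_cells x 8
# integer matrix of neighbour ids (padded with NA) plus a count vector.
# Stored on the grid so the movement loop never recomputes adjacency.
build_neighbor_table <- function(width, height) {
  n <- width * height
  nb <- matrix(NA_integer_, nrow = n, ncol = 8L)
  cnt <- integer(n)
  offsets <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  for (id in seq_len(n)) {
    r <- (id - 1L) %/% width
    c <- (id - 1L) %% width
    rr <- r + offsets[, "dr"]
    cc <- c + offsets[, "dc"]
    keep <- rr >= 0L & rr < height & cc >= 0L & cc < width
    ids <- cell_id(rr[keep], cc[keep], width)
    cnt[id] <- length(ids)
    nb[id, seq_along(ids)] <- ids
  }
  list(ids = nb, n = cnt)
}

new_landscape <- function(H, width, height, K, structure) {
  stopifnot(length(H) == width * height)
  if (!is.numeric(K) || length(K) != 1L || is.na(K) || K <= 0) {
    stop("carrying capacity `K` must be a single positive number", call. = FALSE)
  }
  nbt <- build_neighbor_table(width, height)
  structure(
    list(
      width = as.integer(width),
      height = as.integer(height),
      H = as.numeric(H),
      K = as.numeric(K),
      structure = structure,
      nb_ids = nbt$ids,
      nb_n = nbt$n
    ),
    class = "landscape_grid"
  )
}

# The canonical habitat-index multiset: each of the 11 levels 0, 0.1, ..., 1
# occupies exactly 11 of the 121 cells.
habitat_levels <- function() seq(0, 1, by = 0.1)

#' Build the gradient landscape
#'
#' Constructs the deterministic 11 x 11 gradient landscape: column `j`
#' (0-based) carries intrinsic habitat index `H = j/10`, so habitat quality
#' changes smoothly along one axis and is constant along the other. Every one
#' of the 11 habitat levels `0, 0.1, ..., 1` occupies exactly 11 cells, and
#' all cells share the same carrying capacity `K`. The grid has a closed
#' boundary (no wrap-around).
#'
#' @param K Environmental carrying capacity, a single positive number shared
#'   by all cells. It sets the local abundance at which crowding fully
#'   offsets one unit of habitat match in the suitability rule
#'   `R = 1 - |H - Z| - N/K`.
#' @return A `landscape_grid` object: a list with `width`, `height` (both
#'   11), `H` (length-121 numeric, row-major over 0-based `(row, col)`),
#'   `K`, and `structure` (`"gradient"` or `"fragmented"`).
#' @seealso [make_fragmented_landscape()], [moore_neighbors()],
#'   [realized_suitability()]
#' @examples
#' g <- make_gradient_landscape(K = 40)
#' table(g$H)
#' @export
make_gradient_landscape <- function(K) {
  width <- 11L
  height <- 11L
  # row-major fill: H depends only on the column index
  H <- habitat_levels()[((seq_len(width * height) - 1L) %% width) + 1L]
  new_landscape(H, width, height, K, "gradient")
}

#' Build a fragmented landscape
#'
#' Constructs a random 11 x 11 fragmented landscape: the same multiset of
#' habitat indices as the gradient landscape (11 cells at each of the 11
#' levels `0, 0.1, ..., 1`) assigned to cells by a uniform random
#' permutation. The draw consumes the current R random number stream, so a
#' fixed seed reproduces the layout exactly.
#'
#' @inheritParams make_gradient_landscape
#' @return A `landscape_grid` with `structure = "fragmented"`.
#' @examples
#' set.seed(1)
#' f <- make_fragmented_landscape(K = 40)
#' sum(f$H) # always 60.5: the multiset is conserved
#' @export
make_fragmented_landscape <- function(K) {
  width <- 11L
  height <- 11L
  levels_all <- rep(habitat_levels(), each = width)
  H <- sample(levels_all)
  new_landscape(H, width, height, K, "fragmented")
}

#' Moore neighbours of a cell
#'
#' Returns the up-to-8 cells at Chebyshev distance 1 from `cell` that lie
#' inside the grid. The boundary is closed: corner cells have 3 neighbours,
#' edge cells 5, interior cells 8, and there is no wrap-around.
#'
#' @param grid A `landscape_grid`.
#' @param cell Integer vector `c(row, col)`, 0-based.
#' @return A two-column integer matrix of 0-based `(row, col)` neighbour
#'   coordinates.
#' @examples
#' g <- make_gradient_landscape(40)
#' nrow(moore_neighbors(g, c(0, 0))) # 3 at a corner
#' @export
moore_neighbors <- function(grid, cell) {
  stopifnot(inherits(grid, "landscape_grid"))
  cell <- as.integer(cell)
  if (length(cell) != 2L || anyNA(cell) ||
      cell[1] < 0L || cell[1] >= grid$height ||
      cell[2] < 0L || cell[2] >= grid$width) {
    stop("`cell` must be an on-grid 0-based (row, col) coordinate", call. = FALSE)
  }
  id <- cell_id(cell[1], cell[2], grid$width)
  ids <- grid$nb_ids[id, seq_len(grid$nb_n[id])]
  cell_coords(ids, grid$width)
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "<landscape_grid> %d x %d cells, structure = %s, K = %g\n",
    x$height, x$width, x$structure, x$K
  ))
  invisible(x)
}

#' Convert a landscape to a data frame
#'
#' @param x A `landscape_grid`.
#' @param ... Unused.
#' @return A data frame with columns `row`, `col` (0-based) and `H`.
#' @export
as.data.frame.landscape_grid <- function(x, ...) {
  co <- cell_coords(seq_along(x$H), x$width)
  data.frame(row = co[, "row"], col = co[, "col"], H = x$H)
}

#' Write / read a landscape as CSV
#'
#' The CSV holds one row per cell with columns `row`, `col` (0-based) and
#' `H`; carrying capacity and structure travel in a comment-free side channel
#' (arguments on read), keeping the file trivially inspectable.
#'
#' @param grid A `landscape_grid`.
#' @param path File path.
#' @return `write_landscape_csv()` returns `path` invisibly;
#'   `read_landscape_csv()` returns a `landscape_grid`.
#' @export
write_landscape_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @param K Carrying capacity to attach to the read grid.
#' @param structure Structure label to attach (`"gradient"`, `"fragmented"`
#'   or `"custom"`).
#' @export
read_landscape_csv <- function(path, K, structure = "custom") {
  df <- utils::read.csv(path)
  stopifnot(all(c("row", "col", "H") %in% names(df)))
  width <- max(df$col) + 1L
  height <- max(df$row) + 1L
  H <- numeric(width * height)
  H[cell_id(df$row, df$col, width)] <- df$H
  new_landscape(H, width, height, K, structure)
}
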