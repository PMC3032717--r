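#' Zone specifications
#'
#' The model world consists of three square lattices: Zone 1 is the
#' functional organ tissue, Zone 2 the secondary lymphoid tissue, Zone 3 the
#' blood.  Areas (cell counts) default to 12321 : 2500 : 62500, reflecting
#' the approximate 1000 : 200 : 5000 human volume ratios with the lymphoid
#' zone fixed at 50 x 50.
#'
#' @param config an `immunet_config` (defaults used when missing).
#' @return a data.frame with one row per zone: `zone_id`, `side`, `area`.
#' @examples
#' zone_spec()
#' @export
zone_spec <- function(config = default_config()) {
  side <- as.integer(config$zones$side)
  data.frame(zone_id = 1:3, side = side, area = side * side)
}

#' Moore neighbourhood of a lattice cell
#'
#' All in-bounds cells within Chebyshev distance `1..radius` of `coord`
#' (the centre is excluded, no wraparound; boundary cells return truncated
#' sets).  Coordinates are 0-based.
#'
#' @param coord integer vector `c(x, y)`.
#' @param radius 1 (the eight adjacent cells) or 2 (the 24-cell shell).
#' @param side lattice side length.
#' @return an integer matrix with columns `x`, `y`.
#' @examples
#' nrow(moore_neighborhood(c(5, 5), 1, 11))  # 8
#' nrow(moore_neighborhood(c(0, 0), 1, 11))  # 3 (corner truncation)
#' @export
moore_neighborhood <- function(coord, radius = 1L, side) {
  stopifnot(radius %in% 1:2, length(coord) == 2L)
  x <- coord[1]; y <- coord[2]
  if (x < 0 || y < 0 || x >= side || y >= side)
    stop("coord out of bounds")
  d <- seq.int(-radius, radius)
  g <- expand.grid(dx = d, dy = d)
  g <- g[!(g$dx == 0 & g$dy == 0), ]
  nx <- x + g$dx; ny <- y + g$dy
  ok <- nx >= 0 & ny >= 0 & nx < side & ny < side
  cbind(x = as.integer(nx[ok]), y = as.integer(ny[ok]))
}

#' Signal fields
#'
#' A signal field is one named, diffusing, evaporating scalar concentration
#' grid in one zone (virus, cytokines, chemokines or antibodies; arbitrary
#' units).  `diffuse_step()` applies one tick of the lattice diffusion
#' kernel: each cell becomes `e * (c + D * (mean(Moore neighbours) - c))`,
#' with values below the floor `eps` zeroed.  Bounded grids average over
#' existing neighbours only; `periodic = TRUE` wraps the grid (useful for
#' checking mass conservation, which is exact at `e = 1`).
#'
#' @param name signal identifier.
#' @param zone_id owning zone.
#' @param grid a square numeric matrix of nonnegative concentrations.
#' @param D diffusion constant in (0, 1].
#' @param e evaporation (retention) constant in (0, 1].
#' @param eps concentration floor; values below it are zeroed.
#' @return `signal_field()` returns an object of class `signal_field`;
#'   `diffuse_step()` returns the field after one tick.
#' @examples
#' f <- signal_field("Virus", 1, matrix(0, 9, 9))
#' f$grid[5, 5] <- 1
#' f2 <- diffuse_step(f)
#' sum(f2$grid > 0)  # centre plus the eight neighbours
#' @export
signal_field <- function(name, zone_id, grid, D = 0.6, e = 0.9, eps = 1e-6) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid), all(grid >= 0))
  if (D <= 0 || D > 1 || e <= 0 || e > 1)
    stop("D and e must lie in (0, 1]")
  structure(list(name = name, zone_id = zone_id, grid = grid,
                 D = D, e = e, eps = eps),
            class = "signal_field")
}

#' @rdname signal_field
#' @param field a `signal_field`.
#' @param periodic wrap the lattice edges.
#' @export
diffuse_step <- function(field, periodic = FALSE) {
  stopifnot(inherits(field, "signal_field"))
  field$grid <- cpp_diffuse(field$grid, field$D, field$e, field$eps, periodic)
  field
}

#' Chemotactic gradient target
#'
#' The Moore(1) neighbour of `coord` with maximal concentration, provided
#' that maximum reaches `threshold` and exceeds the centre cell; ties are
#' broken uniformly at random.  Returns `NULL` when no neighbour qualifies
#' (the agent then moves randomly).
#'
#' @param field a `signal_field`.
#' @param coord 0-based `c(x, y)`.
#' @param threshold minimum concentration that triggers chemotaxis.
#' @return `c(x, y)` or `NULL`.
#' @export
gradient_target <- function(field, coord, threshold) {
  stopifnot(inherits(field, "signal_field"))
  out <- cpp_gradient_target(field$grid, as.integer(coord[1]),
                             as.integer(coord[2]), threshold)
  if (length(out) == 0L) NULL else out
}

#' Build the initial world
#'
#' Constructs the world exactly as a run would see it at tick 0: the fixed
#' Zone-1 layout (a centred square block of Parenchymal Agents with four
#' portals just outside the block edge midpoints and the same four central
#' infection sites every run), portals at the Zone-2/Zone-3 edge midpoints,
#' and all mobile agents placed uniformly at random in their home zones
#' (the few antigen-specific lymphocytes at randomly chosen empty
#' coordinates in Zone 2).  Identical seed and configuration give identical
#' placements.
#'
#' @param config an `immunet_config`.
#' @return an `immune_world`: list with `agents` (data.frame), `pc_grid`
#'   (integer matrix of parenchymal states, 0 = no cell), `zones`
#'   (the [zone_spec()] table), `portals` (data.frame) and `n_pc_init`.
#' @examples
#' w <- build_world(default_config(seed = 1L))
#' w$zones$area                      # 12321 2500 62500
#' sum(w$agents$state == "PC_Infected")  # 4
#' @export
build_world <- function(config = default_config()) {
  config <- validate_config(config)
  if (config$scenario == "bacterial")
    stop("the bacterial scenario is not implemented")
  set.seed(config$seed)
  snap <- cpp_build_world(config)
  ag <- as.data.frame(snap$agents)
  ag$type <- factor(cpp_type_names()[ag$type + 1L], levels = cpp_type_names())
  ag$state <- cpp_state_names()[ag$state + 1L]
  ag$phenotype <- c("none", "DC1", "DC2", "Th1", "Treg")[ag$phenotype + 1L]
  portals <- ag[ag$type == "Portal", c("id", "zone", "x", "y")]
  structure(list(agents = ag, pc_grid = snap$pc_grid,
                 zones = zone_spec(config), portals = portals,
                 n_pc_init = snap$n_pc_init, config = config),
            class = "immune_world")
}

#' @export
print.immune_world <- function(x, ...) {
  cat("<immune_world>\n")
  cat("  zones (side/area):",
      paste(sprintf("%d (%d/%d)", x$zones$zone_id, x$zones$side,
                    x$zones$area), collapse = ", "), "\n")
  tab <- table(x$agents$type[x$agents$alive])
  cat("  agents:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = " "), "\n")
  cat("  infected parenchymal sites:",
      sum(x$agents$state == "PC_Infected"), "\n")
  invisible(x)
}
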