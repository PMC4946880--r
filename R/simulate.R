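#' Brownian-dynamics particle trajectories
#'
#' Simulates free 3D Brownian motion of all particles of the given species
#' inside the geometry.  Steps are Gaussian with per-axis variance 2*D*dt;
#' semi-permeable walls (planes of constant x) accept a crossing with the
#' wall's directional permeability and otherwise reflect it; the domain faces
#' always reflect.  The caller's RNG state is used, so wrap in
#' `set.seed()`/`withr::with_seed()` for reproducibility.
#'
#' @param species a `species_spec` or list of them.
#' @param geometry a `geometry_spec`.
#' @param total_time total simulated time in seconds.
#' @param dt time step in seconds.  Must resolve the wall spacing: the RMS
#'   step sqrt(2*D*dt) of the fastest species must be below a quarter of the
#'   smallest wall gap.
#' @return An object of class `particle_trajectories`: positions array
#'   `(steps+1) x particles x 3` (um), per-particle diffusion coefficients and
#'   green/red brightness, the time grid, and the inputs.
#' @examples
#' geom <- geometry_spec(c(0, 10), c(0, 10), c(-2, 2))
#' sp <- species_spec("m", 5, 0.3, count = 20)
#' tr <- simulate_particles(sp, geom, total_time = 0.01, dt = 1e-4)
#' dim(tr$positions)
#' @export
simulate_particles <- function(species, geometry, total_time, dt) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(length(species) >= 1, total_time > 0, dt > 0)
  # wall-resolution precondition
  walls <- geometry$walls
  gaps <- diff(sort(c(geometry$xlim[1], walls$position, geometry$xlim[2])))
  min_gap <- if (length(gaps)) min(gaps) else diff(geometry$xlim)
  for (sp in species) {
    rms <- sqrt(2 * sp$diffusion_coefficient * dt)
    if (nrow(walls) && rms >= min_gap / 4) {
      stop("dt too coarse for species '", sp$label, "': RMS step ",
           signif(rms, 3), " um exceeds a quarter of the minimum wall ",
           "spacing (", signif(min_gap / 4, 3), " um)", call. = FALSE)
    }
  }
  n_steps <- as.integer(ceiling(total_time / dt))
  counts <- vapply(species, function(s) s$count, integer(1))
  np <- sum(counts)
  if (np == 0) stop("no particles to simulate", call. = FALSE)

  start <- matrix(0, np, 3)
  D <- eps_g <- eps_r <- numeric(np)
  sp_index <- integer(np)
  at <- 0L
  for (i in seq_along(species)) {
    s <- species[[i]]
    if (s$count == 0) next
    idx <- at + seq_len(s$count)
    rg <- s$region
    xr <- if (!is.null(rg$x)) rg$x else geometry$xlim
    yr <- if (!is.null(rg$y)) rg$y else geometry$ylim
    zr <- if (!is.null(rg$z)) rg$z else geometry$zlim
    start[idx, 1] <- stats::runif(s$count, xr[1], xr[2])
    start[idx, 2] <- stats::runif(s$count, yr[1], yr[2])
    start[idx, 3] <- stats::runif(s$count, zr[1], zr[2])
    D[idx] <- s$diffusion_coefficient
    eps_g[idx] <- s$brightness_per_unit * s$n_fluorophores_green
    eps_r[idx] <- s$brightness_red_per_unit * s$n_fluorophores_red
    sp_index[idx] <- i
    at <- at + s$count
  }
  wm <- as.matrix(walls[, c("position", "p_f", "p_r"), drop = FALSE])
  storage.mode(wm) <- "double"
  pos <- bd_simulate_cpp(n_steps, dt, D, start,
                         c(geometry$xlim, geometry$ylim, geometry$zlim), wm,
                         as.integer(isTRUE(geometry$periodic_x)))
  structure(list(positions = pos, dt = dt, n_steps = n_steps,
                 total_time = n_steps * dt, D = D, eps_green = eps_g,
                 eps_red = eps_r, species_index = sp_index,
                 species = species, geometry = geometry),
            class = "particle_trajectories")
}

#' @export
print.particle_trajectories <- function(x, ...) {
  cat("particle_trajectories:", dim(x$positions)[2], "particles,",
      x$n_steps, "steps of", x$dt, "s\n")
  invisible(x)
}

#' Species mixture for one- and two-colour simulations
#'
#' Builds the species list for a mixture of green monomers, green homodimers
#' (twice the fluorophore units of the monomer), 1:1 green-red complexes and
#' 2:1 green-red complexes (two green units, one red unit).
#'
#' @param monomer_fraction,dimer_fraction,complex_11_fraction,complex_21_fraction
#'   nonnegative fractions summing to 1.
#' @param total total particle count to split across the species.
#' @param brightness length-2 numeric `(eps_green, eps_red)` per fluorophore
#'   unit.
#' @param diffusion_coefficient shared diffusion coefficient (um^2/s).
#' @return list of `species_spec`, conserving `total` across species (largest
#'   remainder rounding).
#' @export
make_mixture <- function(monomer_fraction = 1, dimer_fraction = 0,
                         complex_11_fraction = 0, complex_21_fraction = 0,
                         total = 200L, brightness = c(0.28, 0.34),
                         diffusion_coefficient = 6.33) {
  f <- c(monomer_fraction, dimer_fraction, complex_11_fraction,
         complex_21_fraction)
  if (any(f < 0)) stop("mixture fractions must be nonnegative", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8)
    stop("mixture fractions must sum to 1", call. = FALSE)
  # largest-remainder apportionment conserves the total count
  raw <- f * total
  n <- floor(raw)
  rem <- total - sum(n)
  if (rem > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  defs <- list(
    list(label = "monomer", g = 1L, r = 0L),
    list(label = "homodimer", g = 2L, r = 0L),
    list(label = "complex_1_1", g = 1L, r = 1L),
    list(label = "complex_2_1", g = 2L, r = 1L))
  out <- list()
  for (i in seq_along(defs)) {
    if (n[i] == 0) next
    d <- defs[[i]]
    out[[length(out) + 1]] <- species_spec(
      d$label, diffusion_coefficient,
      brightness_per_unit = brightness[1],
      brightness_red_per_unit = brightness[2],
      n_fluorophores_green = d$g, n_fluorophores_red = d$r, count = n[i])
  }
  out
}
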