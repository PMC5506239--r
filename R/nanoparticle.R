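AVOGADRO <- 6.02214076e23   # mol^-1, CODATA
PT_ATOMIC_MASS <- 195.084   # g mol^-1, IUPAC

#' Nanoparticle composition specification
#'
#' Describes a monometallic nanoparticle by its atom count, the element's
#' molar mass and its physical size. The particle volume may be supplied
#' directly (useful to reproduce published figures) or derived from the
#' diameter assuming a sphere.
#'
#' @param atoms_per_particle Number of metal atoms per particle (> 0).
#' @param atomic_mass Molar mass of the metal, g/mol (default platinum).
#' @param diameter Particle diameter, nm (> 0).
#' @param particle_volume Particle volume, nm^3; default the spherical volume
#'   `pi/6 * diameter^3`.
#' @return An object of class `particle_spec`.
#' @examples
#' particle_spec(1000, diameter = 2, particle_volume = 4.2)
#' @export
particle_spec <- function(atoms_per_particle,
                          atomic_mass = PT_ATOMIC_MASS,
                          diameter = 2,
                          particle_volume = NULL) {
  stopifnot(is.numeric(atoms_per_particle), is.numeric(atomic_mass),
            is.numeric(diameter))
  if (atoms_per_particle <= 0 || atomic_mass <= 0 || diameter <= 0)
    stop("atoms_per_particle, atomic_mass and diameter must all be > 0",
         call. = FALSE)
  if (is.null(particle_volume)) particle_volume <- pi / 6 * diameter^3
  if (particle_volume <= 0)
    stop("`particle_volume` must be > 0", call. = FALSE)
  structure(
    list(atoms_per_particle = atoms_per_particle, atomic_mass = atomic_mass,
         diameter = diameter, particle_volume = particle_volume),
    class = "particle_spec"
  )
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf(
    "<particle_spec> %g atoms x %g g/mol, d = %g nm, V = %.3g nm^3, mass = %.4g ug\n",
    x$atoms_per_particle, x$atomic_mass, x$diameter, x$particle_volume,
    particle_mass(x)))
  invisible(x)
}

as_particle_spec <- function(x) {
  if (inherits(x, "particle_spec")) return(x)
  if (is.list(x) && "atoms_per_particle" %in% names(x))
    return(do.call(particle_spec, x))
  stop("cannot interpret object as particle_spec", call. = FALSE)
}

#' Mass of a single nanoparticle
#'
#' `atoms_per_particle * atomic_mass / N_Avogadro`, reported in micrograms.
#' For a 1000-atom platinum particle this is 3.239e-13 ug (published accounts
#' often round to 3.25e-13, a ~0.3% difference that propagates into derived
#' concentrations).
#'
#' @param spec A [particle_spec()].
#' @return Particle mass in ug.
#' @examples
#' particle_mass(particle_spec(1000))
#' @export
particle_mass <- function(spec) {
  spec <- as_particle_spec(spec)
  spec$atoms_per_particle * spec$atomic_mass / AVOGADRO * 1e6
}

#' Metal concentration corresponding to a particles-per-cell exposure
#'
#' Converts an administered nanoparticle-to-cell ratio at a given cell density
#' into the metal mass concentration of the suspension:
#' `particles_per_cell * cell_density * particle_mass`, in mg/L. Vectorised
#' over `particles_per_cell`, so a whole exposure series can be converted in
#' one call.
#'
#' @param particles_per_cell Nanoparticles administered per cell (>= 0).
#' @param cell_density Cells per mL (> 0), e.g. 1e7 CFU/mL.
#' @param spec A [particle_spec()].
#' @return Metal concentration(s) in mg/L.
#' @examples
#' exposure_concentration(c(0, 9e5, 1.5e6, 3e6, 6e6), 1e7, particle_spec(1000))
#' @export
exposure_concentration <- function(particles_per_cell, cell_density, spec) {
  if (!is.numeric(particles_per_cell) || any(particles_per_cell < 0))
    stop("`particles_per_cell` must be >= 0", call. = FALSE)
  if (!is.numeric(cell_density) || cell_density <= 0)
    stop("`cell_density` must be > 0 (cells/mL)", call. = FALSE)
  mass_ug <- particle_mass(spec)
  # particles/mL * ug/particle = ug/mL = mg/L
  particles_per_cell * cell_density * mass_ug
}

#' Particles-per-cell ratio from a metal concentration
#'
#' Exact inverse of [exposure_concentration()].
#'
#' @param concentration Metal concentration(s) in mg/L (>= 0).
#' @inheritParams exposure_concentration
#' @return Nanoparticles per cell.
#' @export
particles_per_cell_from_concentration <- function(concentration, cell_density,
                                                  spec) {
  if (!is.numeric(concentration) || any(concentration < 0))
    stop("`concentration` must be >= 0 (mg/L)", call. = FALSE)
  if (!is.numeric(cell_density) || cell_density <= 0)
    stop("`cell_density` must be > 0 (cells/mL)", call. = FALSE)
  concentration / (cell_density * particle_mass(spec))
}

#' Per-cell nanoparticle uptake report
#'
#' Converts a bulk elemental mass measurement (e.g. ICP-MS platinum mass for a
#' washed cell pellet) into per-cell uptake quantities: total internalized
#' particles, particles and metal mass per cell, the fraction of the cell
#' volume the particles occupy, and — when the administered mass is known —
#' the uptake percentage.
#'
#' @param total_metal_mass Measured metal mass, ug (>= 0).
#' @param n_cells Number of cells in the measured sample (> 0).
#' @param spec A [particle_spec()].
#' @param cell_volume Volume of one cell, nm^3 (> 0).
#' @param administered_mass Optional administered metal mass, ug.
#' @return A one-row tibble of class `uptake_report` with columns
#'   `total_particles`, `particles_per_cell`, `mass_per_cell_pg`,
#'   `cell_volume_fraction_pct` and `uptake_pct` (NA when no administered
#'   mass is given), plus 2-significant-figure headline versions
#'   (`particles_per_cell_2sf`, `mass_per_cell_pg_2sf`,
#'   `cell_volume_fraction_pct_1sf`).
#' @examples
#' uptake_report(1.079, 7e8, particle_spec(1000, particle_volume = 4.2),
#'               cell_volume = 4.2e9, administered_mass = 20)
#' @export
uptake_report <- function(total_metal_mass, n_cells, spec, cell_volume,
                          administered_mass = NULL) {
  if (!is.numeric(total_metal_mass) || total_metal_mass < 0)
    stop("`total_metal_mass` must be >= 0 (ug)", call. = FALSE)
  if (!is.numeric(n_cells) || n_cells <= 0)
    stop("`n_cells` must be > 0", call. = FALSE)
  if (!is.numeric(cell_volume) || cell_volume <= 0)
    stop("`cell_volume` must be > 0 (nm^3)", call. = FALSE)
  spec <- as_particle_spec(spec)
  total_particles <- total_metal_mass / particle_mass(spec)
  ppc <- total_particles / n_cells
  mass_per_cell_pg <- total_metal_mass / n_cells * 1e6   # ug -> pg
  volfrac <- ppc * spec$particle_volume / cell_volume * 100
  uptake <- if (is.null(administered_mass)) NA_real_ else {
    if (administered_mass <= 0)
      stop("`administered_mass` must be > 0 (ug)", call. = FALSE)
    100 * total_metal_mass / administered_mass
  }
  out <- tibble::tibble(
    total_particles = total_particles,
    particles_per_cell = ppc,
    mass_per_cell_pg = mass_per_cell_pg,
    cell_volume_fraction_pct = volfrac,
    uptake_pct = uptake,
    particles_per_cell_2sf = signif(ppc, 2),
    mass_per_cell_pg_2sf = signif(mass_per_cell_pg, 2),
    cell_volume_fraction_pct_1sf = signif(volfrac, 1)
  )
  class(out) <- c("uptake_report", class(out))
  out
}
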