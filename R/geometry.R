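# Ensemble geometry: actin site lattice and myosin head placement.
#
# The synthetic ensemble emulates a half sarcomere by an in-vitro-motility
# configuration: one long actin filament with myosin-binding target zones
# every 36 nm (1 or 3 sites per zone) and surface myosin heads whose axial
# offsets to the nearest zone centre are uniformly distributed over the 36 nm
# repeat, binned at 0.1 nm.

#' Build an actin binding-site lattice
#'
#' Target-zone centres are placed at `k * spacing_nm` for every integer
#' `k >= 0` with `k * spacing_nm < length`, so a 20 um filament at 36 nm
#' spacing carries 556 zones. With three sites per zone, flanking sites sit
#' at `+/- site_sep_nm` from each zone centre.
#'
#' @param length_um filament length in micrometres.
#' @param spacing_nm target-zone spacing in nm (default 36).
#' @param sites_per_zone 1 or 3 myosin-binding sites per zone.
#' @param site_sep_nm intra-zone site separation in nm (default 5.5, the
#'   actin monomer rise along one strand).
#' @return An object of class `site_lattice` with elements `zone_centers`,
#'   `site_positions` (nm), `n_zones`, `n_sites`.
#' @export
#' @examples
#' build_lattice(20)$n_sites            # 556
#' build_lattice(20, sites_per_zone = 3)$n_sites  # 1668
build_lattice <- function(length_um, spacing_nm = 36, sites_per_zone = 1L,
                          site_sep_nm = 5.5) {
  if (length_um <= 0 || spacing_nm <= 0) stop("length and spacing must be positive")
  sites_per_zone <- as.integer(sites_per_zone)
  if (!sites_per_zone %in% c(1L, 3L)) stop("sites_per_zone must be 1 or 3")
  length_nm <- length_um * 1000
  zone_centers <- seq(0, by = spacing_nm,
                      length.out = ceiling(length_nm / spacing_nm))
  zone_centers <- zone_centers[zone_centers < length_nm]
  offs <- if (sites_per_zone == 3L) c(-site_sep_nm, 0, site_sep_nm) else 0
  sites <- as.vector(outer(offs, zone_centers, "+"))
  structure(list(
    length_nm = length_nm, spacing_nm = spacing_nm,
    sites_per_zone = sites_per_zone, site_sep_nm = site_sep_nm,
    zone_centers = zone_centers, site_positions = sort(sites),
    n_zones = length(zone_centers),
    n_sites = length(zone_centers) * sites_per_zone
  ), class = "site_lattice")
}

#' @export
print.site_lattice <- function(x, ...) {
  cat(sprintf(
    "Actin site lattice: %.3g um, %g nm zone spacing, %d zones x %d site(s) = %d sites\n",
    x$length_nm / 1000, x$spacing_nm, x$n_zones, x$sites_per_zone, x$n_sites))
  invisible(x)
}

#' Myosin head count from surface density
#'
#' Number of myosin heads able to reach a filament of given length, assuming
#' a band of reachable surface around it: `density * band * length`, floored.
#' At the motility-assay saturating density of 5000 heads/um^2 and a 30 nm
#' band, a 20 um filament sees 3000 heads (150 per um).
#'
#' @param density_per_um2 surface density of active heads, um^-2.
#' @param band_nm width of the reachable band, nm.
#' @param length_um filament length, um.
#' @return integer head count.
#' @export
#' @examples
#' head_count_from_density(5000, 30, 20)  # 3000
head_count_from_density <- function(density_per_um2, band_nm, length_um) {
  stopifnot(density_per_um2 > 0, band_nm > 0, length_um > 0)
  as.integer(floor(density_per_um2 * (band_nm / 1000) * length_um))
}

#' Heads per thin filament in a sarcomere lattice
#'
#' With `n_thick_halves` half thick filaments of `heads_per_half` heads each
#' facing `n_thin` thin filaments, each thin filament interacts with
#' `n_thick_halves * heads_per_half / n_thin` heads (10 x 294 / 20 = 147).
#'
#' @param n_thick_halves number of half thick filaments.
#' @param heads_per_half myosin heads per half thick filament.
#' @param n_thin number of thin filaments.
#' @return numeric (possibly non-integer) heads per thin filament.
#' @export
#' @examples
#' sarcomere_heads_per_thin_filament(10, 294, 20)  # 147
sarcomere_heads_per_thin_filament <- function(n_thick_halves, heads_per_half, n_thin) {
  stopifnot(n_thick_halves > 0, heads_per_half > 0, n_thin > 0)
  n_thick_halves * heads_per_half / n_thin
}

#' Place myosin heads relative to their nearest target zone
#'
#' Offsets are drawn on a 0.1 nm grid spanning one 36 nm repeat. In
#' `"random_binned"` mode each head lands uniformly at random in one of the
#' bins (the bin centre is recorded), reproducibly for a given seed; in
#' `"uniform_grid"` mode offsets are evenly spaced over the repeat (the
#' large-ensemble limit of a uniform head distribution). By default offsets
#' are signed on [-18, +18) nm (360 bins); `signed = FALSE` restricts to
#' [0, 18) nm (180 bins).
#'
#' @param n_heads number of heads (> 0).
#' @param mode `"random_binned"` or `"uniform_grid"`.
#' @param seed optional integer seed for reproducible placement.
#' @param d repeat distance, nm (default 36).
#' @param bin_nm bin width, nm (default 0.1).
#' @param signed logical; signed offsets about the zone centre (default) or
#'   unsigned distances.
#' @return data frame with columns `id` and `offset` (nm).
#' @export
#' @examples
#' h <- place_heads(360, "uniform_grid")
#' range(h$offset)
place_heads <- function(n_heads, mode = c("random_binned", "uniform_grid"),
                        seed = NULL, d = 36, bin_nm = 0.1, signed = TRUE) {
  mode <- match.arg(mode)
  if (n_heads <= 0) stop("n_heads must be positive")
  lo <- if (signed) -d / 2 else 0
  hi <- d / 2
  n_bins <- round((hi - lo) / bin_nm)
  centers <- lo + (seq_len(n_bins) - 0.5) * bin_nm
  if (mode == "uniform_grid") {
    offset <- lo + (seq_len(n_heads) - 0.5) * (hi - lo) / n_heads
  } else {
    if (!is.null(seed)) set.seed(seed)
    offset <- centers[sample.int(n_bins, n_heads, replace = TRUE)]
  }
  data.frame(id = seq_len(n_heads), offset = offset)
}

#' Assemble a motor ensemble
#'
#' Bundles a site lattice, head placements, filament position and external
#' load into the object consumed by [simulate.crossbridge_model()].
#'
#' @param n_heads number of myosin heads, or a data frame of head placements
#'   as returned by [place_heads()].
#' @param lattice a [build_lattice()] object (default: 20 um at 36 nm).
#' @param load external load, pN (positive opposes shortening).
#' @param seed placement seed, used when `n_heads` is a count.
#' @param mode placement mode passed to [place_heads()].
#' @return An object of class `motor_ensemble`.
#' @export
motor_ensemble <- function(n_heads, lattice = build_lattice(20), load = 0,
                           seed = NULL, mode = "random_binned") {
  heads <- if (is.data.frame(n_heads)) n_heads
           else place_heads(n_heads, mode = mode, seed = seed, d = lattice$spacing_nm)
  if (nrow(heads) == 0) stop("ensemble must contain at least one head")
  structure(list(lattice = lattice, heads = heads, position = 0,
                 load = load, seed = seed),
            class = "motor_ensemble")
}

#' @export
print.motor_ensemble <- function(x, ...) {
  cat(sprintf("Motor ensemble: %d heads, load %g pN\n", nrow(x$heads), x$load))
  print(x$lattice)
  invisible(x)
}
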