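#' Cylindrical phantom specification
#'
#' A homogeneous cylinder with the point source at the centre of its axis.
#' The default 20 cm radius x 40 cm height matches the standard full-scatter
#' brachytherapy phantom.
#'
#' @param material a [material()] or a built-in material name
#'   (`"water"`, `"pmma"`, `"polystyrene"`, ...).
#' @param radius cylinder radius, cm.
#' @param height full cylinder height, cm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(material = "water", radius = 20, height = 40) {
  if (is.character(material)) material <- get_material(material)
  stopifnot(inherits(material, "material"))
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (!is.finite(height) || height <= 0) stop("height must be > 0")
  structure(list(material = material, radius = radius, height = height),
            class = "phantom_spec")
}

#' Shell tally specification
#'
#' Thin full-azimuth cylindrical shells centred on the source transverse
#' plane.  Defaults: 0.5 mm thick, 0.5 mm high shells at 1-15 cm, 1 keV
#' energy bins above a 10 keV transport cutoff.
#'
#' @param distances shell centre radii, cm.
#' @param thickness radial shell thickness, cm.
#' @param height axial shell height, cm.
#' @param bin_width energy bin width, MeV.
#' @param cutoff photon transport cutoff energy, MeV.
#' @return an object of class `shell_tally_spec`.
#' @export
shell_tally_spec <- function(distances = 1:15, thickness = 0.05, height = 0.05,
                             bin_width = 0.001, cutoff = 0.010) {
  distances <- as.numeric(distances)
  if (any(distances <= 0)) stop("tally distances must be > 0")
  if (thickness <= 0 || height <= 0 || bin_width <= 0)
    stop("thickness, height and bin_width must be > 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(distances = sort(distances), thickness = thickness,
                 height = height, bin_width = bin_width, cutoff = cutoff),
            class = "shell_tally_spec")
}

# strictly increasing log-energy grid + logged partials for the C++ engine
.engine_grid <- function(tab) {
  e <- tab$energy
  for (i in seq_along(e)[-1]) if (e[i] <= e[i - 1]) e[i] <- e[i - 1] * (1 + 1e-12)
  logz <- function(y) ifelse(y > 0, log(y), -746)
  list(logE = log(e), pe = logz(tab$photoelectric), inc = logz(tab$incoherent),
       coh = logz(tab$coherent), pair = logz(tab$pair))
}

#' Analog photon transport with track-length fluence tallies
#'
#' Simulates `histories` photon histories emitted isotropically from the
#' phantom centre and scores track-length fluence per shell and energy bin.
#' Interactions: photoelectric absorption, incoherent (free-electron
#' Klein-Nishina) scattering, coherent scattering (form-factor-weighted
#' Thomson, for materials with form-factor data), and pair production above
#' 1.022 MeV (local termination plus two back-to-back 0.511 MeV photons).
#' Electrons are not transported (collision kerma approximates dose).
#' Histories are split into equal batches; per-bin 1-sigma uncertainties are
#' standard errors of the batch means.  With the same `seed` and inputs the
#' tally is bit-identical.
#'
#' @param source a [source_spectrum()] or built-in source name.
#' @param phantom a [phantom_spec()].
#' @param tally a [shell_tally_spec()].
#' @param histories total number of photon histories (>= `batches`).
#' @param seed integer RNG seed recorded in the result.
#' @param batches number of statistical batches (default 10).
#' @param coefficients optional [coefficient_table()] overriding the phantom
#'   material's mixture table (used by toy-world fixtures).
#' @param use_coherent include coherent deflections (default TRUE; ignored
#'   when the table's coherent column is all zero).
#' @return an object of class `fluence_tally`: fields `distances`, `e_mid`,
#'   `e_edges`, `fluence` (shells x bins, cm^-2 per source photon), `sigma`,
#'   `batch_fluence` (shells x bins x batches), `histories`, `batches`,
#'   `seed`, `source`, `phantom`, `tally`.
#' @export
simulate_transport <- function(source, phantom, tally = shell_tally_spec(),
                               histories, seed, batches = 10L,
                               coefficients = NULL, use_coherent = TRUE) {
  if (is.character(source)) source <- get_source(source)
  stopifnot(inherits(source, "source_spectrum"),
            inherits(phantom, "phantom_spec"),
            inherits(tally, "shell_tally_spec"))
  histories <- as.numeric(histories)
  batches <- as.integer(batches)
  if (histories < batches) stop("histories must be >= batches")
  if (any(tally$distances + tally$thickness / 2 >= phantom$radius))
    stop("tally distances must lie inside the phantom radius")
  tab <- coefficients %||% mixture_table(phantom$material)
  e_max <- max(source$lines$energy_MeV)
  if (e_max > 2 * 0.51099895) e_max <- max(e_max, 0.511)
  if (tally$cutoff < min(tab$energy) || e_max > max(tab$energy))
    stop(sprintf("coefficient grid [%g, %g] MeV does not cover [%g, %g]",
                 min(tab$energy), max(tab$energy), tally$cutoff, e_max))
  # when e_max falls exactly on a bin edge it belongs to the bin below
  nbins <- ceiling((e_max - tally$cutoff) / tally$bin_width - 1e-9)
  g <- .engine_grid(tab)
  has_coh <- use_coherent && any(tab$coherent > 0)
  if (has_coh) {
    ff <- tryCatch(.mixture_ff_cumulative(phantom$material, e_max),
                   error = function(e) NULL)
    if (is.null(ff)) {
      has_coh <- FALSE
      warning("no form-factor data for phantom material '",
              phantom$material$name,
              "'; coherent interactions leave the direction unchanged")
    }
  }
  if (!has_coh) ff <- list(x2 = numeric(0), cum = numeric(0))
  nb_each <- rep(floor(histories / batches), batches)
  nb_each[batches] <- histories - sum(nb_each[-batches])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  raw <- .simulate_cpp(source$lines$energy_MeV,
                       cumsum(source$lines$probability),
                       g$logE, g$pe, g$inc, g$coh, g$pair,
                       phantom$material$density,
                       phantom$radius, phantom$height / 2,
                       tally$distances, tally$thickness, tally$height,
                       tally$cutoff, tally$bin_width, as.integer(nbins),
                       nb_each, ff$x2, ff$cum, has_coh)
  vol <- 2 * pi * tally$distances * tally$thickness * tally$height
  nshell <- length(tally$distances)
  batch_fl <- array(raw, dim = c(nshell, nbins, batches))
  for (b in seq_len(batches))
    batch_fl[, , b] <- batch_fl[, , b] / (vol * nb_each[b])
  fl <- apply(batch_fl, c(1, 2), mean)
  sg <- apply(batch_fl, c(1, 2), stats::sd) / sqrt(batches)
  edges <- tally$cutoff + tally$bin_width * (0:nbins)
  structure(list(distances = tally$distances,
                 e_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 e_edges = edges, fluence = fl, sigma = sg,
                 batch_fluence = batch_fl, histories = histories,
                 batches = batches, seed = as.integer(seed),
                 source = source$name, phantom = phantom$material$name,
                 tally = tally, coherent = has_coh),
            class = "fluence_tally")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.fluence_tally <- function(x, ...) {
  cat(sprintf(paste0("<fluence_tally: %s in %s, %g histories x %d batches, ",
                     "%d shells (%g-%g cm), %d bins, seed %d>\n"),
              x$source, x$phantom, x$histories, x$batches,
              length(x$distances), min(x$distances), max(x$distances),
              length(x$e_mid), x$seed))
  invisible(x)
}

#' Exponential free-path sampling
#'
#' `s = -log(U)/mu` with `U` uniform on (0, 1].
#'
#' @param mu_linear linear attenuation coefficient, 1/cm (> 0).
#' @param n number of samples.
#' @return path lengths in cm.
#' @export
sample_free_path <- function(mu_linear, n = 1L) {
  if (!is.finite(mu_linear) || mu_linear <= 0) stop("mu_linear must be > 0")
  -log(stats::runif(n)) / mu_linear
}

#' Klein-Nishina Compton sampling
#'
#' Samples (scattered energy, polar scattering angle) pairs from the
#' free-electron Klein-Nishina differential cross section; the kinematic
#' relation `E' = E / (1 + (E/0.511)(1 - cos theta))` holds exactly for every
#' sample.
#'
#' @param energy incident photon energy, MeV.
#' @param n number of samples.
#' @return matrix with columns `energy_MeV` (scattered energy) and
#'   `cos_theta`.
#' @export
sample_compton <- function(energy, n = 1L) {
  if (!is.finite(energy) || energy <= 0) stop("energy must be > 0")
  .sample_compton_cpp(energy, as.integer(n))
}

#' Write a fluence tally to CSV (+ JSON sidecar)
#'
#' Columns `shell_cm`, `E_low_MeV`, `E_high_MeV`, `fluence`, `sigma`; run
#' metadata (seed, histories, phantom, source) goes to `<path>.json`.
#'
#' @param tally a `fluence_tally`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tally, path) {
  stopifnot(inherits(tally, "fluence_tally"))
  nb <- length(tally$e_mid)
  df <- data.frame(
    shell_cm = rep(tally$distances, each = nb),
    E_low_MeV = rep(tally$e_edges[-(nb + 1)], length(tally$distances)),
    E_high_MeV = rep(tally$e_edges[-1], length(tally$distances)),
    fluence = as.vector(t(tally$fluence)),
    sigma = as.vector(t(tally$sigma)))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(source = tally$source, phantom = tally$phantom,
               histories = tally$histories, batches = tally$batches,
               seed = tally$seed,
               distances_cm = tally$distances,
               cutoff_MeV = tally$tally$cutoff,
               bin_width_MeV = tally$tally$bin_width)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
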