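# Standard atomic numbers and (current IUPAC) standard atomic weights for the
# elements occurring in the film and phantom compositions.
.atomic_Z <- c(H = 1, Li = 3, C = 6, N = 7, O = 8, Cl = 17, K = 19,
               Br = 35, Cs = 55)
.atomic_A <- c(H = 1.008, Li = 6.94, C = 12.011, N = 14.007, O = 15.999,
               Cl = 35.45, K = 39.0983, Br = 79.904, Cs = 132.905)

#' Material composition
#'
#' A named elemental mixture by weight fraction with a mass density.  Printed
#' film/phantom compositions carry rounding error (one row sums to 1.035), so
#' fractions are validated loosely here and renormalised to unit sum wherever
#' a mixture quantity is computed.
#'
#' @param name text label.
#' @param elements named numeric vector of weight fractions, names are element
#'   symbols.
#' @param density mass density in g/cm^3.
#' @return an object of class `material`.
#' @export
material <- function(name, elements, density) {
  if (is.null(names(elements)) || any(names(elements) == ""))
    stop("elements must be a named vector of weight fractions")
  unknown <- setdiff(names(elements), names(.atomic_Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  w <- as.numeric(elements)
  if (any(w <= 0) || any(w > 1))
    stop("weight fractions must lie in (0, 1]")
  if (abs(sum(w) - 1) > 0.05)
    stop(sprintf("weight fractions of '%s' sum to %.3f; expected ~1", name, sum(w)))
  if (!is.finite(density) || density <= 0)
    stop("density must be positive")
  structure(list(name = as.character(name)[1],
                 elements = stats::setNames(w, names(elements)),
                 density = as.numeric(density)),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material '%s' rho=%.3g g/cm3: %s>\n", x$name, x$density,
              paste(sprintf("%s %.3f", names(x$elements), x$elements),
                    collapse = ", ")))
  invisible(x)
}

.norm_w <- function(m) m$elements / sum(m$elements)

#' Built-in material and film registry
#'
#' Phantom media (water, PMMA, polystyrene), structural film layers
#' (polyester, adhesive, surface coat) and the active emulsion layers of the
#' seven investigated radiochromic films, with the published weight fractions
#' and densities; plus the layer structure (role, thickness in micrometres,
#' material) of each film.
#'
#' @return a list with elements `materials` (named list of [material()]) and
#'   `films` (named list of `film_stack` objects, each a data.frame-like list
#'   with `layers`).
#' @export
builtin_registry <- function() {
  if (!is.null(.rcfilm_env$registry)) return(.rcfilm_env$registry)
  M <- list(
    water        = material("water", c(H = 0.112, O = 0.888), 1.0),
    pmma         = material("pmma", c(H = 0.081, C = 0.599, O = 0.320), 1.19),
    polystyrene  = material("polystyrene", c(H = 0.077, C = 0.923), 1.06),
    polyester    = material("polyester", c(H = 0.042, C = 0.625, O = 0.333), 1.35),
    adhesive     = material("adhesive", c(H = 0.094, C = 0.656, O = 0.249), 1.2),
    surface      = material("surface", c(H = 0.065, C = 0.323, N = 0.216,
                                         O = 0.205, Li = 0.023, Cl = 0.168), 1.2),
    ebt          = material("ebt", c(H = 0.094, C = 0.574, N = 0.132, O = 0.164,
                                     Li = 0.008, Cl = 0.029), 1.1),
    ebt2_020609  = material("ebt2_020609", c(H = 0.096, C = 0.578, N = 0.002,
                                             O = 0.278, Li = 0.009, Cl = 0.017,
                                             K = 0.006, Br = 0.013), 1.2),
    ebt2_031109  = material("ebt2_031109", c(H = 0.095, C = 0.597, N = 0.002,
                                             O = 0.261, Li = 0.009, Cl = 0.023,
                                             K = 0.013), 1.2),
    rtqa         = material("rtqa", c(H = 0.091, C = 0.537, N = 0.127, O = 0.142,
                                      Li = 0.019, Cl = 0.084), 1.1),
    xrt          = material("xrt", c(H = 0.078, C = 0.462, N = 0.115, O = 0.143,
                                     Br = 0.076, Cs = 0.126), 1.75),
    hs           = material("hs", c(H = 0.090, C = 0.570, N = 0.160, O = 0.180), 1.08),
    xrqa         = material("xrqa", c(H = 0.064, C = 0.381, N = 0.055, O = 0.138,
                                      Li = 0.040, Br = 0.134, Cs = 0.223), 1.2)
  )
  stack <- function(film, roles, thick, mats) {
    structure(list(film = film,
                   layers = data.frame(role = roles, thickness_um = thick,
                                       material = mats,
                                       stringsAsFactors = FALSE)),
              class = "film_stack")
  }
  F <- list(
    ebt  = stack("ebt", c("polyester", "active", "surface", "active", "polyester"),
                 c(97, 17, 6, 17, 97),
                 c("polyester", "ebt", "surface", "ebt", "polyester")),
    ebt2_020609 = stack("ebt2_020609",
                 c("polyester", "adhesive", "surface", "active", "polyester"),
                 c(50, 25, 5, 30, 175),
                 c("polyester", "adhesive", "surface", "ebt2_020609", "polyester")),
    ebt2_031109 = stack("ebt2_031109",
                 c("polyester", "adhesive", "surface", "active", "polyester"),
                 c(50, 25, 5, 30, 175),
                 c("polyester", "adhesive", "surface", "ebt2_031109", "polyester")),
    rtqa = stack("rtqa", c("polyester", "adhesive", "surface", "active", "polyester"),
                 c(97, 12, 3, 17, 97),
                 c("polyester", "adhesive", "surface", "rtqa", "polyester")),
    xrt  = stack("xrt", c("polyester", "active", "polyester"), c(97, 30, 97),
                 c("polyester", "xrt", "polyester")),
    hs   = stack("hs", c("polyester", "active", "polyester"), c(97, 40, 97),
                 c("polyester", "hs", "polyester")),
    xrqa = stack("xrqa", c("polyester", "active", "surface", "active", "polyester"),
                 c(97, 25, 10, 25, 97),
                 c("polyester", "xrqa", "surface", "xrqa", "polyester"))
  )
  .rcfilm_env$registry <- list(materials = M, films = F)
  .rcfilm_env$registry
}

#' Look up a built-in material by name
#' @param name material name in the built-in registry (e.g. `"water"`,
#'   `"xrqa"`); case-insensitive.
#' @return a [material()].
#' @export
get_material <- function(name) {
  M <- builtin_registry()$materials
  key <- tolower(name)
  if (!key %in% names(M))
    stop("unknown material '", name, "'; valid names: ",
         paste(names(M), collapse = ", "))
  M[[key]]
}

#' Mean Z/A of a mixture (electron density per unit mass)
#'
#' \eqn{\langle Z/A\rangle = \sum_i w_i Z_i/A_i} with normalised weight
#' fractions and standard atomic weights.
#'
#' @param mat a [material()].
#' @return dimensionless scalar.
#' @export
electron_density_ratio_Z_over_A <- function(mat) {
  stopifnot(inherits(mat, "material"))
  w <- .norm_w(mat)
  sum(w * .atomic_Z[names(w)] / .atomic_A[names(w)])
}

#' Effective atomic number (Mayneord power law)
#'
#' \eqn{Z_{eff} = (\sum_i a_i Z_i^p)^{1/p}} where \eqn{a_i} are electron-number
#' fractions \eqn{w_i (Z_i/A_i) / \sum_j w_j (Z_j/A_j)}.  The default exponent
#' 2.94 is the classical Mayneord choice for photoelectric-dominated response.
#'
#' @param mat a [material()].
#' @param exponent power-law exponent, > 0.
#' @return dimensionless scalar.
#' @export
effective_atomic_number <- function(mat, exponent = 2.94) {
  stopifnot(inherits(mat, "material"))
  if (!is.finite(exponent) || exponent <= 0) stop("exponent must be > 0")
  w <- .norm_w(mat)
  z <- .atomic_Z[names(w)]
  ne <- w * z / .atomic_A[names(w)]
  a <- ne / sum(ne)
  sum(a * z^exponent)^(1 / exponent)
}

#' Mixture-rule mass interaction coefficient
#'
#' Weight-fraction additivity: \eqn{\sum_i w_i \mu_i(E)/\rho}.  By default the
#' printed weight fractions are renormalised to unit sum first; set
#' `normalize = FALSE` to use them as printed.
#'
#' @param mat a [material()].
#' @param energy photon energies, MeV (vectorised).
#' @param kind coefficient name, see [lookup_coefficient()].
#' @param tables named list of elemental [coefficient_table()]s, by default the
#'   bundled data.
#' @param normalize renormalise weight fractions to unit sum (default TRUE).
#' @return numeric vector, cm^2/g.
#' @export
mixture_coefficient <- function(mat, energy, kind = "total",
                                tables = element_tables(), normalize = TRUE) {
  stopifnot(inherits(mat, "material"))
  w <- if (normalize) .norm_w(mat) else mat$elements
  missing_el <- setdiff(names(w), names(tables))
  if (length(missing_el))
    stop("no coefficient table for element(s): ", paste(missing_el, collapse = ", "))
  out <- 0
  for (el in names(w))
    out <- out + w[[el]] * lookup_coefficient(tables[[el]], energy, kind)
  out
}

#' Mixture coefficient table on the union grid of the constituents
#'
#' Evaluates all five coefficients of a mixture on the union of its
#' constituents' energy grids (so absorption-edge duplicates are preserved)
#' and returns the result as a [coefficient_table()].  This is the form the
#' transport engine consumes.
#'
#' @inheritParams mixture_coefficient
#' @return a [coefficient_table()] named after the material.
#' @export
mixture_table <- function(mat, tables = element_tables(), normalize = TRUE) {
  stopifnot(inherits(mat, "material"))
  e <- sort(unique(unlist(lapply(names(mat$elements),
                                 function(el) tables[[el]]$energy))))
  lo <- max(vapply(names(mat$elements), function(el) min(tables[[el]]$energy), 0))
  hi <- min(vapply(names(mat$elements), function(el) max(tables[[el]]$energy), 0))
  e <- e[e >= lo & e <= hi]
  # retain duplicated edge energies present in any constituent grid
  dup <- unlist(lapply(names(mat$elements), function(el) {
    g <- tables[[el]]$energy
    g[duplicated(g)]
  }))
  e <- sort(c(e, unique(dup[dup >= lo & dup <= hi])))
  # at a duplicated energy, evaluate below-edge side for the first copy and
  # above-edge side for the second by nudging the query
  isdup <- c(FALSE, diff(e) == 0)
  eq <- e
  eq[which(isdup) - 1L] <- e[which(isdup) - 1L] * (1 - 1e-9)
  vals <- lapply(c("photoelectric", "incoherent", "coherent", "pair",
                   "mu_en_over_rho"),
                 function(k) mixture_coefficient(mat, eq, k, tables, normalize))
  names(vals) <- c("photoelectric", "incoherent", "coherent", "pair",
                   "mu_en_over_rho")
  coefficient_table(mat$name, e, vals$photoelectric, vals$incoherent,
                    vals$coherent, vals$pair, vals$mu_en_over_rho)
}

#' Read a material registry override from a YAML config file
#'
#' The file maps material names to `density` and an `elements` map of
#' element: weight-fraction pairs, e.g.
#' \preformatted{
#' mywater:
#'   density: 1.0
#'   elements: {H: 0.112, O: 0.888}
#' }
#'
#' @param path YAML file path.
#' @return named list of [material()] objects.
#' @export
read_materials_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read material config files")
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    spec <- cfg[[nm]]
    material(nm, unlist(spec$elements), spec$density)
  })
  stats::setNames(out, names(cfg))
}
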