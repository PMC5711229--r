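#' Photon interaction coefficient tables
#'
#' A `coefficient_table` holds mass interaction coefficients (cm^2/g) for one
#' element (or one mixture) on a tabulated photon-energy grid: the partial
#' coefficients `photoelectric`, `incoherent`, `coherent` and `pair`, and the
#' mass energy-absorption coefficient `mu_en_over_rho`.  The total mass
#' attenuation coefficient is the sum of the four partials.  Absorption edges
#' (Br and Cs K edges in the bundled data) are represented by duplicated grid
#' energies carrying the below-edge and above-edge values, so that
#' interpolation never bridges an edge.
#'
#' @param element single character label.
#' @param energy strictly increasing photon energies in MeV (exact duplicates
#'   allowed to mark absorption edges).
#' @param photoelectric,incoherent,coherent,pair,mu_en_over_rho numeric vectors
#'   of mass coefficients (cm^2/g), same length as `energy`, all non-negative.
#' @return an object of class `coefficient_table`.
#' @seealso [lookup_coefficient()], [make_toy_table()], [element_tables()]
#' @export
coefficient_table <- function(element, energy, photoelectric, incoherent,
                              coherent, pair, mu_en_over_rho) {
  energy <- as.numeric(energy)
  cols <- list(photoelectric = as.numeric(photoelectric),
               incoherent = as.numeric(incoherent),
               coherent = as.numeric(coherent),
               pair = as.numeric(pair),
               mu_en_over_rho = as.numeric(mu_en_over_rho))
  n <- length(energy)
  if (n < 2L)
    stop("coefficient_table needs at least two grid points")
  for (nm in names(cols)) {
    if (length(cols[[nm]]) != n)
      stop("column '", nm, "' must have the same length as the energy grid")
    if (any(!is.finite(cols[[nm]])) || any(cols[[nm]] < 0))
      stop("column '", nm, "' must be finite and non-negative")
  }
  if (any(diff(energy) < 0))
    stop("energy grid must be non-decreasing")
  if (any(diff(energy) == 0 & c(diff(energy)[-1], 1) == 0))
    stop("more than two identical energies in a row (one duplicated edge node allowed)")
  total <- cols$photoelectric + cols$incoherent + cols$coherent + cols$pair
  if (any(cols$mu_en_over_rho > total * (1 + 1e-9) + 1e-300))
    stop("mu_en_over_rho exceeds the total mass attenuation coefficient")
  structure(c(list(element = as.character(element)[1], energy = energy),
              cols, list(total = total)),
            class = "coefficient_table")
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat(sprintf("<coefficient_table '%s': %d energies, %.4g-%.4g MeV>\n",
              x$element, length(x$energy), min(x$energy), max(x$energy)))
  invisible(x)
}

.coef_kinds <- c("photoelectric", "incoherent", "coherent", "pair",
                 "mu_en_over_rho", "total")

#' Interpolate a mass interaction coefficient
#'
#' Log-log interpolation in photon energy, the standard convention for photon
#' cross sections.  Grid nodes are reproduced exactly.  Queries at a
#' duplicated (absorption-edge) energy return the above-edge value; queries on
#' either side interpolate strictly within their side of the edge.  Intervals
#' where either endpoint is zero fall back to linear interpolation, so that
#' zero columns (e.g. `pair` below threshold) stay exactly zero.
#'
#' @param table a [coefficient_table()].
#' @param energy photon energies in MeV (vectorised); must lie within the grid.
#' @param kind one of `"photoelectric"`, `"incoherent"`, `"coherent"`,
#'   `"pair"`, `"mu_en_over_rho"`, `"total"`.
#' @return numeric vector of coefficients in cm^2/g.
#' @export
lookup_coefficient <- function(table, energy, kind = "total") {
  stopifnot(inherits(table, "coefficient_table"))
  kind <- match.arg(kind, .coef_kinds)
  e <- as.numeric(energy)
  g <- table$energy
  lo <- g[1L]; hi <- g[length(g)]
  if (any(e < lo) || any(e > hi))
    stop(sprintf("energy out of range for element '%s': grid covers [%g, %g] MeV, got %g",
                 table$element, lo, hi, e[which(e < lo | e > hi)[1L]]))
  y <- table[[kind]]
  # findInterval with left.open = FALSE: index of last grid value <= e, so an
  # exact hit on a duplicated edge energy selects the above-edge row.
  i <- findInterval(e, g)
  i[i >= length(g)] <- length(g) - 1L
  x0 <- g[i]; x1 <- g[i + 1L]
  y0 <- y[i]; y1 <- y[i + 1L]
  out <- numeric(length(e))
  exact_hi <- x1 == e & x0 != e   # top grid node: return it bit-exactly
  exact <- x0 == e
  out[exact] <- y0[exact]
  out[exact_hi] <- y1[exact_hi]
  idx <- which(!exact & !exact_hi)
  if (length(idx)) {
    x0i <- x0[idx]; x1i <- x1[idx]; y0i <- y0[idx]; y1i <- y1[idx]; ei <- e[idx]
    f <- (log(ei) - log(x0i)) / (log(x1i) - log(x0i))
    v <- ifelse(y0i > 0 & y1i > 0,
                exp(log(y0i) + f * (log(y1i) - log(y0i))),
                y0i + (ei - x0i) / (x1i - x0i) * (y1i - y0i))
    out[idx] <- v
  }
  out
}

#' Flat toy coefficient table for fixtures
#'
#' Builds an energy-independent table covering 1e-4 to 100 MeV whose
#' photoelectric share is `absorber_fraction` of `mu_total` and whose
#' incoherent share is the remainder; coherent and pair are zero.  Together
#' with single-line toy sources this gives closed-form uncollided fluence and
#' kerma, so every pipeline stage can be checked without physics tables.
#'
#' @param mu_total total mass attenuation coefficient, cm^2/g.
#' @param mu_en mass energy-absorption coefficient, cm^2/g (`<= mu_total`).
#' @param absorber_fraction photoelectric fraction of `mu_total`, in `[0, 1]`.
#' @return a [coefficient_table()] labelled `"toy"`.
#' @export
make_toy_table <- function(mu_total, mu_en, absorber_fraction) {
  if (!is.finite(mu_total) || mu_total < 0)
    stop("mu_total must be a non-negative number")
  if (!is.finite(mu_en) || mu_en < 0 || mu_en > mu_total + 1e-12)
    stop("mu_en must satisfy 0 <= mu_en <= mu_total")
  if (!is.finite(absorber_fraction) || absorber_fraction < 0 || absorber_fraction > 1)
    stop("absorber_fraction must lie in [0, 1]")
  e <- c(1e-4, 100)
  coefficient_table("toy", e,
                    photoelectric = rep(mu_total * absorber_fraction, 2L),
                    incoherent = rep(mu_total * (1 - absorber_fraction), 2L),
                    coherent = c(0, 0), pair = c(0, 0),
                    mu_en_over_rho = rep(mu_en, 2L))
}

#' Bundled elemental coefficient tables
#'
#' Loads the packaged per-element tables (H, C, N, O, Li, Cl, K, Br, Cs;
#' 0.008-1.6 MeV) once per session.  Provenance is recorded in the header of
#' `inst/extdata/xsec_elements.csv`.
#'
#' @param path optional path to a CSV with columns `element`, `energy_MeV`,
#'   `photoelectric`, `incoherent`, `coherent`, `pair`, `mu_en_over_rho`
#'   (comment lines start with `#`), used instead of the packaged file.
#' @return named list of [coefficient_table()] objects.
#' @export
element_tables <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.rcfilm_env$element_tables)) return(.rcfilm_env$element_tables)
    path <- system.file("extdata", "xsec_elements.csv", package = "rcfilm",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "energy_MeV", "photoelectric", "incoherent", "coherent",
            "pair", "mu_en_over_rho")
  if (!all(need %in% names(df)))
    stop("coefficient file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$element), function(d) {
    d <- d[order(d$energy_MeV), , drop = FALSE]
    coefficient_table(d$element[1L], d$energy_MeV, d$photoelectric,
                      d$incoherent, d$coherent, d$pair, d$mu_en_over_rho)
  })
  if (cache) .rcfilm_env$element_tables <- out
  out
}
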