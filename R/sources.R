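#' Discrete photon emission spectrum of a source
#'
#' @param name text label.
#' @param energies line energies in MeV, each in (0, 1.5].
#' @param probabilities emission probabilities (any positive weights; they are
#'   normalised to unit sum).
#' @param reference provenance note for the line data.
#' @return an object of class `source_spectrum` with fields `name`, `lines`
#'   (data.frame `energy_MeV`, `probability`) and `reference`.
#' @export
source_spectrum <- function(name, energies, probabilities, reference = "") {
  e <- as.numeric(energies); p <- as.numeric(probabilities)
  if (length(e) == 0L || length(e) != length(p))
    stop("energies and probabilities must be non-empty and of equal length")
  if (any(!is.finite(e)) || any(e <= 0) || any(e > 1.5))
    stop("line energies must lie in (0, 1.5] MeV")
  if (any(!is.finite(p)) || any(p <= 0))
    stop("emission probabilities must be positive")
  o <- order(e)
  structure(list(name = as.character(name)[1],
                 lines = data.frame(energy_MeV = e[o],
                                    probability = p[o] / sum(p)),
                 reference = reference),
            class = "source_spectrum")
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf("<source_spectrum '%s': %d lines, mean %.4g MeV>\n", x$name,
              nrow(x$lines), sum(x$lines$energy_MeV * x$lines$probability)))
  invisible(x)
}

#' Built-in brachytherapy source models
#'
#' Bare isotropic point emitters:
#' \describe{
#'   \item{co60}{two gamma lines, 1.17 and 1.33 MeV, equal weights.}
#'   \item{cs137}{single 0.662 MeV line.}
#'   \item{ir192}{principal gamma lines of the Ir-192 decay (to Pt-192 and
#'     Os-192) plus Pt/Os K x-rays, from standard decay data, normalised.}
#'   \item{yb169}{principal gamma lines of the Yb-169 decay to Tm-169 plus
#'     Tm K x-rays, from standard decay data, normalised.  Tm L x-rays
#'     (7-10 keV) fall below the 10 keV transport cutoff and are omitted.}
#' }
#' Source encapsulation, cable, beta spectra and internal-conversion electrons
#' are not modelled; the response correction R is a ratio of like-geometry
#' kerma values, which suppresses sensitivity to the common geometry.
#'
#' @return named list of [source_spectrum()] objects.
#' @export
builtin_sources <- function() {
  if (!is.null(.rcfilm_env$sources)) return(.rcfilm_env$sources)
  ir_E <- c(0.06149, 0.06300,                     # Os K-alpha x-rays (EC branch)
            0.06512, 0.06683, 0.07575, 0.07785,   # Pt K x-rays (beta- branch)
            0.13634, 0.20131, 0.20579, 0.28327, 0.29596, 0.30846, 0.31651,
            0.37449, 0.41647, 0.46807, 0.48458, 0.48906, 0.58858, 0.60441,
            0.61246, 0.88454, 1.06148)
  ir_I <- c(0.75, 1.28,
            2.60, 4.46, 1.53, 0.43,
            0.199, 0.473, 3.34, 0.266, 28.71, 29.70, 82.86,
            0.726, 0.670, 47.84, 3.189, 0.438, 4.517, 8.20,
            5.34, 0.292, 0.053)
  yb_E <- c(0.049773, 0.050742, 0.057500, 0.059160,  # Tm K x-rays
            0.063121, 0.093614, 0.109779, 0.118189, 0.130523, 0.177213,
            0.197957, 0.261077, 0.307736)
  yb_I <- c(52.0, 93.0, 29.8, 8.04,
            44.05, 2.58, 17.39, 1.87, 11.38, 22.45,
            36.02, 1.76, 10.05)
  .rcfilm_env$sources <- list(
    co60 = source_spectrum("co60", c(1.17, 1.33), c(0.5, 0.5),
                           "two gamma lines of the Co-60 decay, equal weights"),
    cs137 = source_spectrum("cs137", 0.662, 1,
                            "single 0.662 MeV gamma line of the Cs-137 decay"),
    ir192 = source_spectrum("ir192", ir_E, ir_I,
                            paste("principal Ir-192 gamma lines and Pt/Os K",
                                  "x-rays, standard decay data (intensities",
                                  "per 100 decays), normalised")),
    yb169 = source_spectrum("yb169", yb_E, yb_I,
                            paste("principal Yb-169 gamma lines and Tm K",
                                  "x-rays, standard decay data (intensities",
                                  "per 100 decays), normalised; L x-rays",
                                  "below the 10 keV cutoff omitted"))
  )
  .rcfilm_env$sources
}

#' Look up a built-in source by name
#' @param name one of `"co60"`, `"cs137"`, `"ir192"`, `"yb169"`.
#' @return a [source_spectrum()].
#' @export
get_source <- function(name) {
  S <- builtin_sources()
  key <- tolower(name)
  if (!key %in% names(S))
    stop("unknown source '", name, "'; valid names: ",
         paste(names(S), collapse = ", "))
  S[[key]]
}

#' Sample emission energies from a line spectrum
#'
#' @param spectrum a [source_spectrum()].
#' @param n number of draws.
#' @return numeric vector of line energies (MeV); each line is drawn with its
#'   stated probability.
#' @export
sample_emission <- function(spectrum, n = 1L) {
  stopifnot(inherits(spectrum, "source_spectrum"))
  idx <- findInterval(stats::runif(n), cumsum(spectrum$lines$probability),
                      left.open = TRUE) + 1L
  idx[idx > nrow(spectrum$lines)] <- nrow(spectrum$lines)
  spectrum$lines$energy_MeV[idx]
}

#' Read a source spectrum from a two-column CSV
#'
#' Columns `energy_MeV` and `probability` (header required; `#` comments
#' allowed).
#'
#' @param path CSV file path.
#' @param name label for the resulting spectrum (default: file name).
#' @return a [source_spectrum()].
#' @export
read_spectrum_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("energy_MeV", "probability") %in% names(df)))
    stop("spectrum file must have columns energy_MeV, probability")
  source_spectrum(name %||% sub("\\.csv$", "", basename(path)),
                  df$energy_MeV, df$probability,
                  reference = paste("read from", path))
}
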