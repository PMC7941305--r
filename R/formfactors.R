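## Atomic form factors.
##
## The wavelength-independent part f0(s) uses the 4-Gaussian-plus-constant
## crystallographic parameterization (International Tables for
## Crystallography Vol. C, Cromer-Mann coefficients), shipped as a plain
## text table in extdata.  Anomalous dispersion corrections f'(E), f''(E)
## are linear interpolations on (energy, f', f'') tables: built-in
## theoretical Cromer-Liberman tables for common absorption-edge elements
## are shipped in the same ASCII format accepted for user tables, so
## built-in versus user is purely a lookup-path difference.

.ff_env <- new.env(parent = emptyenv())

ff_table <- function() {
  if (is.null(.ff_env$it92)) {
    path <- system.file("extdata", "it92_coefficients.txt", package = "saxskit")
    tab <- read.table(path, header = FALSE, comment.char = "#",
                      col.names = c("element", "Z", paste0("a", 1:4),
                                    paste0("b", 1:4), "c"),
                      stringsAsFactors = FALSE)
    rownames(tab) <- tab$element
    .ff_env$it92 <- tab
  }
  .ff_env$it92
}

#' Supported element symbols
#'
#' Elements for which wavelength-independent form factor coefficients are
#' embedded (hydrogen through uranium).
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() ff_table()$element

#' Atomic number of a supported element
#' @param element element symbol.
#' @return Integer number of electrons.
#' @export
element_z <- function(element) {
  element <- normalize_element(element)
  tab <- ff_table()
  if (!all(element %in% tab$element))
    stop("unsupported element: ",
         paste(setdiff(element, tab$element), collapse = ", "))
  tab[element, "Z"]
}

#' Wavelength-independent atomic form factor f0(s)
#'
#' Evaluates the 4-Gaussian-plus-constant parameterization
#' `f0 = c + sum_i a_i exp(-b_i (s / 4 pi)^2)` at momentum transfer
#' `s = 4 pi sin(theta) / lambda` (the crystallographic tables are indexed
#' by `sin(theta)/lambda = s / 4 pi`).  At `s = 0` the form factor equals
#' the electron count of the neutral atom to within 0.1 electron.
#'
#' @param element element symbol.
#' @param s momentum transfer, reciprocal Angstrom, `>= 0` (vectorized).
#' @return Form factor in electrons, same length as `s`.
#' @examples
#' f0("C", 0)          # ~6 electrons
#' f0("O", c(0, 0.5, 1))
#' @export
f0 <- function(element, s) {
  element <- normalize_element(element)
  if (length(element) != 1L) stop("'element' must be a single symbol")
  tab <- ff_table()
  if (!element %in% tab$element) stop("unsupported element: ", element)
  if (any(s < 0)) stop("'s' must be >= 0")
  row <- tab[element, ]
  k2 <- (s / (4 * pi))^2
  out <- rep(row$c, length(s))
  for (i in 1:4)
    out <- out + row[[paste0("a", i)]] * exp(-row[[paste0("b", i)]] * k2)
  out
}

#' Read an anomalous-correction table
#'
#' Tables are ASCII with `#` comment lines and rows
#' `energy_eV f_prime f_doubleprime` (a 2-column `energy f_prime` file is
#' accepted, with `f''` taken as 0).  With `path = NULL` the built-in
#' theoretical table for the element is loaded.
#'
#' @param element element symbol the table applies to.
#' @param path path to a user table, or `NULL` for the built-in table.
#' @return An object of class `anomalous_table` with columns `energy`,
#'   `fp`, `fpp`.
#' @export
anomalous_table <- function(element, path = NULL) {
  element <- normalize_element(element)
  builtin <- is.null(path)
  if (builtin) {
    path <- system.file("extdata", "anomalous", paste0(element, ".dat"),
                        package = "saxskit")
    if (!nzchar(path) || !file.exists(path))
      stop("no built-in anomalous table for element ", element,
           "; supply a user table")
  }
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("anomalous table needs >= 2 columns: ", path)
  out <- data.frame(energy = tab[[1]], fp = tab[[2]],
                    fpp = if (ncol(tab) >= 3L) tab[[3]] else 0)
  if (any(diff(out$energy) <= 0))
    stop("energies in the anomalous table must be strictly increasing")
  if (any(out$fpp < 0))
    stop("f'' must be >= 0")
  structure(out, class = c("anomalous_table", "data.frame"),
            element = element, builtin = builtin)
}

#' Anomalous dispersion corrections f'(E), f''(E)
#'
#' Linear interpolation on the energy grid of an anomalous-correction
#' table.  A user-supplied table overrides the built-in one; built-in
#' tables cover 1.0 to 29.4 keV.
#'
#' @param element element symbol.
#' @param energy X-ray energy in eV.
#' @param table optional [anomalous_table()] (or path to one); default is
#'   the built-in table for `element`.
#' @return Named numeric vector `c(fp = , fpp = )` in electrons.
#' @export
anomalous_terms <- function(element, energy, table = NULL) {
  element <- normalize_element(element)
  if (is.character(table)) table <- anomalous_table(element, table)
  if (is.null(table)) table <- anomalous_table(element)
  if (!identical(attr(table, "element"), element))
    stop("anomalous table is for element ", attr(table, "element"),
         ", not ", element)
  if (energy < min(table$energy) || energy > max(table$energy))
    stop(sprintf("energy %.1f eV outside table range [%.1f, %.1f] eV",
                 energy, min(table$energy), max(table$energy)))
  if (nrow(table) == 1L)
    return(c(fp = table$fp, fpp = table$fpp))
  c(fp = approx(table$energy, table$fp, xout = energy)$y,
    fpp = approx(table$energy, table$fpp, xout = energy)$y)
}

#' Effective complex atomic form factor
#'
#' `f(s, E) = f0(s) + f'(E) + i f''(E)`.  With `energy = NULL` the purely
#' real `f0(s)` is returned (as a complex value with zero imaginary part).
#' Near an absorption edge `f' < 0`, so the modulus drops below `f0`: the
#' atom scatters less.
#'
#' @inheritParams f0
#' @inheritParams anomalous_terms
#' @param energy X-ray energy in eV, or `NULL` for no anomalous correction.
#' @return Complex vector of effective form factors, same length as `s`.
#' @export
effective_f <- function(element, s, energy = NULL, table = NULL) {
  base <- f0(element, s)
  if (is.null(energy))
    return(complex(real = base, imaginary = 0))
  an <- anomalous_terms(element, energy, table)
  complex(real = base + an[["fp"]], imaginary = an[["fpp"]])
}
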