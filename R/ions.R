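#' Registry of imaging ions
#'
#' The five light ions commonly considered for energy-loss imaging, with
#' nuclear charge `Z`, mass number `A` and rest energy per nucleon `m_u`
#' (nuclear masses divided by `A`, in MeV).
#'
#' @return A tibble with one row per ion: `ion`, `symbol`, `Z`, `A`, `m_u`.
#' @examples
#' ion_registry()
#' @export
ion_registry <- function() {
  tibble::tibble(
    ion    = c("proton", "helium", "lithium", "boron", "carbon"),
    symbol = c("1H", "4He", "6Li", "10B", "12C"),
    Z      = c(1, 2, 3, 5, 6),
    A      = c(1, 4, 6, 10, 12),
    m_u    = c(938.2720, 931.8448, 933.5863, 932.4436, 931.2385)
  )
}

#' Construct an ion species
#'
#' Looks an ion up in [ion_registry()] by name (or symbol), or builds a custom
#' species from explicit `Z`, `A` and rest energy per nucleon.
#'
#' @param ion Name (`"proton"`, ..., `"carbon"`), symbol (`"4He"`), or an
#'   existing `ion_species` object (returned unchanged).
#' @param Z,A,m_u Charge number, mass number and rest energy per nucleon
#'   (MeV) for a custom species; all three must be given together.
#' @return An object of class `ion_species`: a list with fields `ion`,
#'   `symbol`, `Z`, `A`, `m_u`.
#' @examples
#' ion("helium")
#' ion("X", Z = 4, A = 9, m_u = 931.5)
#' @export
ion <- function(ion, Z = NULL, A = NULL, m_u = NULL) {
  if (inherits(ion, "ion_species")) return(ion)
  if (!is.null(Z) || !is.null(A) || !is.null(m_u)) {
    if (is.null(Z) || is.null(A) || is.null(m_u)) {
      abort("custom species need all of `Z`, `A`, `m_u`.")
    }
    if (Z < 1 || A < Z || m_u <= 0) {
      abort("invalid species: need Z >= 1, A >= Z, m_u > 0.")
    }
    out <- list(ion = as.character(ion), symbol = as.character(ion),
                Z = as.numeric(Z), A = as.numeric(A), m_u = as.numeric(m_u))
    class(out) <- "ion_species"
    return(out)
  }
  reg <- ion_registry()
  i <- match(tolower(as.character(ion)), c(reg$ion, tolower(reg$symbol)))
  if (is.na(i)) {
    abort(paste0("unknown ion '", ion, "'; known: ",
                 paste(reg$ion, collapse = ", "), "."))
  }
  i <- ((i - 1L) %% nrow(reg)) + 1L
  out <- as.list(reg[i, ])
  class(out) <- "ion_species"
  out
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (%s): Z = %g, A = %g, m_u = %.4f MeV\n",
              x$ion, x$symbol, x$Z, x$A, x$m_u))
  invisible(x)
}

#' Construct a stopping medium
#'
#' A medium is described by its density, mean excitation energy, radiation
#' length and electron density relative to water. [water()] is the default
#' everywhere in the package.
#'
#' @param label Medium name.
#' @param rho Density (g/cm^3).
#' @param I_eV Mean excitation energy (eV). The default for water, 78 eV,
#'   matches the value used by modern condensed-history transport codes.
#' @param X0_mm Radiation length (mm); 360.8 mm for water.
#' @param eta_e Electron density relative to water (1 for water).
#' @return An object of class `medium`.
#' @examples
#' water()
#' @export
medium <- function(label, rho, I_eV, X0_mm, eta_e) {
  stopifnot(rho > 0, I_eV > 0, X0_mm > 0, eta_e > 0)
  out <- list(label = label, rho = rho, I_eV = I_eV, X0_mm = X0_mm,
              eta_e = eta_e)
  class(out) <- "medium"
  out
}

#' @rdname medium
#' @export
water <- function() medium("water", rho = 1, I_eV = 78, X0_mm = 360.8, eta_e = 1)

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %s: rho = %g g/cm^3, I = %g eV, X0 = %g mm, eta_e = %g\n",
              x$label, x$rho, x$I_eV, x$X0_mm, x$eta_e))
  invisible(x)
}
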