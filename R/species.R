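#' Ion species
#'
#' Defines an ion species by charge, mass number and (for positron emitters)
#' half-life. The five species studied are carbon and oxygen therapy ions and
#' their positron-emitting analogs: \eqn{^{10}}C (T = 19.29 s), \eqn{^{11}}C
#' (T = 20.334 min = 1220.04 s), \eqn{^{15}}O (T = 122.24 s), and the stable
#' \eqn{^{12}}C and \eqn{^{16}}O.
#'
#' @param name species label, e.g. `"C11"`.
#' @param Z proton number (>= 1).
#' @param A mass number (>= Z).
#' @param stable logical; `TRUE` for non-radioactive species.
#' @param half_life half-life in seconds; required iff `stable = FALSE`.
#' @return an object of class `ion_species`.
#' @examples
#' ion_species("C11", 6, 11, stable = FALSE, half_life = 20.334 * 60)
#' @export
ion_species <- function(name, Z, A, stable, half_life = NULL) {
  if (Z < 1) stopf("Z must be >= 1 (got %s)", Z)
  if (A < Z) stopf("A must be >= Z (got A=%s, Z=%s)", A, Z)
  if (stable && !is.null(half_life))
    stopf("stable species '%s' must not carry a half-life", name)
  if (!stable && (is.null(half_life) || half_life <= 0))
    stopf("radioactive species '%s' needs half_life > 0", name)
  structure(list(name = name, Z = as.integer(Z), A = as.integer(A),
                 stable = isTRUE(stable),
                 half_life = if (stable) NA_real_ else as.double(half_life)),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  hl <- if (x$stable) "stable" else sprintf("T1/2 = %.4g s", x$half_life)
  cat(sprintf("<ion_species> %s (Z=%d, A=%d, %s)\n", x$name, x$Z, x$A, hl))
  invisible(x)
}

# Built-in registry. Half-lives as used in the decay model: 19.29 s (10C),
# 20.334 min (11C), 122.24 s (15O).
.species_table <- function() {
  list(
    C10 = ion_species("C10", 6, 10, FALSE, 19.29),
    C11 = ion_species("C11", 6, 11, FALSE, 20.334 * 60),
    C12 = ion_species("C12", 6, 12, TRUE),
    O15 = ion_species("O15", 8, 15, FALSE, 122.24),
    O16 = ion_species("O16", 8, 16, TRUE)
  )
}

#' Look up a built-in ion species by name
#'
#' @param name one of `"C10"`, `"C11"`, `"C12"`, `"O15"`, `"O16"`, or an
#'   `ion_species` object (returned unchanged).
#' @return an `ion_species`.
#' @export
get_species <- function(name) {
  if (inherits(name, "ion_species")) return(name)
  tab <- .species_table()
  if (!name %in% names(tab))
    stopf("unknown species '%s' (known: %s)", name, paste(names(tab), collapse = ", "))
  tab[[name]]
}

# Stable analog of a radioactive species (same element, therapy isotope).
stable_analog <- function(species) {
  species <- get_species(species)
  if (species$stable) return(species)
  if (species$Z == 6) get_species("C12") else if (species$Z == 8) get_species("O16")
  else stopf("no stable analog registered for Z=%d", species$Z)
}
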