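#' Define an anti-freeze agent
#'
#' An anti-freeze agent (solute) is described by its molecular weight and
#' its degree of dissociation `i` — the effective number of particles each
#' formula unit contributes in solution (1 for sugars and polyols, 2 for a
#' fully dissociated 1:1 salt such as NaCl).
#'
#' @param name character identifier.
#' @param molecular_weight molecular weight in g/mol; must be positive.
#' @param dissociation_degree effective particles per formula unit
#'   (>= 1, default 1).
#' @return An object of class `solute_spec`.
#' @examples
#' glucose <- solute_spec("glucose", 180)
#' nacl <- solute_spec("NaCl", 58.4, dissociation_degree = 2)
#' @export
solute_spec <- function(name, molecular_weight, dissociation_degree = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("solute name must be a non-empty string")
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0)
    validation_error("molecular_weight must be a positive number (g/mol)")
  if (!is.numeric(dissociation_degree) || length(dissociation_degree) != 1L ||
      !is.finite(dissociation_degree) || dissociation_degree < 1)
    validation_error("dissociation_degree must be >= 1")
  structure(
    list(name = name, molecular_weight = molecular_weight,
         dissociation_degree = dissociation_degree),
    class = "solute_spec"
  )
}

#' @export
print.solute_spec <- function(x, ...) {
  cat(sprintf("<solute> %s: Mw %.1f g/mol, i = %g\n",
              x$name, x$molecular_weight, x$dissociation_degree))
  invisible(x)
}

#' Bundled anti-freeze agent registry
#'
#' Returns the registry of anti-freeze agents studied in frozen-dessert
#' model systems: glucose (180 g/mol), sucrose (342), maltodextrin (800,
#' dextrose equivalent 16.5-19.5), ethanol (46.5), xylitol (152) and NaCl
#' (58.4, i = 2). The registry ships as a plain CSV under
#' `inst/extdata/antifreeze_registry.csv` with columns
#' `name, mw_g_per_mol, dissociation_degree`.
#'
#' @param path path to a registry CSV; defaults to the bundled file.
#' @return A data.frame with columns `name`, `mw_g_per_mol`,
#'   `dissociation_degree`.
#' @examples
#' default_registry()
#' @export
default_registry <- function(path = system.file("extdata",
                                                "antifreeze_registry.csv",
                                                package = "cryocurve")) {
  read_registry(path)
}

#' Read a solute registry CSV
#'
#' @param path CSV file with columns `name, mw_g_per_mol,
#'   dissociation_degree`.
#' @return data.frame registry.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) validation_error(paste0("registry not found: ", path))
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mw_g_per_mol", "dissociation_degree")
  missing <- setdiff(need, names(reg))
  if (length(missing))
    validation_error(paste0("registry is missing columns: ",
                            paste(missing, collapse = ", ")))
  if (any(reg$mw_g_per_mol <= 0) || any(reg$dissociation_degree < 1))
    validation_error("registry has non-physical molecular weights or i < 1")
  reg
}

#' Look up a solute in a registry
#'
#' @param name solute name (case-insensitive match on the registry).
#' @param registry registry data.frame, see [default_registry()].
#' @return A [solute_spec()].
#' @examples
#' registry_solute("glucose")
#' @export
registry_solute <- function(name, registry = default_registry()) {
  hit <- which(tolower(registry$name) == tolower(name))
  if (length(hit) != 1L)
    validation_error(paste0("solute not found in registry: ", name))
  solute_spec(registry$name[hit], registry$mw_g_per_mol[hit],
              registry$dissociation_degree[hit])
}

#' Define a solution composition
#'
#' A premix: one or more anti-freeze agents dissolved in water, expressed
#' as mass percentages of the total sample. Water makes up the remainder of
#' the basis mass (default 100 g).
#'
#' @param solutes a [solute_spec()], a list of them, or a character vector
#'   of names resolved against `registry`.
#' @param mass_pct numeric vector of concentrations, % w/w of the total
#'   sample, one per solute; each in (0, 100) and summing below 100. May be
#'   empty (pure water) together with an empty solute list.
#' @param basis_mass total sample mass in g (default 100).
#' @param registry registry used to resolve character solute names.
#' @return An object of class `solution` with elements `solutes` (list of
#'   `solute_spec`), `mass_pct`, `basis_mass`.
#' @examples
#' solution("glucose", 11.5)
#' solution(solute_spec("sucrose", 342), 15)
#' solution(character(0), numeric(0)) # pure water
#' @export
solution <- function(solutes, mass_pct, basis_mass = 100,
                     registry = default_registry()) {
  if (inherits(solutes, "solute_spec")) solutes <- list(solutes)
  if (is.character(solutes))
    solutes <- lapply(solutes, registry_solute, registry = registry)
  if (!is.list(solutes) || !all(vapply(solutes, inherits, logical(1), "solute_spec")))
    validation_error("solutes must be solute_spec objects or registry names")
  if (length(solutes) != length(mass_pct))
    validation_error("one mass_pct per solute is required")
  if (!is.numeric(basis_mass) || basis_mass <= 0)
    validation_error("basis_mass must be positive")
  if (length(mass_pct)) {
    if (any(!is.finite(mass_pct)) || any(mass_pct <= 0) || any(mass_pct >= 100))
      validation_error("each mass_pct must lie in (0, 100)")
    if (sum(mass_pct) >= 100)
      validation_error("solute mass fractions must sum below 100 % (no water left)")
  }
  structure(
    list(solutes = solutes, mass_pct = as.numeric(mass_pct),
         basis_mass = basis_mass),
    class = "solution"
  )
}

#' @export
print.solution <- function(x, ...) {
  if (!length(x$solutes)) {
    cat(sprintf("<solution> pure water, %.0f g\n", x$basis_mass))
    return(invisible(x))
  }
  parts <- vapply(seq_along(x$solutes), function(i)
    sprintf("%s %.3g %%", x$solutes[[i]]$name, x$mass_pct[i]), character(1))
  cat(sprintf("<solution> %s in water, basis %.0f g\n",
              paste(parts, collapse = " + "), x$basis_mass))
  invisible(x)
}

# --- internal accessors -----------------------------------------------------

solute_masses <- function(comp) comp$mass_pct / 100 * comp$basis_mass

water_mass <- function(comp) comp$basis_mass - sum(solute_masses(comp))

solute_moles <- function(comp) {
  mw <- vapply(comp$solutes, `[[`, numeric(1), "molecular_weight")
  solute_masses(comp) / mw
}

solute_names <- function(comp)
  vapply(comp$solutes, `[[`, character(1), "name")

check_solution <- function(comp) {
  if (!inherits(comp, "solution"))
    validation_error("expected a solution object")
  if (water_mass(comp) <= 0)
    validation_error("composition has no water")
  invisible(comp)
}
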