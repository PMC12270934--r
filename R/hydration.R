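#' Validate an ice-content dataset
#'
#' An ice-content dataset is a data.frame with one row per measurement:
#' columns `solute`, `concentration_pct`, `temperature_C`, `replicate`
#' (optional; a single replicate is assumed when absent) and `ice_pct`
#' (% of total sample mass, in [0, 100]).
#'
#' @param data data.frame to validate.
#' @return The validated data.frame (with a `replicate` column), invisibly
#'   usable downstream.
#' @export
as_ice_dataset <- function(data) {
  need <- c("solute", "concentration_pct", "temperature_C", "ice_pct")
  missing <- setdiff(need, names(data))
  if (length(missing))
    validation_error(paste0("ice dataset is missing columns: ",
                            paste(missing, collapse = ", ")))
  if (!nrow(data)) validation_error("ice dataset is empty")
  if (any(!is.finite(data$ice_pct)) ||
      any(data$ice_pct < 0) || any(data$ice_pct > 100))
    validation_error("ice_pct must lie in [0, 100]")
  if (is.null(data$replicate)) data$replicate <- 1L
  data
}

#' Fit an effective-hydration-number table from ice-content data
#'
#' Inverts the ice-content model cell by cell: for every
#' (solute, concentration, temperature) group the measured ice contents
#' are reduced to one effective hydration number via the closed-form
#' inversion ([hydration_number()]).
#'
#' Two replicate-handling modes are provided. The default
#' `"mean-then-invert"` averages the replicate ice contents first and
#' inverts the mean — the convention used when hydration numbers are
#' reported "calculated based on averaged experimental values". The
#' alternative `"invert-then-mean"` inverts each replicate and averages
#' the hydration numbers; the two differ only through the (linear)
#' inversion's interaction with noise and agree exactly on noiseless data.
#'
#' Cells whose inversion yields a negative hydration number (measured ice
#' above the zero-hydration ceiling) are kept, flagged `"negative_h"`, and
#' excluded from interpolation by [predict_ice_curve()].
#'
#' @param data an ice-content dataset, see [as_ice_dataset()].
#' @param registry solute registry, see [default_registry()].
#' @param method replicate handling, `"mean-then-invert"` (default) or
#'   `"invert-then-mean"`.
#' @param constants see [thermo_constants()].
#' @return A data.frame of class `hydration_table` with columns `solute`,
#'   `concentration_pct`, `temperature_C`, `h`, `flag` and an
#'   `interpolation` attribute (default `"nearest"`).
#' @examples
#' d <- data.frame(solute = "glucose", concentration_pct = 15,
#'                 temperature_C = -18, replicate = 1, ice_pct = 61.92)
#' fit_hydration_table(d)
#' @export
fit_hydration_table <- function(data, registry = default_registry(),
                                method = c("mean-then-invert",
                                           "invert-then-mean"),
                                constants = thermo_constants()) {
  method <- match.arg(method)
  data <- as_ice_dataset(data)
  unknown <- setdiff(unique(data$solute), registry$name)
  if (length(unknown))
    validation_error(paste0("solutes not in registry: ",
                            paste(unknown, collapse = ", ")))
  keys <- unique(data[c("solute", "concentration_pct", "temperature_C")])
  keys <- keys[order(keys$solute, keys$concentration_pct,
                     keys$temperature_C), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    key <- keys[k, ]
    grp <- data[data$solute == key$solute &
                  data$concentration_pct == key$concentration_pct &
                  data$temperature_C == key$temperature_C, ]
    comp <- solution(key$solute, key$concentration_pct, registry = registry)
    invert <- function(ice) withCallingHandlers(
      hydration_number(comp, key$temperature_C, ice, constants),
      warning = function(w) invokeRestart("muffleWarning"))
    h <- if (method == "mean-then-invert") invert(mean(grp$ice_pct))
         else mean(vapply(grp$ice_pct, invert, numeric(1)))
    data.frame(solute = key$solute,
               concentration_pct = key$concentration_pct,
               temperature_C = key$temperature_C, h = h,
               flag = if (h < 0) "negative_h" else "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  hydration_table(out)
}

#' Construct a hydration table
#'
#' @param entries data.frame with columns `solute`, `concentration_pct`,
#'   `temperature_C`, `h` and optionally `flag`.
#' @param interpolation lookup policy used by [predict_ice_curve()]:
#'   `"nearest"` (default), `"linear-in-T"` or `"bilinear"`.
#' @return A `hydration_table` data.frame.
#' @export
hydration_table <- function(entries,
                            interpolation = c("nearest", "linear-in-T",
                                              "bilinear")) {
  interpolation <- match.arg(interpolation)
  need <- c("solute", "concentration_pct", "temperature_C", "h")
  missing <- setdiff(need, names(entries))
  if (length(missing))
    validation_error(paste0("hydration table is missing columns: ",
                            paste(missing, collapse = ", ")))
  if (is.null(entries$flag)) entries$flag <- ""
  key <- paste(entries$solute, entries$concentration_pct,
               entries$temperature_C)
  if (anyDuplicated(key))
    validation_error("hydration table has duplicate (solute, c, T) keys")
  structure(entries, class = c("hydration_table", "data.frame"),
            interpolation = interpolation)
}

# Internal: look up h for one (solute, c, T) under the table's policy.
# Flagged (negative-h) cells are excluded. Errors outside the table hull
# unless extrapolate = TRUE.
hydration_lookup <- function(table, solute, concentration_pct, temperature_C,
                             policy = attr(table, "interpolation"),
                             extrapolate = FALSE) {
  cells <- table[table$solute == solute & table$flag == "", , drop = FALSE]
  if (!nrow(cells))
    validation_error(paste0("no usable hydration cells for solute: ", solute))
  in_T <- temperature_C >= min(cells$temperature_C) &
    temperature_C <= max(cells$temperature_C)
  in_c <- concentration_pct >= min(cells$concentration_pct) &
    concentration_pct <= max(cells$concentration_pct)
  if (!extrapolate && (!in_T || !in_c))
    validation_error(sprintf(
      "(%s, %.3g %%, %.3g degC) lies outside the hydration table hull; set extrapolate = TRUE to override",
      solute, concentration_pct, temperature_C))
  if (policy == "nearest") {
    dc <- abs(cells$concentration_pct - concentration_pct)
    sub <- cells[dc == min(dc), , drop = FALSE]
    sub$h[which.min(abs(sub$temperature_C - temperature_C))]
  } else if (policy == "linear-in-T") {
    dc <- abs(cells$concentration_pct - concentration_pct)
    sub <- cells[dc == min(dc), , drop = FALSE]
    interp_h_in_T(sub, temperature_C)
  } else { # bilinear: linear in T at the two bracketing concentrations
    cs <- sort(unique(cells$concentration_pct))
    lo <- max(cs[cs <= concentration_pct], cs[1])
    hi <- min(cs[cs >= concentration_pct], cs[length(cs)])
    h_lo <- interp_h_in_T(cells[cells$concentration_pct == lo, ], temperature_C)
    if (hi == lo) return(h_lo)
    h_hi <- interp_h_in_T(cells[cells$concentration_pct == hi, ], temperature_C)
    h_lo + (h_hi - h_lo) * (concentration_pct - lo) / (hi - lo)
  }
}

interp_h_in_T <- function(cells, temperature_C) {
  if (nrow(cells) == 1L) return(cells$h)
  stats::approx(cells$temperature_C, cells$h, xout = temperature_C,
                rule = 2)$y
}

#' Predict an ice curve from a fitted hydration table
#'
#' Looks up the effective hydration number for each requested temperature
#' under the table's interpolation policy, then evaluates the forward
#' ice-content model. Requests outside the table's temperature or
#' concentration hull raise an error unless `extrapolate = TRUE`, in which
#' case the nearest cell values are carried outward.
#'
#' @param comp a [solution()] (each solute must appear in `table`).
#' @param table a [hydration_table()].
#' @param temperature_C temperatures to evaluate, degC.
#' @param extrapolate allow lookups outside the table hull.
#' @param constants see [thermo_constants()].
#' @return An `ice_curve` data.frame (see [ice_content()]) with an
#'   additional `h` column recording the hydration number used at each
#'   temperature (per solute, columns `h` or `h_<name>` for mixtures).
#' @export
predict_ice_curve <- function(comp, table, temperature_C,
                              extrapolate = FALSE,
                              constants = thermo_constants()) {
  check_solution(comp)
  if (!inherits(table, "hydration_table"))
    validation_error("expected a hydration_table")
  nm <- solute_names(comp)
  rows <- lapply(seq_along(temperature_C), function(j) {
    h <- vapply(seq_along(nm), function(i)
      hydration_lookup(table, nm[i], comp$mass_pct[i], temperature_C[j],
                       extrapolate = extrapolate), numeric(1))
    pt <- ice_content(comp, h, temperature_C[j], constants)
    cbind(pt, stats::setNames(as.data.frame(t(h)),
                              if (length(nm) == 1L) "h" else paste0("h_", nm)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ice_curve", "data.frame")
  out
}
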