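#' @name cryocurve_io
#' @title CSV readers and writers
#'
#' @description
#' All tabular interchange uses UTF-8 comma-separated files with a '.'
#' decimal separator and a mandatory header row. Scalar metadata (sample
#' mass, probe diameter, ...) travels in leading comment lines of the form
#' `#key=value`, which the readers parse and the base CSV machinery
#' ignores. Every writer's output is accepted by its reader bit-identically
#' (round-trip property).
#'
#' Schemas:
#' \itemize{
#'   \item ice dataset: `solute, concentration_pct, temperature_C,
#'     replicate, ice_pct[, flag]`
#'   \item ice curve: `solute, concentration_pct, temperature_C, ice_pct,
#'     valid`
#'   \item hydration table: `solute, concentration_pct, temperature_C, h,
#'     flag`
#'   \item melting curve: `time_s, drip_mass_g, core_temp_C` +
#'     `#initial_mass_g=`
#'   \item penetration: `displacement_mm, force_N` + `#probe_diameter_mm=`
#'   \item DSC trace: `time_s, temp_C, heat_flow` + `#sample_mass_mg=`,
#'     `#anneal_temp_C=`, `#sign_convention=`
#' }
NULL

read_keyed_csv <- function(path, required) {
  if (!file.exists(path)) validation_error(paste0("file not found: ", path))
  lines <- readLines(path, n = 50L)
  keyed <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in keyed) {
    kv <- strsplit(sub("^#", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    validation_error(paste0(path, " is missing columns: ",
                            paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(paste0(path, ": ignoring unknown columns: ",
                   paste(extra, collapse = ", ")), call. = FALSE)
  list(data = df[required], meta = meta)
}

write_keyed_csv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("#%s=%s", k, meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an ice-content dataset CSV
#' @param path CSV path.
#' @return `read_ice_dataset`: a validated ice-content data.frame.
#' @rdname ice_dataset_io
#' @export
read_ice_dataset <- function(path) {
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (is.null(raw$replicate)) raw$replicate <- 1L
  if (is.null(raw$flag)) raw$flag <- ""
  raw$flag[is.na(raw$flag)] <- ""
  as_ice_dataset(raw)
}

#' @param data ice-content data.frame.
#' @rdname ice_dataset_io
#' @export
write_ice_dataset <- function(data, path) {
  data <- as_ice_dataset(data)
  if (is.null(data$flag)) data$flag <- ""
  cols <- c("solute", "concentration_pct", "temperature_C", "replicate",
            "ice_pct", "flag")
  write_keyed_csv(data[cols], path)
}

#' Read / write a hydration table CSV
#' @param path CSV path.
#' @return `read_hydration_table`: a [hydration_table()].
#' @rdname hydration_table_io
#' @export
read_hydration_table <- function(path) {
  x <- read_keyed_csv(path, c("solute", "concentration_pct",
                              "temperature_C", "h", "flag"))
  x$data$flag[is.na(x$data$flag)] <- ""
  policy <- x$meta$interpolation
  hydration_table(x$data,
                  interpolation = if (is.null(policy)) "nearest" else policy)
}

#' @param table a [hydration_table()].
#' @rdname hydration_table_io
#' @export
write_hydration_table <- function(table, path) {
  write_keyed_csv(as.data.frame(table), path,
                  meta = list(interpolation = attr(table, "interpolation")))
}

#' Read / write an ice-curve CSV
#' @param path CSV path.
#' @return `read_ice_curve`: a data.frame with columns `solute`,
#'   `concentration_pct`, `temperature_C`, `ice_pct`, `valid`.
#' @rdname ice_curve_io
#' @export
read_ice_curve <- function(path) {
  read_keyed_csv(path, c("solute", "concentration_pct", "temperature_C",
                         "ice_pct", "valid"))$data
}

#' @param curve ice-curve data.frame (as returned by [read_ice_curve()]).
#' @rdname ice_curve_io
#' @export
write_ice_curve <- function(curve, path) {
  write_keyed_csv(curve, path)
}

#' Read / write a melting-curve CSV
#' @param path CSV path.
#' @return `read_melting_curve`: a [melting_curve()].
#' @rdname melting_curve_io
#' @export
read_melting_curve <- function(path) {
  x <- read_keyed_csv(path, c("time_s", "drip_mass_g", "core_temp_C"))
  if (is.null(x$meta$initial_mass_g))
    validation_error(paste0(path, " is missing the #initial_mass_g= header"))
  melting_curve(x$data$time_s, x$data$drip_mass_g, x$data$core_temp_C,
                as.numeric(x$meta$initial_mass_g))
}

#' @param curve a [melting_curve()].
#' @rdname melting_curve_io
#' @export
write_melting_curve <- function(curve, path) {
  write_keyed_csv(as.data.frame(curve), path,
                  meta = list(initial_mass_g =
                                format(attr(curve, "initial_mass_g"))))
}

#' Read / write a penetration-trace CSV
#' @param path CSV path.
#' @return `read_penetration`: a [penetration_trace()].
#' @rdname penetration_io
#' @export
read_penetration <- function(path) {
  x <- read_keyed_csv(path, c("displacement_mm", "force_N"))
  d <- x$meta$probe_diameter_mm
  penetration_trace(x$data$displacement_mm, x$data$force_N,
                    probe_diameter_mm = if (is.null(d)) 4 else as.numeric(d))
}

#' @param trace a [penetration_trace()].
#' @rdname penetration_io
#' @export
write_penetration <- function(trace, path) {
  write_keyed_csv(as.data.frame(trace), path,
                  meta = list(probe_diameter_mm =
                                format(attr(trace, "probe_diameter_mm"))))
}

#' Read / write a DSC trace CSV
#' @param path CSV path.
#' @return `read_dsc_trace`: a [dsc_trace()].
#' @rdname dsc_trace_io
#' @export
read_dsc_trace <- function(path) {
  x <- read_keyed_csv(path, c("time_s", "temp_C", "heat_flow"))
  m <- x$meta
  get_num <- function(k) {
    v <- m[[k]]
    if (is.null(v) || v %in% c("NA", "NaN", "")) NA_real_ else as.numeric(v)
  }
  dsc_trace(x$data$time_s, x$data$temp_C, x$data$heat_flow,
            sample_mass_mg = get_num("sample_mass_mg"),
            annealing_temp_C = get_num("anneal_temp_C"),
            sign_convention = if (is.null(m$sign_convention)) "endo_up"
                              else m$sign_convention)
}

#' @param trace a [dsc_trace()].
#' @rdname dsc_trace_io
#' @export
write_dsc_trace <- function(trace, path) {
  write_keyed_csv(as.data.frame(trace), path,
                  meta = list(
                    sample_mass_mg = format(attr(trace, "sample_mass_mg")),
                    anneal_temp_C = format(attr(trace, "annealing_temp_C")),
                    sign_convention = attr(trace, "sign_convention")))
}
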