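#' Process stream
#'
#' A stream is a temperature, a pressure, and one mass flow per registry
#' component.  Components not named in `flows` are set to zero, so streams
#' from different parts of the flowsheet can always be combined
#' component-wise.
#'
#' @param temperature Temperature, degC.
#' @param pressure Pressure, bar (the plant runs at 1.01 bar everywhere
#'   except inside the homogenizer; pressure is carried but never drives
#'   the thermodynamics).
#' @param flows Named numeric vector of mass flows, kg/h; names must be
#'   registry components and values non-negative.
#' @return An object of class `process_stream`.
#' @export
#' @examples
#' process_stream(25, flows = c(water = 209.85, protein = 25.03))
process_stream <- function(temperature, pressure = 1.01, flows = numeric()) {
  comps <- component_names()
  full <- stats::setNames(numeric(length(comps)), comps)
  if (length(flows)) {
    if (is.null(names(flows)) || any(!nzchar(names(flows))))
      stop("'flows' must be a named vector")
    bad <- setdiff(names(flows), comps)
    if (length(bad))
      stop("unknown component(s): ", paste(bad, collapse = ", "))
    if (any(flows < 0))
      stop("mass flows must be non-negative")
    full[names(flows)] <- as.numeric(flows)
  }
  structure(
    list(temperature = as.numeric(temperature),
         pressure = as.numeric(pressure),
         flows = full),
    class = "process_stream"
  )
}

#' @export
print.process_stream <- function(x, ...) {
  cat(sprintf("<process_stream> %.2f kg/h at %.2f degC, %.2f bar\n",
              stream_total(x), x$temperature, x$pressure))
  nz <- x$flows[x$flows > 0]
  if (length(nz)) {
    for (nm in names(nz)) cat(sprintf("  %-14s %10.4f kg/h\n", nm, nz[nm]))
  } else {
    cat("  (no flow)\n")
  }
  invisible(x)
}

#' Total mass flow of a stream
#' @param stream A [process_stream()].
#' @return Total flow, kg/h.
#' @export
stream_total <- function(stream) {
  stopifnot(inherits(stream, "process_stream"))
  sum(stream$flows)
}

#' Mass fraction of one component in a stream
#'
#' @param stream A [process_stream()].
#' @param component A registry component name.
#' @return A list with `total` (kg/h) and `fraction` (component flow over
#'   total flow).
#' @export
#' @examples
#' s <- process_stream(50, flows = c(water = 194.03, amino_acids = 12.48))
#' stream_fraction(s, "amino_acids")
stream_fraction <- function(stream, component) {
  stopifnot(inherits(stream, "process_stream"))
  if (!component %in% component_names())
    stop("unknown component: ", component)
  total <- stream_total(stream)
  if (total <= 0)
    stop("mass fraction undefined: stream has zero total flow")
  list(total = total, fraction = stream$flows[[component]] / total)
}

#' Mix streams adiabatically
#'
#' Flows add component-wise; the outlet temperature is the m*cp-weighted
#' mean of the inlet temperatures (constant-cp enthalpy balance), so mixing
#' conserves both mass and sensible heat exactly.  All inlets must share a
#' common pressure.
#'
#' @param streams A list of [process_stream()] objects.
#' @param cpm A [cp_model()] supplying component heat capacities.
#' @return The mixed [process_stream()].
#' @export
#' @examples
#' a <- process_stream(40, flows = c(water = 100))
#' b <- process_stream(25, flows = c(water = 50))
#' mix_streams(list(a, b))$temperature  # 35 degC
mix_streams <- function(streams, cpm = cp_model()) {
  if (!is.list(streams) || length(streams) == 0)
    stop("'streams' must be a non-empty list of process streams")
  lapply(streams, function(s) {
    if (!inherits(s, "process_stream"))
      stop("all elements must be process_stream objects")
    if (any(s$flows < 0)) stop("negative mass flow in inlet stream")
  })
  p <- vapply(streams, function(s) s$pressure, numeric(1))
  if (diff(range(p)) > 1e-9)
    stop("streams must be at a common pressure to mix")

  flows <- Reduce(`+`, lapply(streams, function(s) s$flows))
  mcp <- vapply(streams, function(s)
    sum(s$flows * cpm$cp[names(s$flows)]), numeric(1))
  temp <- if (sum(mcp) > 0) {
    sum(mcp * vapply(streams, function(s) s$temperature, numeric(1))) /
      sum(mcp)
  } else {
    streams[[1]]$temperature
  }
  process_stream(temp, p[1], flows)
}

#' Stream table as a data.frame
#'
#' Lays out a set of streams with one column per stream and one row per
#' quantity (temperature, pressure, total flow, then each component flow),
#' the conventional flowsheet stream-table layout.
#'
#' @param streams Named list of [process_stream()] objects.
#' @return A data.frame; row names identify the quantity.
#' @export
stream_table <- function(streams) {
  stopifnot(is.list(streams), length(streams) > 0)
  if (is.null(names(streams)))
    names(streams) <- paste0("S", seq_along(streams))
  comps <- component_names()
  mat <- vapply(streams, function(s) {
    c(s$temperature, s$pressure, stream_total(s), s$flows[comps])
  }, numeric(3 + length(comps)))
  df <- as.data.frame(mat)
  rownames(df) <- c("temperature_C", "pressure_bar", "total_kg_h",
                    paste0(comps, "_kg_h"))
  df
}

#' Write a stream table to CSV or JSON
#'
#' @param streams Named list of [process_stream()] objects.
#' @param path Output file path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return Invisibly, the data.frame written.
#' @export
write_stream_table <- function(streams, path) {
  df <- stream_table(streams)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(cbind(quantity = rownames(df), df), path,
                     row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(
      lapply(as.list(df), stats::setNames, rownames(df)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported extension: ", ext)
  }
  invisible(df)
}
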