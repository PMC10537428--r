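# Domain types and delimited-text I/O for breakthrough curves.
#
# Unit canon used throughout the package: time in min, volume in mL, mass of
# protein in mg, mass of adsorbent in g, lengths in cm internally.  Bed height
# is accepted in micrometres at the boundary (the natural unit for nanofiber
# membrane stacks) and converted.

UM_PER_CM <- 1e4

#' Bed specification for a membrane (or fixed) adsorber bed
#'
#' Captures the geometry and packing of the adsorber bed.  The bed volume
#' `V_M` is derived as frontal area times height; `W` is the mass of the
#' *adsorptive* material only (inert support fabric is excluded, since all
#' capacities are expressed per gram of functional adsorbent).
#'
#' @param Z bed height, micrometres (> 0).
#' @param A frontal (effective filtration) area, cm^2 (> 0).
#' @param epsilon bed porosity, fraction in (0, 1].
#' @param W adsorptive membrane mass, grams (> 0).
#' @param layers number of stacked membrane layers (positive integer).
#'
#' @return An object of class `bed_spec`: a list with fields `Z` (um), `A`
#'   (cm^2), `epsilon`, `W` (g), `layers`, and the derived bed volume `V_M`
#'   (mL).
#' @examples
#' bed <- bed_spec(Z = 115, A = 3.7, epsilon = 0.8367, W = 0.015)
#' bed$V_M  # 0.04255 mL
#' @export
bed_spec <- function(Z, A, epsilon, W, layers = 1L) {
  stopifnot(is.numeric(Z), length(Z) == 1L, is.finite(Z), Z > 0)
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A), A > 0)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon > 0, epsilon <= 1)
  stopifnot(is.numeric(W), length(W) == 1L, is.finite(W), W > 0)
  layers <- as.integer(layers)
  stopifnot(length(layers) == 1L, !is.na(layers), layers >= 1L)
  structure(
    list(Z = Z, A = A, epsilon = epsilon, W = W, layers = layers,
         V_M = A * (Z / UM_PER_CM)),
    class = "bed_spec"
  )
}

#' Scale a bed to a different number of stacked layers
#'
#' Height and adsorptive mass scale proportionally with the layer count;
#' area and porosity are unchanged.
#'
#' @param bed a [bed_spec()].
#' @param layers new layer count.
#' @return a new `bed_spec`.
#' @export
scale_layers <- function(bed, layers) {
  stopifnot(inherits(bed, "bed_spec"))
  layers <- as.integer(layers)
  f <- layers / bed$layers
  bed_spec(Z = bed$Z * f, A = bed$A, epsilon = bed$epsilon,
           W = bed$W * f, layers = layers)
}

#' @export
print.bed_spec <- function(x, ...) {
  cat(sprintf(
    "Membrane bed: Z = %g um (%d layer%s), A = %g cm^2, eps = %.4f, W = %g g, V_M = %g mL\n",
    x$Z, x$layers, if (x$layers > 1L) "s" else "", x$A, x$epsilon, x$W, x$V_M))
  invisible(x)
}

#' Construct a breakthrough curve
#'
#' A breakthrough curve records the normalized outlet concentration
#' C_t/C_0 of a bed fed at constant inlet concentration `C0`, as a
#' function of time.  Samples are sorted by time; duplicate time points are
#' rejected.  `c_ratio` values slightly above 1 (up to 1.05) are tolerated
#' with a warning as detector overshoot; larger values are an error.
#'
#' @param t sample times, min (strictly increasing after sorting, `t[1] >= 0`).
#' @param c_ratio outlet/inlet concentration ratio, each >= 0.
#' @param C0 inlet concentration, mg/mL (> 0).
#' @param F_mL flow rate, mL/min (> 0).
#' @param bed a [bed_spec()].
#' @param label free-text condition tag (e.g. `"pH 9"`).
#'
#' @return An object of class `breakthrough_curve`.
#' @export
breakthrough_curve <- function(t, c_ratio, C0, F_mL, bed, label = "") {
  stopifnot(is.numeric(t), is.numeric(c_ratio), length(t) == length(c_ratio))
  stopifnot(inherits(bed, "bed_spec"))
  stopifnot(is.numeric(C0), length(C0) == 1L, C0 > 0)
  stopifnot(is.numeric(F_mL), length(F_mL) == 1L, F_mL > 0)
  if (length(t) < 4L)
    stop("a breakthrough curve needs at least 4 samples, got ", length(t))
  ord <- order(t)
  t <- t[ord]; c_ratio <- c_ratio[ord]
  if (anyDuplicated(t))
    stop("duplicate time points in breakthrough curve")
  if (t[1L] < 0) stop("negative sample times are not allowed")
  if (any(!is.finite(c_ratio)) || any(c_ratio < 0))
    stop("c_ratio values must be finite and >= 0")
  over <- c_ratio > 1.05
  if (any(over))
    stop(sum(over), " c_ratio value(s) exceed the 1.05 overshoot tolerance ",
         "(max = ", format(max(c_ratio)), ")")
  n_over1 <- sum(c_ratio > 1)
  if (n_over1 > 0L)
    warning(n_over1, " c_ratio value(s) in (1, 1.05] retained as detector overshoot")
  structure(
    list(t = t, c_ratio = c_ratio, C0 = C0, F = F_mL, bed = bed,
         label = as.character(label)),
    class = "breakthrough_curve"
  )
}

#' @export
print.breakthrough_curve <- function(x, ...) {
  cat(sprintf(
    "Breakthrough curve%s: %d samples on [%g, %g] min, C0 = %g mg/mL, F = %g mL/min\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    length(x$t), min(x$t), max(x$t), x$C0, x$F))
  print(x$bed)
  invisible(x)
}

# Fields an experiment descriptor must supply.
.descriptor_required <- c("C0", "F", "Z", "A", "epsilon", "W")

#' Build a bed + operating descriptor into its components
#' @noRd
.descriptor_to_parts <- function(descriptor) {
  missing_f <- setdiff(.descriptor_required, names(descriptor))
  if (length(missing_f))
    stop("descriptor is missing required field(s): ",
         paste(missing_f, collapse = ", "))
  num <- function(k) {
    v <- suppressWarnings(as.numeric(descriptor[[k]]))
    if (is.na(v)) stop("descriptor field '", k, "' is not numeric")
    v
  }
  bed <- bed_spec(Z = num("Z"), A = num("A"), epsilon = num("epsilon"),
                  W = num("W"),
                  layers = if ("layers" %in% names(descriptor))
                    num("layers") else 1L)
  list(C0 = num("C0"), F = num("F"), bed = bed,
       label = if ("label" %in% names(descriptor))
         as.character(descriptor[["label"]]) else "")
}

#' Read a breakthrough curve from delimited text
#'
#' The file must contain two numeric columns, time (min) and `c_ratio`,
#' separated by commas, tabs or whitespace; a single header line is
#' detected and skipped.  Operating conditions come from `descriptor`, a
#' named list/vector with fields `C0`, `F`, `Z`, `A`, `epsilon`, `W` and
#' optionally `layers` and `label` (this is also the format produced by
#' [read_descriptor()]).
#'
#' @param path path to the delimited curve file.
#' @param descriptor named list or vector of operating fields (see above).
#' @return a [breakthrough_curve()].
#' @export
read_curve <- function(path, descriptor) {
  if (!file.exists(path)) stop("curve file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("curve file is empty: ", path)
  sep <- if (grepl(",", lines[[1L]])) "," else ""
  first <- strsplit(trimws(lines[[1L]]), if (sep == ",") "," else "[ \t]+")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  df <- utils::read.table(text = lines, sep = sep, header = has_header,
                          strip.white = TRUE)
  if (ncol(df) < 2L)
    stop("curve file must have two columns (time, c_ratio); found ", ncol(df))
  tcol <- df[[1L]]; ccol <- df[[2L]]
  if (!is.numeric(tcol) || !is.numeric(ccol))
    stop("curve file columns must be numeric")
  parts <- .descriptor_to_parts(descriptor)
  breakthrough_curve(t = tcol, c_ratio = ccol, C0 = parts$C0,
                     F_mL = parts$F, bed = parts$bed, label = parts$label)
}

#' Write a breakthrough curve (and optionally its descriptor) to text
#'
#' The curve is written as a two-column CSV (`t_min,c_ratio`) at full double
#' precision so that a read/write round trip is lossless to <= 1e-9 relative.
#'
#' @param curve a [breakthrough_curve()].
#' @param path output CSV path.
#' @param descriptor_path if non-`NULL`, also write the operating descriptor
#'   as a flat `key = value` file readable by [read_descriptor()].
#' @return invisibly, `path`.
#' @export
write_curve <- function(curve, path, descriptor_path = NULL) {
  stopifnot(inherits(curve, "breakthrough_curve"))
  df <- data.frame(t_min = curve$t, c_ratio = curve$c_ratio)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     file = path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(descriptor_path)) {
    d <- c(C0 = curve$C0, F = curve$F, Z = curve$bed$Z, A = curve$bed$A,
           epsilon = curve$bed$epsilon, W = curve$bed$W,
           layers = curve$bed$layers)
    write_descriptor(c(as.list(d), list(label = curve$label)), descriptor_path)
  }
  invisible(path)
}

#' Read a flat key = value descriptor/config file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and lines
#' starting with `#` are ignored.  Values are kept as character; numeric
#' coercion is done by consumers.
#'
#' @param path path to the descriptor file.
#' @return named list of character values.
#' @export
read_descriptor <- function(path) {
  if (!file.exists(path)) stop("descriptor file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed descriptor line: ", ln)
    out[[trimws(m[[2L]])]] <- trimws(m[[3L]])
  }
  out
}

#' Write a flat key = value descriptor/config file
#' @param x named list of scalar values.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_descriptor <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  vals <- vapply(x, function(v)
    if (is.numeric(v)) format(v, digits = 17) else as.character(v), "")
  writeLines(paste(names(x), "=", vals), path, useBytes = TRUE)
  invisible(path)
}

# Column order mirrors the conventional indicator-table layout.
.indicator_cols <- c("Z_um", "label", "C0_mg_mL", "F_mL_min",
                     "t_b_min", "t_e_min", "HMTZ_um", "V_b_mL", "BV",
                     "MAER_g_mL", "DBC_mg_g", "EBC_mg_g", "MBU_pct",
                     "P_mg_min_g")

#' Write a performance-indicator table
#'
#' One row per experiment with explicit unit-bearing column names, in the
#' order: bed height, condition label, inlet concentration, flow rate, 10%
#' and 90% breakthrough times, mass-transfer-zone length, loaded volume,
#' bed volumes, exhaustion rate, dynamic and equilibrium binding capacity,
#' bed utilization and productivity.
#'
#' @param indicators a non-empty list of [performance_indicators()] results.
#' @param path output path (CSV, UTF-8).
#' @return invisibly, the written `data.frame`.
#' @export
write_indicator_table <- function(indicators, path) {
  if (!length(indicators)) stop("indicator list is empty")
  if (inherits(indicators, "performance_indicators"))
    indicators <- list(indicators)
  rows <- lapply(indicators, function(ind) {
    stopifnot(inherits(ind, "performance_indicators"))
    data.frame(Z_um = ind$Z, label = ind$label, C0_mg_mL = ind$C0,
               F_mL_min = ind$F, t_b_min = ind$t_b, t_e_min = ind$t_e,
               HMTZ_um = ind$HMTZ, V_b_mL = ind$V_b, BV = ind$BV,
               MAER_g_mL = ind$MAER, DBC_mg_g = ind$DBC, EBC_mg_g = ind$EBC,
               MBU_pct = ind$MBU, P_mg_min_g = ind$P,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  stopifnot(identical(names(df), .indicator_cols))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(df)
}
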