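# Plain-text instrument I/O. All trace files are CSV with a block of
# '# key=value' header lines carrying the scalar metadata, then a header row
# and numeric columns. Readers are strict about required keys and name the
# offending file in every error.

.read_keyed_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- trimws(substr(kv, 1, eq - 1))
      meta[[key]] <- trimws(substr(kv, eq + 1, nchar(kv)))
    }
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2) stop_invalid("no data rows in ", path)
  df <- tryCatch(utils::read.csv(text = paste(body, collapse = "\n"),
                                 check.names = FALSE),
                 error = function(e)
                   stop_invalid("malformed CSV in ", path, ": ", conditionMessage(e)))
  list(meta = meta, data = df)
}

.meta_num <- function(meta, key, path, default = NULL) {
  if (is.null(meta[[key]])) {
    if (!is.null(default)) return(default)
    stop_invalid("missing '# ", key, "=' header in ", path)
  }
  as.numeric(meta[[key]])
}

.write_keyed_csv <- function(path, meta, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta))
    writeLines(sprintf("# %s=%s", key, format(meta[[key]], digits = 15)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DLS correlogram from CSV
#'
#' Expects `# q=<value>` (1/m) and `# temperature_C=<value>` headers and
#' columns `delay_s,g2_minus_1`, or `delay_s,g2` with `baseline =
#' "subtract"`, in which case the long-delay plateau (median of the last
#' 10% of points) is subtracted to recover \eqn{g_2 - 1}.
#'
#' @param path CSV file path.
#' @param baseline `"none"` (default, column already baseline-free) or
#'   `"subtract"`.
#' @return A [correlogram()].
#' @export
read_correlogram_csv <- function(path, baseline = c("none", "subtract")) {
  baseline <- match.arg(baseline)
  x <- .read_keyed_csv(path)
  q <- .meta_num(x$meta, "q", path)
  temp <- .meta_num(x$meta, "temperature_C", path)
  col <- if ("g2_minus_1" %in% names(x$data)) "g2_minus_1"
         else if ("g2" %in% names(x$data)) "g2"
         else stop_invalid("no g2_minus_1 or g2 column in ", path)
  y <- x$data[[col]]
  if (baseline == "subtract" || col == "g2") {
    n <- length(y)
    plateau <- stats::median(y[max(1, floor(0.9 * n)):n])
    y <- y - plateau
  }
  correlogram(x$data$delay_s, y, q, temp,
              label = if (!is.null(x$meta$label)) x$meta$label else basename(path))
}

#' Write a DLS correlogram to CSV
#' @param trace a [correlogram()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_correlogram_csv <- function(trace, path) {
  stopifnot(inherits(trace, "correlogram"))
  .write_keyed_csv(path,
                   list(q = trace$q, temperature_C = trace$temperature_C,
                        label = trace$label),
                   data.frame(delay_s = trace$delay_s,
                              g2_minus_1 = trace$g2_minus_1))
}

#' Read a SAXS profile from CSV
#'
#' Columns `q_invnm,intensity[,sigma]`; optional `# temperature_C=` header.
#' Set `q_unit = "invA"` when the file stores q in 1/Angstrom.
#'
#' @param path CSV file path.
#' @param q_unit `"invnm"` (default) or `"invA"`.
#' @return A [saxs_profile()].
#' @export
read_saxs_csv <- function(path, q_unit = c("invnm", "invA")) {
  q_unit <- match.arg(q_unit)
  x <- .read_keyed_csv(path)
  q <- x$data$q_invnm
  if (is.null(q)) q <- x$data$q
  if (is.null(q)) stop_invalid("no q_invnm column in ", path)
  if (q_unit == "invA") q <- q * 10
  saxs_profile(q, x$data$intensity, sigma = x$data$sigma,
               temperature_C = .meta_num(x$meta, "temperature_C", path, NA_real_),
               label = if (!is.null(x$meta$label)) x$meta$label else basename(path))
}

#' Write a SAXS profile to CSV
#' @param profile a [saxs_profile()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_saxs_csv <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  df <- data.frame(q_invnm = profile$q_invnm, intensity = profile$intensity)
  if (!is.null(profile$sigma)) df$sigma <- profile$sigma
  .write_keyed_csv(path, list(temperature_C = profile$temperature_C,
                              label = profile$label), df)
}

#' Read a DSC trace from CSV
#'
#' Columns `temperature_C,heat_flow_W_per_g` with `# scan_rate_C_per_min=`,
#' `# direction=` and `# exo_sign=` headers. `exo_sign` records the vendor
#' convention: `up` (exotherms positive, default) or `down` (flipped on
#' read so exotherms are stored positive).
#'
#' @param path CSV file path.
#' @return A [dsc_trace()].
#' @export
read_dsc_csv <- function(path) {
  x <- .read_keyed_csv(path)
  rate <- .meta_num(x$meta, "scan_rate_C_per_min", path)
  direction <- if (!is.null(x$meta$direction)) x$meta$direction else "cooling"
  sgn <- if (identical(x$meta$exo_sign, "down")) -1 else 1
  dsc_trace(x$data$temperature_C, sgn * x$data$heat_flow_W_per_g, rate,
            direction = direction,
            label = if (!is.null(x$meta$label)) x$meta$label else basename(path))
}

#' Write a DSC trace to CSV
#' @param trace a [dsc_trace()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dsc_csv <- function(trace, path) {
  stopifnot(inherits(trace, "dsc_trace"))
  .write_keyed_csv(path,
                   list(scan_rate_C_per_min = trace$scan_rate_C_per_min,
                        direction = trace$direction, exo_sign = "up",
                        label = trace$label),
                   data.frame(temperature_C = trace$temperature_C,
                              heat_flow_W_per_g = trace$heat_flow_W_per_g))
}

#' Read a viscosity curve from CSV
#'
#' Columns `temperature_C,eta_mPas` with a `# shear_rate_per_s=` header.
#'
#' @param path CSV file path.
#' @return A [viscosity_curve()].
#' @export
read_viscosity_csv <- function(path) {
  x <- .read_keyed_csv(path)
  viscosity_curve(x$data$temperature_C, x$data$eta_mPas,
                  shear_rate_per_s = .meta_num(x$meta, "shear_rate_per_s", path, NA_real_),
                  label = if (!is.null(x$meta$label)) x$meta$label else basename(path))
}

#' Write a viscosity curve to CSV
#' @param curve a [viscosity_curve()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_viscosity_csv <- function(curve, path) {
  stopifnot(inherits(curve, "viscosity_curve"))
  .write_keyed_csv(path,
                   list(shear_rate_per_s = curve$shear_rate_per_s,
                        label = curve$label),
                   data.frame(temperature_C = curve$temperature_C,
                              eta_mPas = curve$eta_mPas))
}

#' Read a TCSPC decay histogram from CSV
#'
#' Columns `time_ns,counts[,irf_counts]` with `# temperature_C=` (and
#' optionally `# rep_rate_MHz=`) headers.
#'
#' @param path CSV file path.
#' @return A [decay_histogram()].
#' @export
read_decay_csv <- function(path) {
  x <- .read_keyed_csv(path)
  decay_histogram(x$data$time_ns, x$data$counts,
                  irf_counts = x$data$irf_counts,
                  temperature_C = .meta_num(x$meta, "temperature_C", path, NA_real_),
                  label = if (!is.null(x$meta$label)) x$meta$label else basename(path))
}

#' Write a TCSPC decay histogram to CSV
#' @param hist a [decay_histogram()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_decay_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- data.frame(time_ns = hist$time_ns, counts = hist$counts)
  if (!is.null(hist$irf_counts)) df$irf_counts <- hist$irf_counts
  .write_keyed_csv(path, list(temperature_C = hist$temperature_C,
                              label = hist$label), df)
}

#' Read Forster-Hoffman calibration pairs from CSV
#'
#' Columns `tau_ns,eta_cP` with an optional `# temperature_C=` header.
#'
#' @param path CSV file path.
#' @return A data.frame with columns `tau_ns`, `eta_cP` and attribute
#'   `temperature_C`.
#' @export
read_calibration_csv <- function(path) {
  x <- .read_keyed_csv(path)
  if (is.null(x$data$tau_ns) || is.null(x$data$eta_cP))
    stop_invalid("need tau_ns and eta_cP columns in ", path)
  out <- data.frame(tau_ns = x$data$tau_ns, eta_cP = x$data$eta_cP)
  attr(out, "temperature_C") <- .meta_num(x$meta, "temperature_C", path, NA_real_)
  out
}
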