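# Respirometry: CO2 evolution rate (CER) from effluent CO2 fraction and
# flow series, and its time integral (cCER), normalized to dry matter.

#' Assemble and validate a respirometry trace
#'
#' @param time Hours, strictly increasing, length >= 2.
#' @param co2_fraction Effluent CO2 volume fraction in `[0, 1]`.
#' @param flow Effluent flow in L min^-1, non-negative.
#' @param dry_mass Dry matter in the reactor, g (> 0); stored as an
#'   attribute on the returned tibble.
#' @param co2_baseline Optional inlet CO2 fraction to subtract, same length
#'   or scalar; default 0.
#' @return Tibble with columns `time`, `co2_fraction`, `flow` (and
#'   `co2_baseline` when given), attribute `dry_mass_g`.
#' @export
resp_trace <- function(time, co2_fraction, flow, dry_mass, co2_baseline = NULL) {
  n <- length(time)
  stopifnot(n >= 2, length(co2_fraction) == n, length(flow) == n)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(co2_fraction < 0 | co2_fraction > 1)) {
    stop("co2_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(flow < 0)) stop("flow must be non-negative", call. = FALSE)
  if (!is.numeric(dry_mass) || length(dry_mass) != 1L || dry_mass <= 0) {
    stop("dry_mass must be a single positive number (g)", call. = FALSE)
  }
  out <- tibble::tibble(time = time, co2_fraction = co2_fraction, flow = flow)
  if (!is.null(co2_baseline)) {
    out$co2_baseline <- rep_len(co2_baseline, n)
  }
  attr(out, "dry_mass_g") <- dry_mass
  out
}

#' Read/write a respirometry trace TSV
#'
#' The dry mass travels in a `# dry_mass_g: <x>` comment line above the
#' header so one file is self-contained.
#'
#' @param path Trace TSV with columns `time`, `co2_fraction`, `flow` and
#'   optionally `co2_baseline`.
#' @return For `read_resp_trace`, a validated trace tibble (see
#'   [resp_trace()]).
#' @export
read_resp_trace <- function(path) {
  lines <- readr::read_lines(path, n_max = 10, progress = FALSE)
  m <- stringr::str_match(lines, "^#\\s*dry_mass_g:\\s*([0-9.eE+-]+)")[, 2]
  dry_mass <- suppressWarnings(as.numeric(m[!is.na(m)][1]))
  if (is.na(dry_mass)) {
    stop("trace file '", path, "' lacks a '# dry_mass_g:' header", call. = FALSE)
  }
  df <- read_tsv_quiet(path)
  check_columns(df, c("time", "co2_fraction", "flow"), "respirometry", path)
  resp_trace(df$time, df$co2_fraction, df$flow, dry_mass,
             co2_baseline = df[["co2_baseline"]])
}

#' @rdname read_resp_trace
#' @param trace Trace tibble from [resp_trace()].
#' @export
write_resp_trace <- function(trace, path) {
  dry_mass <- attr(trace, "dry_mass_g")
  readr::write_lines(sprintf("# dry_mass_g: %.6g", dry_mass), path)
  readr::write_tsv(trace, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' CO2 evolution rate from a respirometry trace
#'
#' CER(t) = flow x 60 x co2_fraction x (44.01 / Vm) x 1000 / dry_mass,
#' in mg CO2 g^-1 dry matter h^-1, with Vm the molar volume of the gas at
#' sensor conditions (L mol^-1). Any `co2_baseline` column is subtracted
#' from the fraction first (floored at zero).
#'
#' @param trace Trace tibble from [resp_trace()] or [read_resp_trace()].
#' @param molar_volume Gas molar volume in L mol^-1 (default 24.0, ambient).
#' @return The trace with an added `cer` column.
#' @export
compute_cer <- function(trace, molar_volume = 24.0) {
  dry_mass <- attr(trace, "dry_mass_g")
  if (is.null(dry_mass)) stop("trace lacks a dry_mass_g attribute", call. = FALSE)
  stopifnot(molar_volume > 0)
  frac <- trace$co2_fraction
  if (!is.null(trace[["co2_baseline"]])) {
    frac <- pmax(frac - trace$co2_baseline, 0)
  }
  trace$cer <- trace$flow * 60 * frac * (44.01 / molar_volume) * 1000 / dry_mass
  trace
}

#' Cumulative CO2 evolution (cCER) by trapezoidal integration
#'
#' Integrates CER over the time span; additive over contiguous segments and
#' non-decreasing in time when CER >= 0.
#'
#' @param time Hours, strictly increasing.
#' @param cer CER series, mg CO2 g^-1 h^-1.
#' @param cumulative Return the running integral instead of the total.
#' @return Total cCER in mg CO2 g^-1 dry matter, or the running series.
#' @export
integrate_ccer <- function(time, cer, cumulative = FALSE) {
  stopifnot(length(time) == length(cer))
  if (length(time) < 2L) {
    warning("fewer than two points; cCER is 0", call. = FALSE)
    return(if (cumulative) rep(0, length(time)) else 0)
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (cumulative) {
    as.numeric(pracma::cumtrapz(time, cer))
  } else {
    pracma::trapz(time, cer)
  }
}
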