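#' Flow-rate waveform over one cardiac period
#'
#' @param times sample times (s), strictly increasing, in `[0, T)`.
#' @param values flow rates (mL/s); mean must be positive.
#' @param T period (s).
#' @return object of class `waveform`.
#' @export
waveform <- function(times, values, T) {
  if (T <= 0) stop("period must be positive")
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] < 0 || times[length(times)] >= T)
    stop("times must lie in [0, T)")
  if (mean(values) <= 0) stop("mean flow must be positive")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 T = T),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> T=%.3g s, %d samples, mean Q %.3g mL/s\n",
              x$T, length(x$times), mean(x$values)))
  invisible(x)
}

#' Mean flow of a waveform (mL/s)
#' @param wf a `waveform`.
#' @return numeric scalar.
#' @export
mean_flow <- function(wf) mean(wf$values)

#' Scale a representative inflow waveform to a case inlet
#'
#' The normalized waveform shape is preserved; only the amplitude changes.
#' With `"match_mean_velocity"` (default) the output mean velocity
#' (mean flow / inlet area) equals the reference mean velocity
#' (reference mean flow / reference area). With `"flow_proportional_area"`
#' the mean flow is scaled proportionally to the inlet area relative to the
#' reference area. For these definitions both policies reduce to the same
#' linear scaling `Q * inlet_area / ref_area`; both names are kept because
#' configuration files refer to the policy by name.
#'
#' @param ref reference `waveform`.
#' @param inlet_area case inlet area (mm^2), > 0.
#' @param ref_area reference inlet area (mm^2), > 0.
#' @param policy scaling policy (see above).
#' @return scaled `waveform`.
#' @export
scale_inflow <- function(ref, inlet_area, ref_area,
                         policy = c("match_mean_velocity",
                                    "flow_proportional_area")) {
  policy <- match.arg(policy)
  if (inlet_area <= 0) stop("inlet area must be positive")
  if (ref_area <= 0) stop("reference area must be positive")
  k <- inlet_area / ref_area
  waveform(ref$times, ref$values * k, ref$T)
}

#' Outlet flow splitting (Murray / shape-based)
#'
#' `"murray"`: fractions proportional to the outlet equivalent diameter
#' raised to `exponent` (classical d^3 law by default), using the terminal
#' station of each outlet branch profile. `"shape_based"`: proportional to
#' the mean equivalent diameter over the whole distal branch profile raised
#' to `exponent` — the split reflects the averaged branch shape rather than
#' a single terminal cross-section, so local terminal tapering or bulging
#' does not dominate the ratio.
#'
#' @param outlet_profiles named list of `csa_profile` objects, one per
#'   outlet (the distal end of each profile is the outlet).
#' @param method `"murray"` or `"shape_based"`.
#' @param exponent diameter exponent (default 3; 2-3 sensible).
#' @return object of class `outlet_split`: list(ids, fractions, diameters,
#'   method, exponent); fractions sum to 1.
#' @export
outlet_split <- function(outlet_profiles,
                         method = c("murray", "shape_based"), exponent = 3) {
  method <- match.arg(method)
  if (length(outlet_profiles) < 2L) stop("need at least 2 outlets")
  if (any(vapply(outlet_profiles, function(p) length(p$d_eq) == 0L,
                 logical(1))))
    stop("empty outlet profile")
  d <- vapply(outlet_profiles, function(p) {
    switch(method,
           murray = p$d_eq[length(p$d_eq)],
           shape_based = mean(p$d_eq))
  }, numeric(1))
  split_from_diameters(d, names(outlet_profiles), method, exponent)
}

#' Outlet split directly from diameters
#' @param d numeric vector of outlet (equivalent) diameters (mm).
#' @param ids outlet labels (default names of `d` or indices).
#' @param method label stored in the result.
#' @param exponent diameter exponent.
#' @return `outlet_split`.
#' @export
split_from_diameters <- function(d, ids = NULL, method = "murray",
                                 exponent = 3) {
  if (all(d == 0)) stop("all outlet diameters are zero")
  if (any(d < 0)) stop("negative outlet diameter")
  ids <- ids %||% names(d) %||% as.character(seq_along(d))
  w <- d^exponent
  structure(list(ids = ids, fractions = setNames(w / sum(w), ids),
                 diameters = setNames(d, ids), method = method,
                 exponent = exponent),
            class = "outlet_split")
}

#' @export
print.outlet_split <- function(x, ...) {
  cat(sprintf("<outlet_split> %s (n=%g): %s\n", x$method, x$exponent,
              paste(sprintf("%s=%.4f", x$ids, x$fractions),
                    collapse = ", ")))
  invisible(x)
}

#' Read/write waveforms as CSV (t, Q)
#' @param path CSV path with columns `t` (s) and `Q` (mL/s).
#' @param T period; default the implied sample period
#'   `max(t) + median(diff(t))`.
#' @return a `waveform`.
#' @export
read_waveform <- function(path, T = NULL) {
  df <- read.csv(path)
  if (!all(c("t", "Q") %in% names(df))) stop("waveform CSV needs t,Q columns")
  T <- T %||% (max(df$t) + median(diff(df$t)))
  waveform(df$t, df$Q, T)
}

#' @rdname read_waveform
#' @param wf a `waveform`.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wf, path) {
  write.csv(data.frame(t = wf$times, Q = wf$values), path, row.names = FALSE)
  invisible(path)
}

#' Write an outlet split as JSON keyed by outlet id
#' @param split an `outlet_split`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(
    list(method = split$method, exponent = split$exponent,
         fractions = as.list(split$fractions)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
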