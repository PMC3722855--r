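#' Ramp-and-hold loading history
#'
#' A loading history is a tibble of sampled time (s) and engineering shear
#' strain (dimensionless, lateral displacement / specimen height) with the
#' ramp time and hold strain recorded as attributes. Use [make_loading()] to
#' build the canonical linear-ramp-then-hold signal; this constructor accepts
#' arbitrary sampled histories (e.g. measured actuator displacement divided
#' by height).
#'
#' @param time Sample times (s), strictly increasing, starting at 0.
#' @param strain Engineering shear strain per sample; `strain[1]` must be 0
#'   and all values must lie in `[0, hold_strain]` (small tolerance allowed).
#' @param ramp_time Duration of the loading ramp (s).
#' @param hold_strain Strain level held after the ramp (dimensionless).
#' @return A tibble of class `vf_loading` with columns `time_s`, `strain`.
#' @seealso [make_loading()]
#' @export
loading_history <- function(time, strain, ramp_time, hold_strain) {
  time <- as.numeric(time)
  strain <- as.numeric(strain)
  stopifnot(length(time) == length(strain), length(time) >= 2L)
  if (time[1] != 0) stop("`time` must start at 0.")
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing.")
  if (abs(strain[1]) > 1e-12) stop("`strain` must start at 0.")
  tol <- 1e-6 + 1e-6 * hold_strain
  if (any(strain < -tol) || any(strain > hold_strain + tol)) {
    stop("`strain` must lie within [0, hold_strain].")
  }
  post <- time > ramp_time + 1e-12
  if (any(post) && any(abs(strain[post] - hold_strain) > 1e-6 + 1e-3 * hold_strain)) {
    stop("After `ramp_time`, strain must equal `hold_strain` (to sampling tolerance).")
  }
  out <- tibble::tibble(time_s = time, strain = strain)
  attr(out, "ramp_time") <- ramp_time
  attr(out, "hold_strain") <- hold_strain
  class(out) <- c("vf_loading", class(out))
  out
}

#' @export
print.vf_loading <- function(x, ...) {
  cat(sprintf(
    "<vf_loading> ramp %.4g s to strain %.4g, %d samples over %.4g s\n",
    attr(x, "ramp_time"), attr(x, "hold_strain"), nrow(x), max(x$time_s)
  ))
  NextMethod()
}

new_stress_trace <- function(time, stress) {
  out <- tibble::tibble(time_s = as.numeric(time), stress_pa = as.numeric(stress))
  class(out) <- c("vf_stress_trace", class(out))
  out
}

new_force_trace <- function(time, force) {
  out <- tibble::tibble(time_s = as.numeric(time), force_n = as.numeric(force))
  class(out) <- c("vf_force_trace", class(out))
  out
}

trace_value_col <- function(trace) {
  if (inherits(trace, "vf_force_trace") || "force_n" %in% names(trace)) return("force_n")
  if (inherits(trace, "vf_stress_trace") || "stress_pa" %in% names(trace)) return("stress_pa")
  if ("strain" %in% names(trace)) return("strain")
  setdiff(names(trace), "time_s")[1]
}

#' Read / write time-series traces as two-column CSV
#'
#' Traces (loading, stress, force) serialise to two-column CSV with a header
#' `time_s,<quantity>`; readers tolerate comment lines starting with `#`.
#'
#' @param trace A trace tibble (`time_s` plus one value column).
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   tibble whose class is inferred from the value column name
#'   (`stress_pa` / `force_n` / plain tibble otherwise).
#' @export
write_trace <- function(trace, path) {
  col <- trace_value_col(trace)
  readr::write_csv(tibble::as_tibble(trace)[, c("time_s", col)], path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!("time_s" %in% names(df)) || ncol(df) < 2L) {
    stop("Trace CSV must have a `time_s` column plus one value column.")
  }
  col <- setdiff(names(df), "time_s")[1]
  switch(col,
    stress_pa = new_stress_trace(df$time_s, df$stress_pa),
    force_n = new_force_trace(df$time_s, df$force_n),
    tibble::as_tibble(df)
  )
}
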