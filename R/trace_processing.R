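#' Force trace from a cutting trial
#'
#' A continuously recorded force signal from one pass of a cutting trial.
#' Displacement is derived from time and the (constant) stage speed unless
#' an explicit displacement vector is supplied, in which case it takes
#' precedence.
#'
#' @param time sample times in seconds, strictly increasing, length >= 2.
#' @param force forces in newtons, same length as `time`.
#' @param stage_speed stage speed in m s^-1; default 0.3 mm s^-1.
#' @param pass_id `"first"` (cut through intact sheet) or `"second"`
#'   (re-run through the open cut, measuring spacing forces only).
#' @param trial_id label tying the two passes of a trial together.
#' @param displacement optional displacement in metres; overrides
#'   `time * stage_speed`.
#' @return An object of class `force_trace`.
#' @export
force_trace <- function(time, force, stage_speed = 0.3e-3,
                        pass_id = c("first", "second"),
                        trial_id = "trial", displacement = NULL) {
  pass_id <- match.arg(pass_id)
  if (length(time) < 2L || length(force) != length(time)) {
    stop("'time' and 'force' must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(force))) {
    stop("'time' and 'force' must be finite", call. = FALSE)
  }
  bad <- which(diff(time) <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("'time' must be strictly increasing (violated at row %d)",
                 bad[1L] + 1L), call. = FALSE)
  }
  if (!is.numeric(stage_speed) || length(stage_speed) != 1L ||
      stage_speed <= 0) {
    stop("'stage_speed' must be a single positive number (m s^-1)",
         call. = FALSE)
  }
  if (is.null(displacement)) {
    displacement <- time * stage_speed
  } else {
    if (length(displacement) != length(time) ||
        any(diff(displacement) <= 0)) {
      stop("'displacement' must be strictly increasing and match 'time'",
           call. = FALSE)
    }
  }
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 displacement = as.numeric(displacement),
                 stage_speed = stage_speed, pass_id = pass_id,
                 trial_id = trial_id),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace '%s' (%s pass): %d samples, %.2f mm travel\n",
              x$trial_id, x$pass_id, length(x$time),
              diff(range(x$displacement)) * 1e3))
  invisible(x)
}

# Column-header dialect: name encodes the unit. Conversion factors to SI.
.trace_columns <- list(
  time = c(time_s = 1, time_ms = 1e-3),
  force = c(force_N = 1, force_mN = 1e-3, force_uN = 1e-6),
  displacement = c(displacement_m = 1, displacement_mm = 1e-3,
                   displacement_um = 1e-6)
)

#' Read a force trace from a delimited text file
#'
#' The default dialect is comma-separated UTF-8 with a header row whose
#' column names declare the units: `time_s,force_mN` or
#' `displacement_mm,force_mN` (also accepted: `time_ms`, `force_N`,
#' `force_uN`, `displacement_m`, `displacement_um`). Values are converted
#' to SI on read. A custom `format_spec` may remap header names.
#'
#' @param path path to the file.
#' @param stage_speed,pass_id,trial_id passed to [force_trace()].
#' @param format_spec optional named list mapping the file's column names
#'   to dialect names, e.g. `list(t = "time_s", F = "force_mN")`.
#' @param sep field separator; default `","`.
#' @return A [force_trace()].
#' @export
read_trace <- function(path, stage_speed = 0.3e-3,
                       pass_id = c("first", "second"),
                       trial_id = NULL, format_spec = NULL, sep = ",") {
  pass_id <- match.arg(pass_id)
  if (is.null(trial_id)) trial_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!is.null(format_spec)) {
    idx <- match(names(format_spec), names(df))
    if (anyNA(idx)) {
      stop(sprintf("format_spec names %s not found in '%s'",
                   paste(names(format_spec)[is.na(idx)], collapse = ", "),
                   path), call. = FALSE)
    }
    names(df)[idx] <- unlist(format_spec)
  }
  pick <- function(kind) {
    units <- .trace_columns[[kind]]
    hit <- intersect(names(units), names(df))
    if (length(hit) == 0L) return(NULL)
    df[[hit[1L]]] * units[[hit[1L]]]
  }
  force <- pick("force")
  if (is.null(force)) {
    stop(sprintf("no force column (e.g. 'force_mN') found in '%s'", path),
         call. = FALSE)
  }
  time <- pick("time")
  displacement <- pick("displacement")
  if (is.null(time) && is.null(displacement)) {
    stop(sprintf("no time or displacement column found in '%s'", path),
         call. = FALSE)
  }
  if (is.null(time)) time <- displacement / stage_speed
  force_trace(time = time, force = force, stage_speed = stage_speed,
              pass_id = pass_id, trial_id = trial_id,
              displacement = displacement)
}

#' Write a force trace in the standard CSV dialect
#'
#' @param trace a [force_trace()].
#' @param path output path; columns `time_s,force_mN`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(data.frame(time_s = trace$time,
                              force_mN = trace$force * 1e3),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate the steady-state window of a cutting trace
#'
#' For a first pass, the initiation peak (the global force maximum over the
#' portion of the trace that leaves room for a full window) is found, and
#' the window starts at the first sample after the peak where the force has
#' settled to within `settle_fraction` of the median force over the final
#' `window_length` of travel; it then spans `window_length`. For a second
#' pass (or when `start_displacement` is given, e.g. to align the spacing
#' window to the first-pass window) peak detection is skipped.
#'
#' @param trace a [force_trace()].
#' @param window_length window length in metres of travel; default 2 mm.
#' @param settle_fraction relative settling tolerance; default 0.1.
#' @param start_displacement optional explicit window start (m).
#' @return An object of class `steady_state_window`: list with
#'   `start_displacement`, `end_displacement`, `mean_force`, `force_sd`,
#'   `n`, `peak_index` (NA when peak detection is skipped).
#' @export
detect_steady_state <- function(trace, window_length = 2e-3,
                                settle_fraction = 0.1,
                                start_displacement = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  x <- trace$displacement
  f <- trace$force
  x_end <- x[length(x)]
  dx <- stats::median(diff(x))
  peak_index <- NA_integer_

  if (!is.null(start_displacement)) {
    s0 <- start_displacement
  } else if (trace$pass_id == "second") {
    s0 <- x[1L]
  } else {
    # the initiation peak is the global maximum (it overshoots the plateau)
    peak_index <- which.max(f)
    if (x[peak_index] + window_length > x_end + dx + 1e-12) {
      stop("insufficient steady state: less than the window length of ",
           "travel after the initiation peak", call. = FALSE)
    }
    trailing <- f[x >= x_end - window_length]
    med <- stats::median(trailing)
    tol <- settle_fraction * max(abs(med), .Machine$double.eps)
    after <- seq(peak_index + 1L, length(x))
    settled <- after[abs(f[after] - med) <= tol]
    if (length(settled) == 0L) {
      stop("insufficient steady state: force never settles after the peak",
           call. = FALSE)
    }
    s0 <- x[settled[1L]]
  }

  # allow one sample spacing of slack at the trace end
  if (s0 + window_length > x_end + dx + 1e-12) {
    stop("insufficient steady state: less than the window length of travel ",
         "after the settling point", call. = FALSE)
  }
  sel <- which(x >= s0 - 1e-12 & x <= s0 + window_length + 1e-12)
  if (!is.na(peak_index)) sel <- sel[sel > peak_index]
  structure(
    list(start_displacement = s0,
         end_displacement = min(s0 + window_length, x_end),
         mean_force = mean(f[sel]),
         force_sd = stats::sd(f[sel]),
         n = length(sel),
         peak_index = peak_index,
         trial_id = trace$trial_id,
         pass_id = trace$pass_id),
    class = "steady_state_window"
  )
}

#' Combine first- and second-pass windows into a cut measurement
#'
#' The first-pass steady-state mean is the total cutting force `Fc`; the
#' second-pass mean is the spacing force `Fs` (sidewall friction plus
#' elastic sheet deformation); their difference is the fracture force
#' `Ff = Fc - Fs`. A negative fracture force is retained and flagged,
#' never clipped.
#'
#' @param first,second [detect_steady_state()] windows from the same trial.
#' @return An object of class `cut_measurement` with fields `Fc`, `Fs`,
#'   `Ff` (N), `Fc_sd`, `Fs_sd`, `thickness_corrected`, `flag`
#'   (`NA` or `"negative_fracture_force"`), `trial_id`.
#' @export
decompose_passes <- function(first, second) {
  stopifnot(inherits(first, "steady_state_window"),
            inherits(second, "steady_state_window"))
  if (!identical(first$trial_id, second$trial_id)) {
    warning("combining windows from different trial_ids: '",
            first$trial_id, "' and '", second$trial_id, "'")
  }
  Fc <- first$mean_force
  Fs <- second$mean_force
  flag <- NA_character_
  if (Fs > Fc) {
    flag <- "negative_fracture_force"
    warning(sprintf("trial '%s': spacing force exceeds total cutting force",
                    first$trial_id))
  }
  structure(
    list(Fc = Fc, Fs = Fs, Ff = Fc - Fs,
         Fc_sd = first$force_sd, Fs_sd = second$force_sd,
         thickness_corrected = FALSE,
         sample_thickness = NA_real_, reference_thickness = NA_real_,
         flag = flag, trial_id = first$trial_id),
    class = "cut_measurement"
  )
}

#' @export
print.cut_measurement <- function(x, ...) {
  cat(sprintf("Cut measurement '%s'%s\n", x$trial_id,
              if (x$thickness_corrected) " (thickness-corrected)" else ""))
  cat(sprintf("  Fc = %.3g mN, Fs = %.3g mN, Ff = %.3g mN\n",
              x$Fc * 1e3, x$Fs * 1e3, x$Ff * 1e3))
  if (!is.na(x$flag)) cat(sprintf("  flag: %s\n", x$flag))
  invisible(x)
}

#' Correct a measurement to a reference lamina thickness
#'
#' Biological laminae vary in thickness between samples; forces are rescaled
#' to the substrate's mean thickness as `F * reference / sample`. All three
#' force components are scaled by the same factor, so `Fc = Ff + Fs` is
#' preserved. Applying the correction twice is an error unless
#' `allow_recorrect = TRUE` (used e.g. to undo a correction by swapping the
#' two thicknesses).
#'
#' @param measurement a [decompose_passes()] result.
#' @param sample_thickness measured thickness of this sample (m); `> 0`.
#' @param reference_thickness reference (mean) thickness (m); `> 0`.
#' @param allow_recorrect set `TRUE` to permit correcting an
#'   already-corrected measurement.
#' @return The corrected `cut_measurement`.
#' @export
thickness_correct <- function(measurement, sample_thickness,
                              reference_thickness,
                              allow_recorrect = FALSE) {
  stopifnot(inherits(measurement, "cut_measurement"))
  if (measurement$thickness_corrected && !allow_recorrect) {
    stop("measurement is already thickness-corrected", call. = FALSE)
  }
  for (v in list(sample_thickness = sample_thickness,
                 reference_thickness = reference_thickness)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("thicknesses must be single positive numbers (m)", call. = FALSE)
    }
  }
  k <- reference_thickness / sample_thickness
  measurement$Fc <- measurement$Fc * k
  measurement$Fs <- measurement$Fs * k
  measurement$Ff <- measurement$Ff * k
  measurement$Fc_sd <- measurement$Fc_sd * k
  measurement$Fs_sd <- measurement$Fs_sd * k
  measurement$thickness_corrected <- TRUE
  measurement$sample_thickness <- sample_thickness
  measurement$reference_thickness <- reference_thickness
  measurement
}

#' Spacing-force fraction Fs / Fc
#'
#' @param measurement a `cut_measurement`.
#' @return The fraction of the total cutting force due to spacing forces.
#' @export
spacing_fraction <- function(measurement) {
  stopifnot(inherits(measurement, "cut_measurement"))
  if (measurement$Fc <= 0) {
    stop("total cutting force must be positive", call. = FALSE)
  }
  measurement$Fs / measurement$Fc
}

#' Flatten cut measurements into a tidy data frame
#'
#' @param measurements a list of `cut_measurement` objects.
#' @return A data frame with one row per trial: `trial_id`, `Fc_mN`,
#'   `Fs_mN`, `Ff_mN`, `thickness_corrected`, `flag`.
#' @export
measurements_to_df <- function(measurements) {
  stopifnot(all(vapply(measurements, inherits, TRUE, "cut_measurement")))
  data.frame(
    trial_id = vapply(measurements, `[[`, "", "trial_id"),
    Fc_mN = vapply(measurements, `[[`, 0, "Fc") * 1e3,
    Fs_mN = vapply(measurements, `[[`, 0, "Fs") * 1e3,
    Ff_mN = vapply(measurements, `[[`, 0, "Ff") * 1e3,
    thickness_corrected = vapply(measurements, `[[`, TRUE,
                                 "thickness_corrected"),
    flag = vapply(measurements, `[[`, "", "flag"),
    stringsAsFactors = FALSE
  )
}
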