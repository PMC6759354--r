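#' Stimulus trace container
#'
#' An M x T array of stimulus values sampled on a uniform time grid, plus
#' optional per-sample labels (which digit or orientation is on).
#'
#' @param values Numeric M x T matrix (rows = stimulus dimensions). A vector
#'   is treated as a 1 x T matrix.
#' @param dt Sampling step in ms.
#' @param labels Optional vector of length T annotating each sample (NA
#'   where no stimulus is on).
#' @return An object of class \code{stimulus_trace} with elements
#'   \code{values}, \code{dt}, \code{time} (ms, starting at 0) and
#'   \code{labels}.
#' @export
stimulus_trace <- function(values, dt, labels = NULL) {
  if (is.vector(values) && is.numeric(values)) {
    values <- matrix(values, nrow = 1L)
  }
  if (!is.matrix(values) || !is.numeric(values) || ncol(values) < 1L) {
    stop("values must be a numeric M x T matrix with T >= 1")
  }
  if (any(!is.finite(values))) stop("stimulus values must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a positive scalar (ms)")
  }
  if (!is.null(labels) && length(labels) != ncol(values)) {
    stop("labels must have one entry per time sample")
  }
  structure(
    list(values = values, dt = dt,
         time = (seq_len(ncol(values)) - 1L) * dt,
         labels = labels),
    class = "stimulus_trace"
  )
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("Stimulus trace: M = %d, %d samples, dt = %g ms (%.4g ms)\n",
              nrow(x$values), ncol(x$values), x$dt, ncol(x$values) * x$dt))
  invisible(x)
}

# Seven-segment table, segments ordered A, B, C, D, E, F, G (top, upper
# right, lower right, bottom, lower left, upper left, middle).
SEGMENT_TABLE <- rbind(
  `0` = c(1, 1, 1, 1, 1, 1, 0),
  `1` = c(0, 1, 1, 0, 0, 0, 0),
  `2` = c(1, 1, 0, 1, 1, 0, 1),
  `3` = c(1, 1, 1, 1, 0, 0, 1),
  `4` = c(0, 1, 1, 0, 0, 1, 1),
  `5` = c(1, 0, 1, 1, 0, 1, 1),
  `6` = c(1, 0, 1, 1, 1, 1, 1),
  `7` = c(1, 1, 1, 0, 0, 0, 0),
  `8` = c(1, 1, 1, 1, 1, 1, 1),
  `9` = c(1, 1, 1, 1, 0, 1, 1)
)

#' Seven-segment pattern for a digit
#'
#' Encodes a decimal digit as a 7-vector, one dimension per bar of a digital
#' display (segment order A, B, C, D, E, F, G). Active segments take the
#' given amplitude, inactive segments are 0.
#'
#' @param digit Integer 0-9.
#' @param amplitude Positive value of an active segment (default 2, the
#'   midpoint of the 0-4 range used to train the baseline decoder).
#' @return Numeric 7-vector.
#' @export
digit_pattern <- function(digit, amplitude = 2) {
  if (length(digit) != 1L || is.na(digit) || digit %% 1 != 0 ||
      digit < 0 || digit > 9) {
    stop("digit must be a single integer in 0..9")
  }
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude <= 0) {
    stop("amplitude must be a positive scalar")
  }
  amplitude * SEGMENT_TABLE[as.character(as.integer(digit)), ]
}

#' Piecewise-constant digit sequence stimulus
#'
#' Each digit is shown for \code{on_ms}; consecutive digits are separated by
#' \code{off_ms} of zero input (no trailing gap after the last digit). The
#' default presentation (200 ms on, 100 ms between digits) gives a 2300 ms
#' trace for 8 digits.
#'
#' @param digits Integer vector of digits 0-9.
#' @param on_ms,off_ms Presentation and gap durations in ms.
#' @param amplitude Active-segment amplitude.
#' @param dt Sampling step in ms.
#' @return A \code{stimulus_trace} with M = 7; \code{labels} holds the digit
#'   shown at each sample (NA during gaps).
#' @export
digit_sequence <- function(digits, on_ms = 200, off_ms = 100, amplitude = 2,
                           dt = 0.1) {
  if (length(digits) < 1L) stop("digits must be a nonempty vector")
  n_on <- round(on_ms / dt)
  n_off <- round(off_ms / dt)
  cols <- list()
  labels <- list()
  for (k in seq_along(digits)) {
    pat <- digit_pattern(digits[k], amplitude)
    cols[[length(cols) + 1L]] <- matrix(pat, nrow = 7, ncol = n_on)
    labels[[length(labels) + 1L]] <- rep(digits[k], n_on)
    if (k < length(digits) && n_off > 0) {
      cols[[length(cols) + 1L]] <- matrix(0, nrow = 7, ncol = n_off)
      labels[[length(labels) + 1L]] <- rep(NA_real_, n_off)
    }
  }
  stimulus_trace(do.call(cbind, cols), dt, labels = unlist(labels))
}

#' Random constant training patterns
#'
#' Generates the stimulus set used to train the baseline network's optimal
#' linear decoder: constant M-dimensional patterns with entries drawn
#' i.i.d. uniform on [low, high], each held for \code{duration_ms}.
#'
#' @param n Number of patterns.
#' @param duration_ms Duration of each pattern in ms.
#' @param low,high Uniform range of the entries.
#' @param M Stimulus dimension.
#' @param dt Sampling step in ms.
#' @param seed Integer seed (required; the draw is the only randomness).
#' @return List of \code{n} \code{stimulus_trace} objects.
#' @export
random_pattern_stimuli <- function(n = 100, duration_ms = 300, low = 0,
                                   high = 4, M = 7, dt = 0.1, seed) {
  if (missing(seed)) stop("seed is required for random pattern generation")
  stopifnot(n >= 1, duration_ms > 0, high >= low)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  TT <- round(duration_ms / dt)
  lapply(seq_len(n), function(k) {
    pat <- stats::runif(M, low, high)
    stimulus_trace(matrix(pat, nrow = M, ncol = TT), dt)
  })
}

#' Constant pulse stimulus
#'
#' A scalar (or M-dimensional constant) pulse: \code{value} inside
#' [onset, onset + duration), zero outside.
#'
#' @param value Pulse amplitude (scalar, or length-M vector).
#' @param duration_ms Pulse duration in ms.
#' @param onset_ms Pulse onset in ms (default 0).
#' @param dt Sampling step in ms.
#' @param total_ms Total trace duration (default onset + duration).
#' @return A \code{stimulus_trace}.
#' @export
constant_pulse <- function(value, duration_ms, onset_ms = 0, dt = 0.1,
                           total_ms = onset_ms + duration_ms) {
  stopifnot(duration_ms > 0, onset_ms >= 0, total_ms >= onset_ms)
  M <- length(value)
  TT <- round(total_ms / dt)
  vals <- matrix(0, nrow = M, ncol = TT)
  i0 <- round(onset_ms / dt)
  i1 <- min(TT, i0 + round(duration_ms / dt))
  if (i1 > i0) vals[, (i0 + 1L):i1] <- value
  stimulus_trace(vals, dt)
}

#' Oriented two-dimensional drive
#'
#' Maps an orientation theta(t) in (-pi/2, pi/2] and magnitude C(t) >= 0
#' onto the two-dimensional stimulus \code{[C cos(2 theta), C sin(2 theta)]}.
#' The angle doubling maps orientation (period pi) onto the full circle so
#' that the stimulus direction, the neurons' preferred-orientation weights
#' and the decoded orientation all share one convention; the Euclidean norm
#' of the stimulus equals C(t) at every sample.
#'
#' @param theta Orientation in radians; scalar or length-T vector.
#' @param C Magnitude; scalar or length-T vector (>= 0).
#' @param duration_ms Trace duration when theta and C are scalars.
#' @param dt Sampling step in ms.
#' @return A \code{stimulus_trace} with M = 2; \code{labels} holds theta.
#' @export
orientation_stimulus <- function(theta, C, duration_ms = NULL, dt = 0.1) {
  if (length(theta) == 1L && length(C) == 1L) {
    if (is.null(duration_ms)) stop("duration_ms required for scalar inputs")
    TT <- round(duration_ms / dt)
    theta <- rep(theta, TT)
    C <- rep(C, TT)
  } else {
    TT <- max(length(theta), length(C))
    theta <- rep_len(theta, TT)
    C <- rep_len(C, TT)
  }
  if (any(C < 0)) stop("stimulus magnitude C must be non-negative")
  vals <- rbind(C * cos(2 * theta), C * sin(2 * theta))
  stimulus_trace(vals, dt, labels = theta)
}

#' Concatenate stimulus traces in time
#'
#' @param ... \code{stimulus_trace} objects with equal M and dt.
#' @return A single \code{stimulus_trace}.
#' @export
concat_stimuli <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 1L)
  dt <- parts[[1L]]$dt
  M <- nrow(parts[[1L]]$values)
  for (p in parts) {
    if (!inherits(p, "stimulus_trace")) stop("all parts must be stimulus traces")
    if (p$dt != dt || nrow(p$values) != M) stop("parts must share M and dt")
  }
  labels <- lapply(parts, function(p) {
    if (is.null(p$labels)) rep(NA_real_, ncol(p$values)) else p$labels
  })
  stimulus_trace(do.call(cbind, lapply(parts, `[[`, "values")), dt,
                 labels = unlist(labels))
}

# ---- seeded-draw helpers ---------------------------------------------------

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
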