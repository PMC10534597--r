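.adaptive_rule <- "max(mean(magnitudes), 20) + 10"

#' The eight-threshold detector configuration
#'
#' Defaults are the final tuned values of the method. Two thresholds are rules
#' rather than numbers: `max_limit` defaults to the adaptive rule
#' `max(mean(magnitudes), 20) + 10`, resolved once per input series, and
#' `max_limit_2` defaults to `"max_limit"` (equal to the resolved `max_limit`).
#' Either may be given as a plain number instead.
#'
#' Three further knobs parameterize the final stability check, whose tolerances
#' the method leaves qualitative ("close to g", "low" standard deviation); they
#' are package defaults, not tuned values: `stability_window` (entry units over
#' which the post-fall signal is inspected; `NULL` means reuse `dist_2`),
#' `mean_tol` and `std_tol` (m/s^2).
#'
#' @param min_limit Upper limit for classifying a magnitude as low (m/s^2).
#' @param max_limit Lower limit for classifying a magnitude as high: a number,
#'   or `"adaptive"` / the rule string for the per-series rule.
#' @param sub_1 Minimum entry gap separating two sets of lows/highs.
#' @param fall_duration Maximum entry span (finish-high minus start-low) for a
#'   low/high pairing to count as a possible fall.
#' @param fall_limitation Entry span above which a fall is "long" and must be
#'   shrunk toward its peak or rejected.
#' @param dist_1,dist_2 Entry distance before/after a fall searched for
#'   neighbouring highs in the peak-dominance check.
#' @param max_limit_2 Lower limit for classifying neighbouring magnitudes as
#'   high: a number, or `"max_limit"` to equal the resolved `max_limit`.
#' @param stability_window,mean_tol,std_tol Post-fall stability check
#'   parameters (see Details).
#'
#' @return An object of class `threshold_set`.
#' @seealso [resolve_thresholds()], [read_thresholds()], [write_thresholds()]
#' @export
threshold_set <- function(min_limit = 6.5,
                          max_limit = "adaptive",
                          sub_1 = 50,
                          fall_duration = 105,
                          fall_limitation = 85,
                          dist_1 = 100,
                          dist_2 = 100,
                          max_limit_2 = "max_limit",
                          stability_window = NULL,
                          mean_tol = 1.5,
                          std_tol = 2.0) {
  num_pos <- function(v, name) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("%s must be a single positive number", name), call. = FALSE)
    }
    as.double(v)
  }
  if (is.character(max_limit)) {
    ml <- gsub(" ", "", tolower(max_limit))
    if (!ml %in% c("adaptive", gsub(" ", "", .adaptive_rule),
                   "max(avg,20)+10", "max(average(magnitudes),20)+10")) {
      stop("max_limit must be a number or the adaptive rule string", call. = FALSE)
    }
    max_limit <- "adaptive"
  } else {
    max_limit <- num_pos(max_limit, "max_limit")
  }
  if (is.character(max_limit_2)) {
    if (gsub(" ", "", tolower(max_limit_2)) != "max_limit") {
      stop("max_limit_2 must be a number or \"max_limit\"", call. = FALSE)
    }
    max_limit_2 <- "max_limit"
  } else {
    max_limit_2 <- num_pos(max_limit_2, "max_limit_2")
  }
  ts <- structure(
    list(min_limit = num_pos(min_limit, "min_limit"),
         max_limit = max_limit,
         sub_1 = num_pos(sub_1, "sub_1"),
         fall_duration = num_pos(fall_duration, "fall_duration"),
         fall_limitation = num_pos(fall_limitation, "fall_limitation"),
         dist_1 = num_pos(dist_1, "dist_1"),
         dist_2 = num_pos(dist_2, "dist_2"),
         max_limit_2 = max_limit_2,
         stability_window = if (is.null(stability_window)) NULL
                            else num_pos(stability_window, "stability_window"),
         mean_tol = num_pos(mean_tol, "mean_tol"),
         std_tol = num_pos(std_tol, "std_tol")),
    class = "threshold_set"
  )
  if (ts$fall_limitation > ts$fall_duration) {
    warning("fall_limitation exceeds fall_duration; the long-fall shrink stage is vacuous",
            call. = FALSE)
  }
  ts
}

#' @export
print.threshold_set <- function(x, ...) {
  fmt <- function(v) if (is.character(v)) v else format(v)
  cat("<threshold_set>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  %-17s %s\n", nm, fmt(x[[nm]])))
  }
  if (is.null(x$stability_window)) cat("  stability_window  (= dist_2)\n")
  invisible(x)
}

#' Resolve rule-valued thresholds against a magnitude series
#'
#' Evaluates the adaptive `max_limit` rule (`max(mean(magnitudes), 20) + 10`)
#' over the entire input series, resolves `max_limit_2 = max_limit` when
#' requested, and fills the stability window from `dist_2` when unset. All
#' other fields pass through unchanged.
#'
#' @param thresholds A [threshold_set()].
#' @param magnitudes Non-empty numeric vector of magnitudes (m/s^2).
#' @return A `threshold_set` whose fields are all plain numbers.
#' @examples
#' resolve_thresholds(threshold_set(), rep(16.6, 10))$max_limit  # 30
#' @export
resolve_thresholds <- function(thresholds, magnitudes) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (!is.numeric(magnitudes) || length(magnitudes) == 0L || anyNA(magnitudes)) {
    stop("magnitudes must be a non-empty numeric vector without NA", call. = FALSE)
  }
  out <- thresholds
  if (identical(out$max_limit, "adaptive")) {
    out$max_limit <- max(mean(magnitudes), 20) + 10
  }
  if (identical(out$max_limit_2, "max_limit")) {
    out$max_limit_2 <- out$max_limit
  }
  if (is.null(out$stability_window)) {
    out$stability_window <- out$dist_2
  }
  if (out$min_limit >= out$max_limit) {
    warning("min_limit is not below the resolved max_limit; detection degenerates",
            call. = FALSE)
  }
  out
}

# yaml emits doubles at limited precision by default; force %.17g so that a
# written config reads back bit-identically.
.yaml_num_handler <- function(x) {
  structure(sprintf("%.17g", x), class = "verbatim")
}

#' Write / read a threshold configuration file
#'
#' Flat YAML key/value document whose keys are the threshold names, so the
#' method's published threshold table can be read directly against the config.
#' Numeric values round-trip bit-exactly.
#'
#' @param thresholds A [threshold_set()].
#' @param path File path.
#' @return `write_thresholds` returns `path` invisibly; `read_thresholds`
#'   returns a [threshold_set()].
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  vals <- Filter(Negate(is.null), unclass(thresholds))
  yaml::write_yaml(vals, path, handlers = list(numeric = .yaml_num_handler))
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(threshold_set))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown threshold keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  do.call(threshold_set, raw)
}
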