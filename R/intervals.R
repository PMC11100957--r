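#' Motion phases and FoG episodes
#'
#' The event vocabulary shared by the detector, the expert annotation and the
#' evaluation: *motion phases* are foot-movement intervals (approximating the
#' swing phase, but also shuffles and trembling heel lifts), and *FoG
#' episodes* are expert-marked freezing intervals with a subtype. Both are
#' plain tibbles so they compose with dplyr verbs.
#'
#' @param start,end interval bounds in seconds, `end > start`.
#' @param source `"detected"` or `"annotated"`.
#' @param leg `"left"` or `"right"`.
#' @param class_label `"none"` until classified/labelled, else `"normal"` or
#'   `"fog"`.
#' @return a tibble with one row per interval.
#' @export
motion_phases <- function(start = numeric(), end = numeric(),
                          source = "annotated", leg = "left",
                          class_label = "none") {
  out <- tibble::tibble(
    start = as.numeric(start), end = as.numeric(end),
    source = rep_len(source, length(start)),
    leg = rep_len(leg, length(start)),
    class_label = rep_len(class_label, length(start))
  )
  validate_intervals(out, what = "motion phases", allow_overlap = FALSE)
  out
}

#' @rdname motion_phases
#' @param subtype FoG subtype: `"shuffling"`, `"festination"`, `"trembling"`
#'   or `"akinesia"`.
#' @export
fog_episodes <- function(start = numeric(), end = numeric(),
                         subtype = "shuffling") {
  subtype <- rep_len(subtype, length(start))
  bad <- setdiff(
    unique(subtype),
    c("shuffling", "festination", "trembling", "akinesia")
  )
  if (length(bad) > 0L) {
    stop_invalid("unknown FoG subtype: ", paste(bad, collapse = ", "))
  }
  out <- tibble::tibble(
    start = as.numeric(start), end = as.numeric(end), subtype = subtype
  )
  validate_intervals(out, what = "FoG episodes", allow_overlap = FALSE)
  out
}

validate_intervals <- function(x, what = "intervals", allow_overlap = FALSE) {
  if (nrow(x) == 0L) {
    return(invisible(x))
  }
  if (any(x$end <= x$start)) {
    stop_invalid(what, ": every interval needs end > start")
  }
  if (!allow_overlap && nrow(x) >= 2L) {
    o <- order(x$start)
    if (any(x$start[o][-1L] < x$end[o][-nrow(x)])) {
      stop_invalid(what, " must be non-overlapping")
    }
  }
  invisible(x)
}

#' Read and write interval annotations
#'
#' Intervals (motion phases or FoG episodes) are serialized as a JSON document
#' `{schema, kind, intervals}` sorted by start time. The schema field guards
#' against silently reading files written by incompatible versions.
#'
#' @param x a tibble of intervals ([motion_phases()] or [fog_episodes()]).
#' @param path file path.
#' @param kind stored alongside the data; inferred from columns if missing.
#' @return `read_intervals()` returns the tibble; `write_intervals()` returns
#'   `path` invisibly.
#' @export
write_intervals <- function(x, path, kind = NULL) {
  if (is.null(kind)) {
    kind <- if ("subtype" %in% names(x)) "fog_episodes" else "motion_phases"
  }
  # phases from different provenances (detected vs annotated) may overlap;
  # within one provenance, and for FoG episodes, overlap is invalid
  mixed <- identical(kind, "motion_phases") && "source" %in% names(x) &&
    length(unique(x$source)) > 1L
  validate_intervals(x, what = kind, allow_overlap = mixed)
  x <- dplyr::arrange(tibble::as_tibble(x), .data$start)
  doc <- list(schema = "gaitcue/intervals/1", kind = kind, intervals = x)
  jsonlite::write_json(
    doc, path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) {
    stop_invalid("no such file: ", path)
  }
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$schema, "gaitcue/intervals/1")) {
    stop_invalid("unrecognized interval schema in ", path)
  }
  x <- tibble::as_tibble(doc$intervals)
  if (length(doc$intervals) == 0L || nrow(x) == 0L) {
    x <- if (identical(doc$kind, "fog_episodes")) {
      fog_episodes()
    } else {
      motion_phases()
    }
  }
  validate_intervals(x, what = doc$kind)
  x
}
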