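# Evaluation of detection, cueing and classification against expert
# annotation: interval-overlap matching, delay statistics, cueing coverage,
# end-time FoG labelling, confusion metrics and gait reports.
#
# All interval logic is on half-open intervals [start, end): a shared
# endpoint is not an overlap, which prevents double matching at boundaries.

#' Match detected against annotated motion phases
#'
#' A detected phase is *exclusive* to an annotated phase if it overlaps that
#' phase and no other. An annotated phase counts as correctly detected if at
#' least one exclusive detected phase overlaps it; among several, only the
#' first (earliest start) is kept as the match, since that one rules the
#' pulse-train generation. Detected phases overlapping zero or two-plus
#' annotated phases are false detections.
#'
#' @param annotated,detected tibbles of time-ordered, non-overlapping motion
#'   phases (`start`, `end`).
#' @return an object of class `fog_match`: `pairs` (matched annotated /
#'   detected bounds), `missed`, `false_detections`, `counts` and `rates`
#'   (percent, rounded half-up to one decimal as printed in gait reports).
#' @export
match_phases <- function(annotated, detected) {
  validate_intervals(tibble::as_tibble(annotated), "annotated phases")
  # detected phases only need valid bounds: a detector glitch that yields
  # overlapping detections must still be countable as false detections
  validate_intervals(
    tibble::as_tibble(detected), "detected phases",
    allow_overlap = TRUE
  )
  na <- nrow(annotated)
  nd <- nrow(detected)
  overlaps_count <- integer(nd)
  first_annot <- integer(nd)
  for (j in seq_len(nd)) {
    hit <- which(intervals_overlap(
      annotated$start, annotated$end, detected$start[j], detected$end[j]
    ))
    overlaps_count[j] <- length(hit)
    first_annot[j] <- if (length(hit) == 1L) hit else NA_integer_
  }
  exclusive <- overlaps_count == 1L
  pairs <- vector("list", na)
  matched <- logical(na)
  for (i in seq_len(na)) {
    cand <- which(exclusive & first_annot == i)
    if (length(cand) > 0L) {
      j <- cand[which.min(detected$start[cand])]
      matched[i] <- TRUE
      pairs[[i]] <- tibble::tibble(
        a_start = annotated$start[i], a_end = annotated$end[i],
        d_start = detected$start[j], d_end = detected$end[j]
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0L) {
    pairs <- tibble::tibble(
      a_start = numeric(), a_end = numeric(),
      d_start = numeric(), d_end = numeric()
    )
  }
  false_idx <- which(overlaps_count != 1L)
  counts <- list(
    n_annotated = na,
    n_correct = sum(matched),
    n_missed = na - sum(matched),
    n_false = length(false_idx)
  )
  rates <- list(
    rate_correct = if (na > 0) {
      round_half_up(100 * counts$n_correct / na, 1)
    } else {
      NA_real_
    },
    rate_missed = if (na > 0) {
      round_half_up(100 * counts$n_missed / na, 1)
    } else {
      NA_real_
    }
  )
  structure(
    list(
      pairs = pairs,
      missed = tibble::as_tibble(annotated)[!matched, , drop = FALSE],
      false_detections = tibble::as_tibble(detected)[false_idx, ,
        drop = FALSE
      ],
      counts = counts, rates = rates
    ),
    class = "fog_match"
  )
}

#' @export
print.fog_match <- function(x, ...) {
  cat(sprintf(
    "<fog_match> %d annotated: %d (%.1f%%) detected, %d (%.1f%%) missed, %d false\n",
    x$counts$n_annotated, x$counts$n_correct, x$rates$rate_correct,
    x$counts$n_missed, x$rates$rate_missed, x$counts$n_false
  ))
  invisible(x)
}

#' Start/end detection delays of matched phases
#'
#' For every matched pair: `start_delay = detected start - annotated start`,
#' `end_delay = detected end - annotated end`, and the duration difference
#' `detected duration - annotated duration` (equal to end minus start
#' delay).
#'
#' @param match a `fog_match` from [match_phases()].
#' @return an object of class `fog_delays` with per-pair `samples` and a
#'   median/quartile `summary`; empty when there are no matches.
#' @export
delay_stats <- function(match) {
  if (!inherits(match, "fog_match")) {
    stop_invalid("delay_stats() needs a fog_match")
  }
  p <- match$pairs
  samples <- tibble::tibble(
    start_delay = p$d_start - p$a_start,
    end_delay = p$d_end - p$a_end,
    duration_diff = (p$d_end - p$d_start) - (p$a_end - p$a_start)
  )
  summarize_q <- function(v) {
    if (length(v) == 0L) {
      return(c(q25 = NA_real_, median = NA_real_, q75 = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(q25 = q[1], median = q[2], q75 = q[3])
  }
  summary <- dplyr::bind_rows(
    c(measure = "start_delay", summarize_q(samples$start_delay)),
    c(measure = "end_delay", summarize_q(samples$end_delay)),
    c(measure = "duration_diff", summarize_q(samples$duration_diff))
  )
  summary <- dplyr::mutate(
    summary,
    dplyr::across(c("q25", "median", "q75"), as.numeric)
  )
  structure(
    list(samples = samples, summary = summary),
    class = "fog_delays"
  )
}

#' Temporal cueing coverage within on-demand intervals
#'
#' Restricted to the union of on-demand cueing intervals: which share of
#' motion-phase time was stimulated, and which share of non-motion-phase
#' time was stimulated.
#'
#' @param annotated_mps annotated motion phases (`start`, `end`).
#' @param trains pulse trains (`start`, `end`).
#' @param intervals on-demand cueing intervals (`start`, `end`).
#' @return list with `pct_mp_time_stimulated` and
#'   `pct_nonmp_time_stimulated` (percent; `NA` when the respective
#'   denominator is empty).
#' @export
cueing_coverage <- function(annotated_mps, trains, intervals) {
  iv <- interval_union(intervals$start, intervals$end)
  mp <- interval_union(annotated_mps$start, annotated_mps$end)
  st <- interval_union(trains$start, trains$end)
  iv_len <- sum(iv$end - iv$start)
  mp_in <- interval_intersection_length(mp, iv)
  st_in <- interval_intersection_length(st, iv)
  # stim within MPs within intervals: intersect trains with MPs, then clip
  st_mp <- 0
  if (nrow(st) > 0L && nrow(mp) > 0L) {
    pieces_s <- numeric()
    pieces_e <- numeric()
    for (i in seq_len(nrow(st))) {
      lo <- pmax(st$start[i], mp$start)
      hi <- pmin(st$end[i], mp$end)
      keep <- hi > lo
      pieces_s <- c(pieces_s, lo[keep])
      pieces_e <- c(pieces_e, hi[keep])
    }
    st_mp <- interval_intersection_length(
      interval_union(pieces_s, pieces_e), iv
    )
  }
  nonmp_in <- iv_len - mp_in
  list(
    pct_mp_time_stimulated = if (mp_in > 0) 100 * st_mp / mp_in else NA_real_,
    pct_nonmp_time_stimulated = if (nonmp_in > 0) {
      100 * (st_in - st_mp) / nonmp_in
    } else {
      NA_real_
    }
  )
}

#' Label detected phases from expert FoG episodes
#'
#' A detected motion phase is FoG-associated iff its end time lies inside an
#' expert-marked episode (inclusive of the episode start, exclusive of its
#' end); otherwise it is normal.
#'
#' @param detected detected motion phases (`start`, `end`).
#' @param episodes FoG episodes (`start`, `end`), non-overlapping.
#' @return character vector of `"fog"` / `"normal"`, one per detected phase.
#' @export
label_detected <- function(detected, episodes) {
  validate_intervals(tibble::as_tibble(episodes), "FoG episodes")
  if (nrow(detected) == 0L) {
    return(character())
  }
  vapply(detected$end, function(e) {
    if (any(e >= episodes$start & e < episodes$end)) "fog" else "normal"
  }, "")
}

#' Sensitivity, specificity and accuracy of the FoG classification
#'
#' FoG is the positive class. With a grouping vector, per-group metrics are
#' reported alongside the total computed from the summed confusion matrix.
#'
#' @param predicted,truth character vectors of `"fog"` / `"normal"`.
#' @param group optional grouping (e.g. trial ids).
#' @return list with `per_group` (tibble; `NULL` without grouping), `total`
#'   (named vector, percent) and `confusion` (summed counts).
#' @export
classification_metrics <- function(predicted, truth, group = NULL) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    stop_invalid("predicted and truth must be equal-length, non-empty")
  }
  per_group <- NULL
  if (!is.null(group)) {
    per_group <- dplyr::bind_rows(lapply(unique(group), function(g) {
      cm <- confusion_counts(predicted[group == g], truth[group == g])
      m <- confusion_metrics(cm)
      tibble::tibble(
        group = g, sensitivity = m["sensitivity"],
        specificity = m["specificity"], accuracy = m["accuracy"]
      )
    }))
  }
  cm <- confusion_counts(predicted, truth)
  list(
    per_group = per_group,
    total = confusion_metrics(cm),
    confusion = cm
  )
}

#' Per-session gait report
#'
#' Summarizes one cueing session the way a daily gait report would: total
#' duration, cueing time, motion-phase counts (total, FoG-affected, cued)
#' and the derived percentages. A motion phase counts as cued if a pulse
#' train overlaps it or was emitted at its end (the retroactive cue of the
#' interval-opening phase).
#'
#' @param session a `cueing_session` from [run_pipeline()], or a list with
#'   `duration_s`, `phases` (with `class_label`), `trains` and `config`.
#' @return a one-row tibble.
#' @export
gait_report <- function(session) {
  phases <- session$phases
  trains <- session$trains
  duration_s <- session$duration_s
  latency <- session$config$event_latency %||% 0
  n_mps <- nrow(phases)
  n_fog <- if (n_mps > 0) sum(phases$class_label == "fog") else 0L
  cued <- 0L
  if (n_mps > 0L && nrow(trains) > 0L) {
    for (i in seq_len(n_mps)) {
      hit <- intervals_overlap(
        trains$start, trains$end,
        phases$start[i], phases$end[i] + latency + 0.002
      )
      cued <- cued + any(hit)
    }
  }
  cueing_s <- interval_union_length(trains$start, trains$end)
  tibble::tibble(
    duration_s = duration_s,
    cueing_s = cueing_s,
    n_mps = n_mps,
    n_fog_mps = n_fog,
    n_cued_mps = as.integer(cued),
    percent_fog = if (n_mps > 0) round_half_up(100 * n_fog / n_mps, 1) else 0,
    percent_cueing_active = if (duration_s > 0) {
      round_half_up(100 * cueing_s / duration_s, 1)
    } else {
      0
    }
  )
}

#' Average cueing-active share across courses and subjects
#'
#' The report arithmetic behind a statement like "cueing was active for X%
#' of the trial durations": per course, the cueing share is 100 *
#' cueing_s / duration_s; shares are averaged per subject and then across
#' subjects, each stage rounded half-up to one decimal for printing.
#'
#' @param courses tibble with columns `subject`, `duration_s`, `cueing_s`
#'   (one row per course/test).
#' @return list with `per_subject` (tibble `subject`,
#'   `percent_cueing_active`) and `overall` (scalar percent).
#' @export
cueing_active_summary <- function(courses) {
  per_subject <- courses |>
    dplyr::mutate(share = 100 * .data$cueing_s / .data$duration_s) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      percent_cueing_active = round_half_up(mean(.data$share), 1),
      .groups = "drop"
    )
  list(
    per_subject = per_subject,
    overall = round_half_up(mean(per_subject$percent_cueing_active), 1)
  )
}
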