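# Run the detection + feature + labelling stages over a simulated cohort,
# collecting match counts per trial and the labelled feature table.
process_cohort <- function(cohort) {
  match_rows <- list()
  feat_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    out <- extract_all(cohort$stream[[i]])
    truth <- cohort$truth[[i]]
    m <- match_phases(truth$motion_phases, out$phases$motion)
    match_rows[[i]] <- tibble::tibble(
      subject = cohort$subject[i], trial = cohort$trial[i],
      n_annotated = m$counts$n_annotated, n_correct = m$counts$n_correct,
      n_missed = m$counts$n_missed, n_false = m$counts$n_false
    )
    labels <- label_detected(out$phases$motion, truth$fog_episodes)
    feat_rows[[i]] <- dplyr::mutate(
      out$features,
      subject = cohort$subject[i], label = labels
    )
  }
  list(
    matches = dplyr::bind_rows(match_rows),
    features = dplyr::bind_rows(feat_rows)
  )
}
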