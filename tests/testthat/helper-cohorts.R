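# Small cohort builders shared across test files.

# Planted cohort at reduced size for fast unit tests.
small_planted_cohort <- function(seed = 1, n_subjects = 40, n_rois = 16,
                                 n_timepoints = 80, n_edges = 5,
                                 coupling_base = 1, coupling_slope = 0.8) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_rois = n_rois,
    n_timepoints = n_timepoints,
    signature_edges = default_signature_edges(n_rois, n_edges),
    coupling_base = coupling_base, coupling_slope = coupling_slope,
    seed = seed
  ))
}

# Cohort with no planted structure at all.
null_cohort <- function(seed = 1, n_subjects = 30, n_rois = 16,
                        n_timepoints = 60) {
  generate_cohort(cohort_config(
    n_subjects = n_subjects, n_rois = n_rois,
    n_timepoints = n_timepoints,
    signature_edges = matrix(integer(0), 0, 2),
    coupling_base = 0, coupling_slope = 0,
    seed = seed
  ))
}
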