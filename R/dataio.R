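#' Read a phenotype table
#'
#' Loads a comma-separated phenotype file with a header. `subject_id`
#' and `score` are mandatory; recognised optional columns (`age`,
#' `sex`, `education`, `moca`, `hy`, `mean_fd`, `ledd`, `site`) are
#' typed, and blank cells stay missing (NA), never zero.
#'
#' @param path CSV file path.
#' @return Data frame, one row per subject.
#' @export
load_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (col in c("subject_id", "score")) {
    if (!col %in% names(df)) stop("phenotype file lacks column '", col, "'")
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  for (col in intersect(c("score", "age", "education", "moca", "hy",
                          "mean_fd", "ledd"), names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  message("loaded ", nrow(df), " subjects from ", path)
  df
}

#' Read per-subject ROI time-series matrices
#'
#' Each subject is one tab-separated, headerless numeric matrix
#' (timepoints x ROIs) named `<subject_id>.tsv` in `dir`. The subject
#' order follows `subject_ids`, which is how alignment with the
#' phenotype table is enforced.
#'
#' @param dir Directory of per-subject files.
#' @param subject_ids Character vector ordering the subjects.
#' @return Named list of timepoints x ROIs matrices.
#' @export
load_timeseries <- function(dir, subject_ids) {
  series <- lapply(subject_ids, function(id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("no time-series file for subject ", id)
    m <- as.matrix(utils::read.table(f, sep = "\t", header = FALSE))
    if (!is.numeric(m)) stop("non-numeric cells in file for subject ", id)
    dimnames(m) <- NULL
    m
  })
  names(series) <- subject_ids
  ncols <- vapply(series, ncol, integer(1L))
  if (length(unique(ncols)) > 1L) {
    usual <- as.integer(names(which.max(table(ncols))))
    stop("ROI count mismatch for subject(s): ",
         paste(subject_ids[ncols != usual], collapse = ", "))
  }
  series
}

#' Write a (synthetic) cohort to disk
#'
#' One tab-separated headerless matrix per subject
#' (`<subject_id>.tsv`), plus `phenotypes.csv`, optionally
#' `assignment.csv`, and `ground_truth.json` when ground truth is
#' present.
#'
#' @param cohort A [generate_cohort()] result (or a list with `series`
#'   and `phenotypes`).
#' @param dir Output directory (created if needed).
#' @param assignment Optional node-to-network data frame.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, assignment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$series)) {
    utils::write.table(cohort$series[[id]],
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  if (!is.null(assignment)) {
    utils::write.csv(assignment, file.path(dir, "assignment.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    jsonlite::write_json(
      list(signature_edges = unname(apply(gt$signature_edges, 1L,
                                          as.integer, simplify = FALSE)),
           coupling = gt$coupling,
           scores = gt$scores),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = I(17)
    )
  }
  invisible(dir)
}

#' Motion-based subject exclusion gate
#'
#' Excludes subjects whose head motion exceeds the stated thresholds:
#' mean framewise displacement strictly greater than `max_mean_fd`
#' (a value exactly at the threshold is kept), and — when the optional
#' `translation` / `rotation` columns are present — maximum translation
#' or rotation strictly greater than their thresholds. Reports the
#' Pearson correlation between score and mean FD on the included set,
#' the standard pre-modeling check that motion does not masquerade as
#' behavior.
#'
#' @param phenotypes Data frame with `subject_id`, `score`, `mean_fd`
#'   (and optionally `translation`, `rotation`).
#' @param max_mean_fd Threshold in mm (default 0.2).
#' @param max_translation Threshold in mm (default 3).
#' @param max_rotation Threshold in degrees (default 3).
#' @return List with `included`, `excluded` (subject-id vectors), `r`,
#'   `p_value` of score vs mean FD among the included.
#' @export
motion_gate <- function(phenotypes, max_mean_fd = 0.2,
                        max_translation = 3, max_rotation = 3) {
  if (!"mean_fd" %in% names(phenotypes)) stop("mean_fd column required")
  drop <- phenotypes$mean_fd > max_mean_fd
  if ("translation" %in% names(phenotypes)) {
    drop <- drop | phenotypes$translation > max_translation
  }
  if ("rotation" %in% names(phenotypes)) {
    drop <- drop | phenotypes$rotation > max_rotation
  }
  drop[is.na(drop)] <- TRUE
  if (all(drop)) stop("no subjects survive the motion gate")
  inc <- phenotypes[!drop, , drop = FALSE]
  r <- p <- NA_real_
  if (nrow(inc) >= 4L && stats::sd(inc$score) > 0 &&
      stats::sd(inc$mean_fd) > 0) {
    r <- stats::cor(inc$score, inc$mean_fd)
    p <- .r_to_p(r, nrow(inc), df_loss = 2L)
    if (abs(r) > 0.5) {
      warning("score correlates strongly with head motion (r = ",
              format(r, digits = 3), "); predictions may be confounded")
    }
  }
  list(included = inc$subject_id,
       excluded = phenotypes$subject_id[drop],
       r = r, p_value = p)
}

#' Write a connectome stack as delimited text
#'
#' Subjects x edges values as a tab-separated matrix plus a JSON
#' sidecar (`<path>.json`) recording profile, q, n_rois and the edge
#' index so the stack is self-describing.
#'
#' @param stack A `connectome_stack`.
#' @param path Output path for the value matrix.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(stack, path) {
  stopifnot(inherits(stack, "connectome_stack"))
  utils::write.table(stack$values, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(profile = stack$profile, q = stack$q, n_rois = stack$n_rois,
         method = stack$method, subject_ids = stack$subject_ids,
         edge_index = unname(apply(stack$edge_index, 1L, as.integer,
                                   simplify = FALSE))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17), na = "null"
  )
  invisible(path)
}

#' Read a connectome stack written by [write_connectome()]
#'
#' @param path Path of the value matrix (sidecar `<path>.json` must
#'   exist).
#' @return A `connectome_stack`.
#' @export
read_connectome <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- list(meta$subject_ids, NULL)
  e <- meta$edge_index
  if (is.list(e)) e <- do.call(rbind, e)
  structure(
    list(values = values,
         profile = meta$profile,
         q = if (is.null(meta$q)) NA_real_ else as.numeric(meta$q),
         n_rois = as.integer(meta$n_rois),
         edge_index = matrix(as.integer(e), ncol = 2L,
                             dimnames = list(NULL, c("i", "j"))),
         method = if (is.null(meta$method)) NA_character_ else meta$method,
         subject_ids = meta$subject_ids),
    class = "connectome_stack"
  )
}
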