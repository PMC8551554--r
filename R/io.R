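#' Write a cohort to disk
#'
#' One TSV matrix (channels/regions x samples) plus a JSON sidecar
#' (`fs`, `labels`, `group`, `condition`, `seed`) per subject.
#'
#' @param study A `cohort_study` (see [simulate_group_study]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (subject, group, condition, file).
#' @export
write_cohort <- function(study, dir) {
  stopifnot(inherits(study, "cohort_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (arm in c("hc", "pd_off", "pd_on")) {
    for (obj in study[[arm]]) {
      id <- paste0(obj$meta$subject, "_", tolower(obj$meta$condition))
      file <- file.path(dir, paste0(id, ".tsv"))
      utils::write.table(t(obj$data), file, sep = "\t", row.names = FALSE,
                         col.names = rownames(obj$data))
      side <- list(fs = obj$fs,
                   labels = rownames(obj$data),
                   kind = if (inherits(obj, "recording")) "recording" else "source_activity",
                   group = obj$meta$group, condition = obj$meta$condition,
                   seed = obj$meta$seed)
      jsonlite::write_json(side, file.path(dir, paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = obj$meta$subject, group = obj$meta$group,
        condition = obj$meta$condition, file = basename(file))
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE)
  gt_file <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(study$ground_truth, gt_file, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Read one subject written by [write_cohort]
#'
#' @param path Path to the subject's `.tsv` file (sidecar `.json` expected
#'   alongside).
#' @return A [recording] or [source_activity] according to the sidecar.
#' @export
read_subject <- function(path) {
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path), simplifyVector = TRUE)
  d <- t(as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     check.names = FALSE)))
  meta <- list(group = side$group, condition = side$condition, seed = side$seed)
  if (identical(side$kind, "source_activity")) {
    out <- source_activity(d, side$fs, side$labels)
    out$meta <- meta
    out
  } else {
    recording(d, side$fs, side$labels, meta = meta)
  }
}

#' Write a connectivity matrix as TSV with region-label headers
#'
#' @param cm A `connectivity_matrix`.
#' @param file Output path.
#' @export
write_connectivity_tsv <- function(cm, file) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(cm$values, file, sep = "\t",
                     row.names = TRUE, col.names = NA)
  invisible(file)
}
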