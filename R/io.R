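#' Write a study to the standard on-disk layout
#'
#' Layout: `sessions.tsv` (columns `subject_id`, `dataset_id`, `session_id`,
#' `hc_use`, `cycle_day`, `e2`, `p4`, `mean_fd`; tab-separated, missing cells
#' empty), one `adjacency/<subject>_<session>.tsv` square matrix per session
#' with region labels as header and index column, and `ground_truth.json`
#' when the study carries planted ground truth.
#'
#' @param study An `"fc_study"`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_study <- function(study, dir) {
  stopifnot(inherits(study, "fc_study"))
  dir.create(file.path(dir, "adjacency"), recursive = TRUE, showWarnings = FALSE)
  sess <- study$sessions
  utils::write.table(sess, file.path(dir, "sessions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  for (s in seq_len(nrow(sess))) {
    key <- paste(sess$subject_id[s], sess$session_id[s], sep = "_")
    m <- study$connectomes[[s]]$matrix
    utils::write.table(
      data.frame(region = rownames(m), m, check.names = FALSE),
      file.path(dir, "adjacency", paste0(key, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(study$truth)) {
    truth <- study$truth
    jsonlite::write_json(
      list(
        seed = truth$seed,
        effects = as.list(truth$effects),
        noise_scale = truth$noise_scale,
        individual_offset_scale = truth$individual_offset_scale,
        dataset_offset_scale = truth$dataset_offset_scale,
        masks = lapply(truth$masks, function(e)
          lapply(seq_len(nrow(e)), function(r) c(e[r, 1], e[r, 2])))
      ),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' Load a study written by [save_study()]
#'
#' Validates that every listed session has an adjacency file and that the
#' region labels agree (same set, same order) across all matrices.
#'
#' @param dir Study directory.
#' @return An `"fc_study"`.
#' @export
load_study <- function(dir) {
  sess_path <- file.path(dir, "sessions.tsv")
  if (!file.exists(sess_path)) stop("no sessions.tsv under ", dir)
  sess <- utils::read.delim(sess_path, sep = "\t",
                            na.strings = c("", "n/a", "NA"),
                            colClasses = c(subject_id = "character",
                                           dataset_id = "character",
                                           session_id = "character"))
  connectomes <- vector("list", nrow(sess))
  labels <- NULL
  for (s in seq_len(nrow(sess))) {
    key <- paste(sess$subject_id[s], sess$session_id[s], sep = "_")
    path <- file.path(dir, "adjacency", paste0(key, ".tsv"))
    if (!file.exists(path)) {
      stop("no adjacency matrix for session ", key)
    }
    tab <- utils::read.delim(path, sep = "\t", check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    if (is.null(labels)) {
      labels <- colnames(m)
    } else if (!identical(colnames(m), labels) ||
               !identical(rownames(m), labels)) {
      stop("region labels in ", key, " do not match the first session")
    }
    connectomes[[s]] <- connectome(m, labels)
  }
  names(connectomes) <- paste(sess$subject_id, sess$session_id, sep = "_")

  truth <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    raw <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    masks <- lapply(raw$masks, function(e) {
      e <- if (is.matrix(e)) {
        matrix(as.integer(e), ncol = 2)
      } else {
        matrix(as.integer(unlist(e)), ncol = 2, byrow = TRUE)
      }
      dimnames(e) <- list(NULL, c("i", "j"))
      e
    })
    truth <- list(
      masks = masks,
      mask_ids = lapply(masks, function(e)
        edge_id(e[, 1], e[, 2], length(labels))),
      effects = unlist(raw$effects), seed = raw$seed,
      noise_scale = raw$noise_scale,
      individual_offset_scale = raw$individual_offset_scale,
      dataset_offset_scale = raw$dataset_offset_scale
    )
  }
  structure(
    list(sessions = sess, connectomes = connectomes,
         region_labels = labels, truth = truth),
    class = "fc_study"
  )
}

#' Read a region-to-network label table
#'
#' Expects a TSV with columns `region_id` (0-based), `region_name`,
#' `network_name`, one row per region.
#'
#' @param path File path.
#' @return Data frame with those three columns.
#' @export
read_network_labels <- function(path) {
  tab <- utils::read.delim(path, sep = "\t",
                           na.strings = c("", "n/a", "NA"))
  need <- c("region_id", "region_name", "network_name")
  if (!all(need %in% names(tab))) {
    stop("network label table needs columns: ", paste(need, collapse = ", "))
  }
  tab
}
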