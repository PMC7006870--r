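#' Write a subject to plain-text files
#'
#' Writes three files into `dir`: `<id>_bold.tsv` (rows = voxels, columns =
#' volumes, header row of 0-based volume indices), `<id>_labels.tsv`
#' (`voxel_id`, `froi_name`), and `<id>_truth.json` (ground-truth activity
#' and amplitudes, when present).
#'
#' @param subject A `subject_data` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named list).
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject$subject_id
  bold_path <- file.path(dir, paste0(id, "_bold.tsv"))
  labels_path <- file.path(dir, paste0(id, "_labels.tsv"))
  truth_path <- file.path(dir, paste0(id, "_truth.json"))

  bold_df <- as.data.frame(subject$bold)
  names(bold_df) <- paste0("vol", seq_len(ncol(subject$bold)) - 1L)
  readr::write_tsv(bold_df, bold_path)
  readr::write_tsv(
    tibble(voxel_id = subject$voxels$voxel_id,
           froi_name = subject$voxels$froi),
    labels_path
  )
  truth <- subject$voxels[setdiff(names(subject$voxels), c("froi"))]
  jsonlite::write_json(
    list(subject_id = id, truth = truth),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(bold = bold_path, labels = labels_path, truth = truth_path))
}

#' Read a subject from plain-text files
#'
#' Reads the BOLD matrix and voxel labels written by [write_subject()] (or
#' prepared externally in the same layout). The label file's voxel order is
#' authoritative. Handles UTF-8 BOMs and CRLF line endings.
#'
#' @param bold_path TSV of BOLD values, voxels x volumes, with a header row.
#' @param labels_path Two-column TSV `voxel_id`, `froi_name`.
#' @param truth_path Optional JSON sidecar with ground truth.
#' @param subject_id Identifier; defaults to the bold file name stem.
#' @return A `subject_data` object.
#' @export
read_subject <- function(bold_path, labels_path, truth_path = NULL,
                         subject_id = sub("_bold\\.tsv$", "", basename(bold_path))) {
  bold_df <- readr::read_tsv(bold_path, show_col_types = FALSE, progress = FALSE)
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("voxel_id", "froi_name") %in% names(labels))) {
    abort_langcore("Labels file needs columns `voxel_id` and `froi_name`.",
                   "invalid_input")
  }
  if (anyDuplicated(labels$voxel_id)) {
    abort_langcore("Duplicate voxel ids in labels file.", "invalid_input")
  }
  if (nrow(bold_df) != nrow(labels)) {
    abort_langcore(sprintf(
      "Row-count mismatch: %d BOLD rows vs %d labelled voxels.",
      nrow(bold_df), nrow(labels)
    ), "invalid_input")
  }
  bold <- as.matrix(bold_df)
  dimnames(bold) <- NULL
  voxels <- tibble(voxel_id = labels$voxel_id, froi = labels$froi_name)
  if (!is.null(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)$truth
    if (!all(truth$voxel_id == voxels$voxel_id)) {
      abort_langcore("Truth sidecar voxel ids do not match the labels file.",
                     "invalid_input")
    }
    voxels$truth_active <- truth$truth_active
    voxels$truth_beta <- truth$truth_beta
  }
  structure(
    list(subject_id = subject_id, bold = bold, voxels = voxels),
    class = "subject_data"
  )
}

#' Write a network as an edge-list TSV (plus nodes) and GraphML
#'
#' @param net A `voxel_network`, `froi_network`, or `common_network`.
#' @param path_prefix File path prefix; `_edges.tsv`, `_nodes.tsv` and
#'   `.graphml` are appended.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, path_prefix) {
  edges <- tidy(net)
  nodes <- as_tibble(net$nodes)
  readr::write_tsv(edges, paste0(path_prefix, "_edges.tsv"))
  readr::write_tsv(nodes, paste0(path_prefix, "_nodes.tsv"))
  name_col <- names(nodes)[1L]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = as.data.frame(nodes[, c(name_col, setdiff(names(nodes), name_col))])
  )
  graphml <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  invisible(list(edges = paste0(path_prefix, "_edges.tsv"),
                 nodes = paste0(path_prefix, "_nodes.tsv"),
                 graphml = graphml))
}
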