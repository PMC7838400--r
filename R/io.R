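#' Read and write node tables as CSV
#'
#' The on-disk format has columns
#' `node_id,x,y,z,module,hemisphere`.
#'
#' @param node_table A `node_table`.
#' @param path File path.
#' @return `read_node_table()` returns a `node_table`;
#'   `write_node_table()` returns `path` invisibly.
#' @export
write_node_table <- function(node_table, path) {
  utils::write.csv(as.data.frame(node_table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("node_id", "x", "y", "z", "module", "hemisphere")
  if (!all(needed %in% names(df))) {
    stop_invalid("node table must have columns %s", paste(needed, collapse = ","))
  }
  df$node_id <- as.integer(df$node_id)
  df$module <- as.integer(df$module)
  class(df) <- c("node_table", "data.frame")
  df
}

#' Read and write connectome matrices as CSV
#'
#' Matrices are stored with node ids as header row and first column.
#'
#' @param conn A [connectome()].
#' @param path File path.
#' @param subject_id,group,mask_id Metadata to attach when reading (CSV
#'   stores only the matrix).
#' @return `read_connectome()` returns a [connectome()];
#'   `write_connectome()` returns `path` invisibly.
#' @export
write_connectome <- function(conn, path) {
  utils::write.csv(conn$z, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, subject_id = NA_character_, group = "HC",
                            mask_id = NA_character_) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  z <- as.matrix(df)
  connectome(z, retained_nodes = as.integer(rownames(df)),
             subject_id = subject_id, group = group, mask_id = mask_id)
}

#' Read and write node-form lesion masks as CSV
#'
#' One lesioned node id per row, column `node_id`.
#'
#' @param mask A node-form [lesion_mask()].
#' @param path File path.
#' @param mask_id Mask id to attach when reading.
#' @return `read_lesion_mask_csv()` returns a node-form [lesion_mask()].
#' @export
write_lesion_mask_csv <- function(mask, path) {
  if (mask$form != "nodes") stop_invalid("only node-form masks are written as CSV")
  utils::write.csv(data.frame(node_id = mask$nodes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lesion_mask_csv
#' @export
read_lesion_mask_csv <- function(path, mask_id = basename(path)) {
  df <- utils::read.csv(path)
  lesion_mask(mask_id, nodes = df$node_id)
}

#' Read and write voxel-form lesion masks as NIfTI
#'
#' @param mask A voxel-form [lesion_mask()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param mask_id Mask id to attach when reading.
#' @return `read_lesion_mask_nifti()` returns a voxel-form
#'   [lesion_mask()].
#' @export
write_lesion_mask_nifti <- function(mask, path) {
  if (mask$form != "voxel") stop_invalid("only voxel-form masks are written as NIfTI")
  img <- RNifti::asNifti(mask$data)
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_lesion_mask_nifti
#' @export
read_lesion_mask_nifti <- function(path, mask_id = basename(path)) {
  img <- RNifti::readNifti(path)
  affine <- structure(RNifti::xform(img), class = NULL)
  data <- array(as.integer(as.array(img) != 0), dim = dim(img))
  lesion_mask(mask_id, data = data, affine = matrix(affine, 4, 4))
}

#' Write a cohort to per-subject CSVs plus a JSON manifest
#'
#' @param cohort A `cohort` from [generate_connectome_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$connectomes, function(cn) {
    f <- file.path(dir, paste0(cn$subject_id, ".csv"))
    write_connectome(cn, f)
    basename(f)
  }, character(1))
  manifest <- list(
    subjects = data.frame(
      subject_id = vapply(cohort$connectomes, `[[`, "", "subject_id"),
      group = vapply(cohort$connectomes, `[[`, "", "group"),
      file = files, stringsAsFactors = FALSE),
    params = unclass(cohort$params),
    planted_global = cohort$planted_global,
    planted_local = cohort$planted_local)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  write_node_table(cohort$node_table, file.path(dir, "node_table.csv"))
  invisible(path)
}
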