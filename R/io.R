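DATASET_FORMAT_VERSION <- "1.0"

#' Write a dataset to its on-disk layout
#'
#' Canonical plain-text layout: one directory per subject holding
#' `manifest.json` (format version, design, conditions, seeds/provenance),
#' `geometry.tsv`, and per-run TSV matrices under `bold/`, `downstream/`
#' and `nuisance/`; ground truth, when present, goes to
#' `ground_truth.json`. The round trip is lossless to full double
#' precision.
#'
#' @param ds A `bg_dataset`.
#' @param path Directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "bg_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (d in c("bold", "downstream", "nuisance")) {
    dir.create(file.path(path, d), showWarnings = FALSE)
  }
  manifest <- list(format_version = DATASET_FORMAT_VERSION,
                   subject_id = ds$subject_id,
                   design = unclass(ds$design)[c("tr", "block_s", "fix_s",
                                                 "n_cycles",
                                                 "n_runs_per_condition")],
                   condition = ds$condition, run_type = ds$run_type,
                   areas = rownames(ds$downstream[[1]]))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(ds$geometry, file.path(path, "geometry.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  wmat <- function(m, f) {
    utils::write.table(format(m, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       f, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  for (r in seq_along(ds$bold)) {
    wmat(ds$bold[[r]], file.path(path, "bold", sprintf("run_%02d.tsv", r)))
    wmat(ds$downstream[[r]],
         file.path(path, "downstream", sprintf("run_%02d.tsv", r)))
    wmat(ds$nuisance[[r]],
         file.path(path, "nuisance", sprintf("run_%02d.tsv", r)))
  }
  if (!is.null(ds$ground_truth)) {
    gt <- ds$ground_truth
    if (is.matrix(gt$coupling_gain)) {
      gt$coupling_gain <- list(bin = rownames(gt$coupling_gain),
                               focal = unname(gt$coupling_gain[, "focal"]),
                               diffused = unname(gt$coupling_gain[, "diffused"]))
    }
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a dataset from its on-disk layout
#'
#' @param path Directory written by [write_dataset()].
#' @return A `bg_dataset`.
#' @export
read_dataset <- function(path) {
  need <- c("manifest.json", "geometry.tsv", "bold", "downstream",
            "nuisance")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("dataset at '", path, "' is missing ", f)
    }
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (is.null(manifest$format_version)) stop("manifest lacks format_version")
  if (manifest$format_version != DATASET_FORMAT_VERSION) {
    warning("dataset format version ", manifest$format_version,
            " read by reader for ", DATASET_FORMAT_VERSION)
  }
  known <- c(need, "ground_truth.json")
  extra <- setdiff(list.files(path), known)
  if (length(extra) > 0) {
    warning("ignoring unknown entries: ", paste(extra, collapse = ", "))
  }
  d <- manifest$design
  design <- design_spec(d$tr, d$block_s, d$fix_s, d$n_cycles,
                        d$n_runs_per_condition)
  geometry <- utils::read.table(file.path(path, "geometry.tsv"),
                                header = TRUE, sep = "\t")
  class(geometry) <- c("vertex_geometry", "data.frame")
  rmat <- function(f) {
    m <- as.matrix(utils::read.table(f, sep = "\t"))
    dimnames(m) <- NULL
    m
  }
  runs <- sort(list.files(file.path(path, "bold"), pattern = "^run_"))
  bold <- downstream <- nuisance <- vector("list", length(runs))
  for (r in seq_along(runs)) {
    bold[[r]] <- rmat(file.path(path, "bold", runs[r]))
    dw <- rmat(file.path(path, "downstream", runs[r]))
    rownames(dw) <- manifest$areas
    downstream[[r]] <- dw
    nu <- rmat(file.path(path, "nuisance", runs[r]))
    colnames(nu) <- c(paste0("motion", 1:6), "wm", "ventricle")[seq_len(ncol(nu))]
    nuisance[[r]] <- nu
    if (ncol(bold[[r]]) != nrow(nuisance[[r]]) ||
        ncol(dw) != ncol(bold[[r]])) {
      stop("shape mismatch in ", file.path(path, "bold", runs[r]))
    }
  }
  gt <- NULL
  gt_path <- file.path(path, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    if (!is.null(gt$coupling_gain)) {
      cg <- gt$coupling_gain
      gt$coupling_gain <- cbind(focal = cg$focal, diffused = cg$diffused)
      rownames(gt$coupling_gain) <- cg$bin
    }
  }
  structure(list(bold = bold, downstream = downstream,
                 nuisance = nuisance, condition = manifest$condition,
                 run_type = manifest$run_type, geometry = geometry,
                 design = design, subject_id = manifest$subject_id,
                 ground_truth = gt),
            class = "bg_dataset")
}

#' Import a volumetric NIfTI time series as a dataset
#'
#' Bridge for real data: reads a 4-D NIfTI BOLD series and a 3-D mask (node
#' = voxel inside the mask), a geometry table giving eccentricity and polar
#' angle per node, per-run nuisance TSVs (time x 8), and downstream area
#' mean series as a TSV. Requires the `RNifti` package.
#'
#' @param bold_paths Character vector of per-run 4-D NIfTI files.
#' @param mask_path 3-D NIfTI mask (> 0 inside).
#' @param geometry data.frame with `eccentricity` and `polar_angle` per
#'   in-mask voxel (mask order).
#' @param nuisance_paths Per-run nuisance TSVs (time x 8, no header).
#' @param downstream_paths Per-run TSVs of area x time downstream series.
#' @param design A [design_spec()].
#' @param condition,run_type Per-run labels.
#' @param subject_id Identifier.
#' @return A `bg_dataset`.
#' @export
import_nifti <- function(bold_paths, mask_path, geometry, nuisance_paths,
                         downstream_paths, design,
                         condition, run_type = rep("main",
                                                   length(bold_paths)),
                         subject_id = "imported") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI import requires the RNifti package")
  }
  mask <- RNifti::readNifti(mask_path) > 0
  n_nodes <- sum(mask)
  if (nrow(geometry) != n_nodes) {
    stop("geometry rows (", nrow(geometry), ") != in-mask voxels (",
         n_nodes, ")")
  }
  stopifnot(length(bold_paths) == length(nuisance_paths),
            length(bold_paths) == length(downstream_paths),
            length(bold_paths) == length(condition))
  bold <- downstream <- nuisance <- vector("list", length(bold_paths))
  for (r in seq_along(bold_paths)) {
    img <- RNifti::readNifti(bold_paths[r])
    if (length(dim(img)) != 4 || !all(dim(img)[1:3] == dim(mask))) {
      stop("BOLD/mask shape mismatch in ", bold_paths[r])
    }
    T <- dim(img)[4]
    mat <- matrix(img, prod(dim(mask)), T)[as.vector(mask), , drop = FALSE]
    bold[[r]] <- mat
    X <- as.matrix(utils::read.table(nuisance_paths[r], sep = "\t"))
    if (nrow(X) != T || ncol(X) != 8) {
      stop("nuisance file ", nuisance_paths[r], " must be time x 8")
    }
    nuisance[[r]] <- X
    dw <- as.matrix(utils::read.table(downstream_paths[r], sep = "\t",
                                      row.names = 1))
    if (ncol(dw) != T) stop("downstream/time mismatch in ",
                            downstream_paths[r])
    downstream[[r]] <- dw
  }
  geometry$node_id <- seq_len(n_nodes) - 1L
  if (is.null(geometry$is_stimulated_truth)) {
    geometry$is_stimulated_truth <- NA
  }
  class(geometry) <- c("vertex_geometry", "data.frame")
  structure(list(bold = bold, downstream = downstream,
                 nuisance = nuisance, condition = condition,
                 run_type = run_type, geometry = geometry,
                 design = design, subject_id = subject_id,
                 ground_truth = NULL),
            class = "bg_dataset")
}
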