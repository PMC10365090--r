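# Assembly of per-lesion feature vectors into cohort tables, normalization
# and omics merging. Column order is owned by the pinned registry.

#' Extraction configuration
#'
#' @param target_spacing_mm isotropic resampling target (default 1 mm)
#' @param gray_levels quantization ladder (default 8,16,24,32,40,48,64)
#' @param gabor a [gabor_bank_config()]
#' @param doh_threshold blob-detector threshold, HU^2
#' @export
extraction_config <- function(target_spacing_mm = 1,
                              gray_levels = default_gray_levels(),
                              gabor = gabor_bank_config(),
                              doh_threshold = 50) {
  structure(list(target_spacing_mm = target_spacing_mm,
                 gray_levels = as.integer(gray_levels),
                 gabor = gabor, doh_threshold = doh_threshold),
            class = "extraction_config")
}

#' Extract the full 342-feature radiomic vector for one lesion
#'
#' Runs resampling, quantization at every gray-level count, and all feature
#' families, then assembles the values in registry order. Deterministic for
#' fixed input; errors (naming the family) rather than returning NaN.
#'
#' @param volume a [ct_volume()]
#' @param mask a [segmentation_mask()]
#' @param config an [extraction_config()]
#' @return named numeric vector of length 342 in registry order
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  reg <- feature_registry()
  roi <- resample_isotropic(volume, mask, config$target_spacing_mm)
  roi_mask <- structure(list(labels = roi$mask,
                             spacing_mm = rep(roi$spacing_mm, 3),
                             origin_mm = c(0, 0, 0)),
                        class = "segmentation_mask")
  vals <- c(
    with_family("size", size_shape(roi_mask)),
    with_family("moments", moment_invariants(roi_mask)),
    with_family("skeleton", skeleton_features(roi_mask)),
    with_family("dist", radial_distance_features(roi_mask)),
    c(lacunarity = with_family("lacunarity", lacunarity(roi_mask)$slope)),
    with_family("first_order", first_order(roi))
  )
  for (G in config$gray_levels) {
    q <- suppressWarnings(quantize_equal_probability(roi, G))
    tex <- c(with_family("glcm", glcm_features(q)),
             with_family("glrlm", glrlm_features(q)),
             with_family("glszm", glszm_features(q)),
             with_family("ngtdm", ngtdm_features(q)))
    names(tex) <- paste0(names(tex), "_G", G)
    vals <- c(vals, tex)
  }
  vals <- c(vals,
            with_family("gabor", gabor_features(roi, config$gabor)),
            with_family("fourier", fourier_features(roi)),
            with_family("descriptors",
                        keypoint_gradient_features(roi, config$doh_threshold)))
  out <- vals[reg$name]
  bad <- reg$name[!is.finite(out)]
  if (length(bad) > 0)
    stopf("feature extraction produced non-finite values for: %s",
          paste(bad, collapse = ", "))
  names(out) <- reg$name
  out
}

with_family <- function(family, expr) {
  tryCatch(expr, error = function(e)
    stopf("feature family '%s' failed: %s", family, conditionMessage(e)))
}

#' Cohort feature table
#'
#' @param x numeric matrix, subjects x features, with rownames (subject ids)
#'   and colnames (feature names)
#' @param labels data.frame of per-subject label columns (same row order)
#' @param provenance character vector, one of "radiomic", "gene", "hotcold"
#'   per column
#' @param constant_flags logical vector marking columns zeroed because they
#'   were constant at normalization
#' @export
feature_table <- function(x, labels = NULL,
                          provenance = rep("radiomic", ncol(x)),
                          constant_flags = rep(FALSE, ncol(x))) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (anyNA(x)) stopf("feature table contains missing values")
  structure(list(x = x, labels = labels,
                 provenance = setNames(provenance, colnames(x)),
                 constant_flags = setNames(constant_flags, colnames(x))),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(table(x$provenance)),
                            table(x$provenance)), collapse = ", ")))
  invisible(x)
}

#' Z-score normalize a feature table
#'
#' Each non-constant column is centred and scaled to unit SD using this
#' table's own statistics — training and validation tables are normalized
#' independently, matching the separate-normalization protocol. Constant
#' columns are set to 0 and flagged.
#'
#' @param table a [feature_table()]
#' @return normalized [feature_table()]
#' @export
zscore_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  const <- !is.finite(sdev) | sdev == 0
  x <- sweep(x, 2, mu, `-`)
  x[, !const] <- sweep(x[, !const, drop = FALSE], 2, sdev[!const], `/`)
  x[, const] <- 0
  feature_table(x, labels = table$labels, provenance = table$provenance,
                constant_flags = const)
}

#' Merge omics columns into a radiomic feature table
#'
#' Inner join on subject ids. `omics` is either a numeric matrix of gene
#' log-expression (subjects x genes, rownames = ids) or a named binary
#' vector of HOT/COLD status (merged as the single column `hotcold`).
#'
#' @param radiomic a [feature_table()]
#' @param omics expression matrix or named hotcold vector
#' @return merged [feature_table()] with provenance flags set
#' @export
merge_omics <- function(radiomic, omics) {
  stopifnot(inherits(radiomic, "feature_table"))
  if (is.matrix(omics)) {
    ids <- intersect(rownames(radiomic$x), rownames(omics))
    if (length(ids) == 0) stopf("no common subject ids between tables")
    extra <- omics[ids, , drop = FALSE]
    prov <- rep("gene", ncol(extra))
  } else {
    if (is.null(names(omics))) stopf("hotcold labels must be named by subject")
    ids <- intersect(rownames(radiomic$x), names(omics))
    if (length(ids) == 0) stopf("no common subject ids between tables")
    extra <- matrix(as.numeric(omics[ids]), ncol = 1,
                    dimnames = list(ids, "hotcold"))
    prov <- "hotcold"
  }
  keep <- match(ids, rownames(radiomic$x))
  x <- cbind(radiomic$x[keep, , drop = FALSE], extra)
  labels <- if (!is.null(radiomic$labels))
    radiomic$labels[keep, , drop = FALSE] else NULL
  feature_table(x, labels = labels,
                provenance = c(unname(radiomic$provenance[colnames(radiomic$x)]),
                               prov),
                constant_flags = c(radiomic$constant_flags[colnames(radiomic$x)],
                                   setNames(rep(FALSE, ncol(extra)),
                                            colnames(extra))))
}

#' Build a feature table from a synthetic cohort
#'
#' @param cohort output of [generate_cohort()]
#' @param config an [extraction_config()]
#' @param verbose print progress
#' @return a [feature_table()] with `dc` and `hotcold` label columns
#' @export
cohort_feature_table <- function(cohort, config = extraction_config(),
                                 verbose = FALSE) {
  vecs <- lapply(seq_along(cohort), function(i) {
    s <- cohort[[i]]
    if (verbose && i %% 10 == 0) message("  extracted ", i, "/",
                                         length(cohort))
    extract_all(s$volume, s$mask, config)
  })
  x <- do.call(rbind, vecs)
  rownames(x) <- vapply(cohort, `[[`, character(1), "subject_id")
  labels <- data.frame(
    dc = vapply(cohort, `[[`, integer(1), "dc_label"),
    hotcold = vapply(cohort, `[[`, integer(1), "hotcold_label"),
    row.names = rownames(x))
  feature_table(x, labels = labels)
}

#' Write / read a feature table as TSV with a JSON sidecar manifest
#'
#' @param table a [feature_table()]
#' @param path output `.tsv` path; the manifest goes to `<path>.manifest.json`
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = rownames(table$x), table$x,
                   check.names = FALSE)
  if (!is.null(table$labels)) df <- cbind(df, table$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(registry_hash = feature_registry_hash(),
                   n_features = ncol(table$x),
                   provenance = as.list(table(table$provenance)),
                   package_version = as.character(packageVersion("radiomix")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param label_cols names of label columns in the file
#' @export
read_feature_table <- function(path, label_cols = c("dc", "hotcold")) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- df$subject_id
  labs <- intersect(label_cols, colnames(df))
  x <- as.matrix(df[, setdiff(colnames(df), c("subject_id", labs)),
                    drop = FALSE])
  rownames(x) <- ids
  labels <- if (length(labs) > 0)
    data.frame(df[, labs, drop = FALSE], row.names = ids) else NULL
  feature_table(x, labels = labels)
}
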