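# Formula x sample dataset assembly, subsetting, and TSV round-trip.

#' Sample metadata constructor and validator
#'
#' @param sample_id Unique sample labels.
#' @param catchment Catchment labels.
#' @param position Hillslope position, one of shoulder, back, foot, toe,
#'   stream.
#' @param depth_cm Soil sampling depth (5, 15, 30 or 60 cm); `NA` for
#'   stream samples.
#' @param sample_type "soil" or "stream". Stream samples must have `NA`
#'   depth; soil samples must have a depth.
#' @return Validated data frame of sample metadata.
#' @export
sample_metadata <- function(sample_id, catchment, position, depth_cm,
                            sample_type) {
  md <- data.frame(sample_id = as.character(sample_id),
                   catchment = as.character(catchment),
                   position = as.character(position),
                   depth_cm = as.numeric(depth_cm),
                   sample_type = as.character(sample_type),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_pos <- setdiff(md$position, c("shoulder", "back", "foot", "toe", "stream"))
  if (length(bad_pos)) {
    stop("unknown position label(s): ", paste(bad_pos, collapse = ", "),
         call. = FALSE)
  }
  if (any(md$sample_type == "stream" & !is.na(md$depth_cm))) {
    stop("stream samples must not carry a depth", call. = FALSE)
  }
  if (any(md$sample_type == "soil" & is.na(md$depth_cm))) {
    stop("soil samples must carry a depth", call. = FALSE)
  }
  md
}

#' Build a formula x sample DOM dataset
#'
#' Unions the formulas of the per-sample tables (canonical formula string as
#' the join key), computes descriptors and compound classes once per
#' formula, and stores normalised intensities in a dense formula x sample
#' matrix (0 = not detected).
#'
#' @param tables Named list of per-sample data frames with columns formula
#'   and intensity; names are sample ids.
#' @param metadata Data frame as from [sample_metadata()]; its sample_id set
#'   must match `names(tables)` exactly.
#' @param class_table Compound-class boundary table for [classify()].
#' @return A `dom_dataset`: list with `formulas` (annotation data frame,
#'   one row per formula), `samples` (metadata, ordered as the matrix
#'   columns) and `intensity` (matrix, rownames = formula strings,
#'   colnames = sample ids).
#' @export
build_dataset <- function(tables, metadata,
                          class_table = default_class_table()) {
  ids <- names(tables)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("per-sample tables must be uniquely named by sample_id", call. = FALSE)
  }
  orphans <- c(setdiff(ids, metadata$sample_id), setdiff(metadata$sample_id, ids))
  if (length(orphans)) {
    stop("sample ids not matched between tables and metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  all_f <- sort(unique(unlist(lapply(tables, function(t) t$formula))))
  mat <- matrix(0, nrow = length(all_f), ncol = length(ids),
                dimnames = list(all_f, ids))
  for (s in ids) {
    t <- tables[[s]]
    if (anyDuplicated(t$formula)) {
      stop("duplicate formula rows in sample ", s, call. = FALSE)
    }
    mat[t$formula, s] <- t$intensity
  }
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  ann <- annotate_formulas(rownames(mat), table = class_table)
  structure(list(formulas = ann, samples = metadata, intensity = mat),
            class = "dom_dataset")
}

#' @export
print.dom_dataset <- function(x, ...) {
  cat("DOM dataset:", nrow(x$intensity), "formulas x",
      ncol(x$intensity), "samples\n")
  cat("classes:",
      paste(names(sort(table(x$formulas$compound_class), decreasing = TRUE)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Subset a DOM dataset
#'
#' Filters rows (formulas) and/or columns (samples). Intensities are
#' deliberately NOT renormalised: group relative abundances and weighted
#' masses are defined on the original per-sample normalised intensities, so
#' the share of a subset is the sum of its members' original intensities.
#' Formula rows that become all-zero after a sample subset are dropped to
#' preserve presence semantics.
#'
#' @param ds A `dom_dataset`.
#' @param formulas Logical/integer index over formula rows, a character
#'   vector of formula strings, or a predicate function over the `formulas`
#'   annotation data frame returning a logical vector.
#' @param samples Logical/integer index over samples, a character vector of
#'   sample ids, or a predicate function over the `samples` metadata.
#' @return A `dom_dataset`; empty subsets warn.
#' @export
subset_dataset <- function(ds, formulas = NULL, samples = NULL) {
  fi <- seq_len(nrow(ds$intensity))
  si <- seq_len(ncol(ds$intensity))
  if (!is.null(formulas)) {
    fi <- if (is.function(formulas)) which(formulas(ds$formulas))
          else if (is.character(formulas)) which(ds$formulas$formula %in% formulas)
          else which(seq_len(nrow(ds$intensity)) %in% seq_len(nrow(ds$intensity))[formulas])
  }
  if (!is.null(samples)) {
    si <- if (is.function(samples)) which(samples(ds$samples))
          else if (is.character(samples)) which(ds$samples$sample_id %in% samples)
          else which(seq_len(ncol(ds$intensity)) %in% seq_len(ncol(ds$intensity))[samples])
  }
  mat <- ds$intensity[fi, si, drop = FALSE]
  keep <- rowSums(mat) > 0
  mat <- mat[keep, , drop = FALSE]
  out <- structure(list(
    formulas = ds$formulas[fi, , drop = FALSE][keep, , drop = FALSE],
    samples = ds$samples[si, , drop = FALSE],
    intensity = mat), class = "dom_dataset")
  rownames(out$formulas) <- NULL
  rownames(out$samples) <- NULL
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    warning("subset produced an empty dataset", call. = FALSE)
  }
  out
}

#' Write a DOM dataset to TSV files
#'
#' Long-format intensities (sample_id, formula, intensity; zero cells
#' omitted) and the sample metadata, both UTF-8 with "." decimal.
#'
#' @param ds A `dom_dataset`.
#' @param data_path,metadata_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(ds, data_path, metadata_path) {
  idx <- which(ds$intensity > 0, arr.ind = TRUE)
  long <- data.frame(
    sample_id = colnames(ds$intensity)[idx[, 2]],
    formula = rownames(ds$intensity)[idx[, 1]],
    intensity = ds$intensity[idx],
    stringsAsFactors = FALSE)
  long <- long[order(long$sample_id, long$formula), ]
  long$intensity <- formatC(long$intensity, digits = 17, format = "g")
  utils::write.table(long, data_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(data_path, metadata_path))
}

#' Read a DOM dataset from TSV files written by [write_dataset()]
#'
#' @param data_path,metadata_path Input TSV paths.
#' @param class_table Compound-class boundary table.
#' @return A `dom_dataset`.
#' @export
read_dataset <- function(data_path, metadata_path,
                         class_table = default_class_table()) {
  long <- utils::read.table(data_path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character", "numeric"))
  md <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  md <- sample_metadata(md$sample_id, md$catchment, md$position,
                        md$depth_cm, md$sample_type)
  tables <- split(long[, c("formula", "intensity")], long$sample_id)
  build_dataset(tables, md, class_table = class_table)
}
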