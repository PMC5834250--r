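#' Gene expression matrix (GEM) with per-sample condition labels
#'
#' A GEM is the pipeline's universal currency: a transcripts x samples
#' matrix of non-negative expression values (FPKM/RPKM scale when raw,
#' or log2 quantile-normalized after preprocessing), together with a
#' condition label for every sample and a tag recording the scale.
#'
#' @param values numeric matrix, rows = transcripts, columns = samples;
#'   rownames and colnames are the transcript and sample IDs.
#' @param condition named character vector mapping sample ID -> condition
#'   label; must cover every column of `values`. An unnamed vector of
#'   `ncol(values)` labels in column order is also accepted.
#' @param scale_tag `"raw"` or `"log2_quantile"`.
#'
#' @return An object of class `"gem"`: a list with elements `values`
#'   (the matrix), `condition` (named character, one per sample, in
#'   column order) and `scale_tag`.
#' @export
gem <- function(values, condition, scale_tag = c("raw", "log2_quantile")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry transcript rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate transcript ID: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ID: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)))
    stop("GEM values must be finite")
  if (scale_tag == "raw" && any(values < 0))
    stop("raw GEM values must be >= 0")
  if (is.null(names(condition))) {
    if (length(condition) != ncol(values))
      stop("unnamed 'condition' must have one label per sample")
    names(condition) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(condition))
  if (length(missing))
    stop("sample missing from annotation: ", missing[1L])
  condition <- stats::setNames(as.character(condition[colnames(values)]),
                               colnames(values))
  structure(
    list(values = values, condition = condition, scale_tag = scale_tag),
    class = "gem")
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("GEM: %d transcripts x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_tag))
  tab <- table(x$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' Transcript and sample accessors
#' @param gem a [gem] object.
#' @return character vectors of IDs.
#' @export
transcript_ids <- function(gem) rownames(gem$values)

#' @rdname transcript_ids
#' @export
sample_ids <- function(gem) colnames(gem$values)

#' Read a GEM and its sample annotation from TSV files
#'
#' The matrix file is tab-separated with a header row of sample IDs and
#' transcript IDs in the first column. The annotation file has two
#' columns, `sample_id` and `condition` (header optional but
#' recommended).
#'
#' @param path path to the expression TSV.
#' @param annotation_path path to the two-column sample annotation TSV.
#' @param scale_tag scale of the stored values, `"raw"` by default.
#' @return a [gem] object.
#' @export
read_gem <- function(path, annotation_path, scale_tag = "raw") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression TSV needs an ID column and >= 1 sample")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop("annotation TSV needs sample_id and condition columns")
  cond <- stats::setNames(as.character(ann[[2L]]), as.character(ann[[1L]]))
  gem(m, cond, scale_tag = scale_tag)
}

#' Write a GEM (and optionally its annotation) to TSV
#'
#' Values are printed with 15 significant digits so that a
#' read-after-write round trip reproduces the GEM to printed precision.
#'
#' @param gem a [gem] object.
#' @param path output path for the expression TSV.
#' @param annotation_path optional output path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_gem <- function(gem, path, annotation_path = NULL) {
  stopifnot(inherits(gem, "gem"))
  m <- gem$values
  df <- data.frame(transcript_id = rownames(m),
                   signif(m, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("transcript_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = colnames(m),
                      condition = gem$condition,
                      stringsAsFactors = FALSE)
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Subset a GEM by transcripts and/or samples
#'
#' @param gem a [gem] object.
#' @param transcripts,samples character vectors of IDs (or NULL for all).
#' @return a [gem] with the selected rows/columns, labels carried along.
#' @export
subset_gem <- function(gem, transcripts = NULL, samples = NULL) {
  stopifnot(inherits(gem, "gem"))
  m <- gem$values
  if (!is.null(transcripts)) m <- m[transcripts, , drop = FALSE]
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (nrow(m) == 0L || ncol(m) == 0L) stop("subset is empty")
  gem(m, gem$condition[colnames(m)], scale_tag = gem$scale_tag)
}
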