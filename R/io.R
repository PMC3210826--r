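## Plain-text readers and writers: TSV expression matrices (probes in rows,
## reserved annotation columns), design CSV, round-trip lossless for finite
## values. UTF-8, tab-separated, '.' decimal, identifiers unquoted.

.reservedAnnotation <- c("negative_control", "target")

#' Read an expression TSV
#'
#' First column = probe identifiers (must be unique); optional reserved
#' annotation columns `negative_control` (0/1 or TRUE/FALSE) and `target`;
#' all remaining columns are numeric sample intensities. Duplicate probe
#' identifiers and non-numeric cells are errors that name the offender.
#'
#' @param path TSV file path.
#' @param assayName Name for the single assay. Default `"exprs"`.
#' @return An [ArrayExperiment].
#' @export
readExpressionTsv <- function(path, assayName = "exprs") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "NA")
  ids <- as.character(d[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate probe identifiers: ", paste(dup, collapse = ", "))
  ann <- intersect(.reservedAnnotation, colnames(d))
  sampleCols <- setdiff(colnames(d)[-1], ann)
  vals <- matrix(NA_real_, length(ids), length(sampleCols),
                 dimnames = list(ids, sampleCols))
  for (j in sampleCols) {
    col <- d[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(col) != "NA")
    if (length(bad))
      stop("non-numeric cell at row ", bad[1], " (probe '", ids[bad[1]],
           "'), column '", j, "': '", col[bad[1]], "'")
    vals[, j] <- num
  }
  rd <- S4Vectors::DataFrame(row.names = ids)
  if ("negative_control" %in% ann)
    rd$negativeControl <- as.logical(d$negative_control)
  if ("target" %in% ann) {
    tg <- as.character(d$target)
    tg[!nzchar(tg)] <- NA_character_
    rd$target <- tg
  }
  ArrayExperiment(stats::setNames(list(vals), assayName), rowData = rd)
}

#' Write an expression TSV
#'
#' Inverse of [readExpressionTsv]: probe identifiers, any reserved
#' annotation columns present, then sample columns. Numeric values are
#' written with 17 significant digits so finite values round-trip exactly.
#'
#' @param x An [ArrayExperiment].
#' @param path Output path.
#' @param assay Assay to write.
#' @return The path, invisibly.
#' @export
writeExpressionTsv <- function(x, path, assay = 1L) {
  m <- .assayMatrix(x, assay)
  out <- data.frame(probe = rownames(m), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(x)
  if ("negativeControl" %in% colnames(rd))
    out$negative_control <- as.integer(rd$negativeControl)
  if ("target" %in% colnames(rd)) {
    tg <- as.character(rd$target)
    tg[is.na(tg)] <- ""
    out$target <- tg
  }
  for (j in colnames(m))
    out[[j]] <- ifelse(is.na(m[, j]), "NA",
                       formatC(m[, j], digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample design CSV
#'
#' Requires columns `sample` and `group`; extra columns (array, dye,
#' inclusion flags) are carried along.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
readDesignCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(d)))
    stop("design table must contain columns 'sample' and 'group'")
  d
}

#' Attach a design table to an experiment
#'
#' Matches `design$sample` against the experiment's sample names; every
#' sample of the matrix must appear in the design (and vice versa).
#'
#' @param x An [ArrayExperiment].
#' @param design A design data.frame (see [readDesignCsv]).
#' @return `x` with the design merged into `colData`.
#' @export
attachDesign <- function(x, design) {
  missing <- setdiff(colnames(x), design$sample)
  if (length(missing))
    stop("design table lacks sample(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(design$sample, colnames(x))
  if (length(unknown))
    stop("design table has unknown sample(s): ",
         paste(unknown, collapse = ", "))
  design <- design[match(colnames(x), design$sample), , drop = FALSE]
  SummarizedExperiment::colData(x) <- S4Vectors::DataFrame(
    design, row.names = design$sample)
  x
}
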