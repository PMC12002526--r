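#' @include AllClasses.R
NULL

#' Read a sample-by-taxon count table
#'
#' Expects a header row of taxon identifiers and a first column of sample
#' identifiers (the common OTU-table export layout). Tab-separated by
#' default, comma-separated with `dialect = "csv"`. Input row and column
#' order is preserved; malformed cells are reported by name.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return a [CountTable-class].
#' @export
readCountTable <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           comment.char = "", quote = "")
  if (ncol(raw) < 2L) stop("table must have a sample-id column and >= 1 taxon column",
                           call. = FALSE)
  ids <- raw[[1L]]
  taxa <- colnames(raw)[-1L]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id '%s'", ids[duplicated(ids)][1L]), call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop(sprintf("duplicate taxon id '%s'", taxa[duplicated(taxa)][1L]), call. = FALSE)
  }
  M <- matrix(NA_real_, nrow(raw), length(taxa), dimnames = list(ids, taxa))
  for (j in seq_along(taxa)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at sample '%s', taxon '%s'",
                   raw[[j + 1L]][i], ids[i], taxa[j]), call. = FALSE)
    }
    M[, j] <- v
  }
  neg <- which(M < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at sample '%s', taxon '%s'",
                 ids[neg[1L, 1L]], taxa[neg[1L, 2L]]), call. = FALSE)
  }
  siLog("INFO", sprintf("read %d samples x %d taxa from %s", nrow(M), ncol(M), path))
  CountTable(M)
}

#' Write a count table as TSV
#'
#' @param table a [CountTable-class].
#' @param path destination file.
#' @param dialect `"tsv"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
writeCountTable <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(methods::is(table, "CountTable"))
  x <- counts(table)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a two-column label file (sample_id, label)
#'
#' Labels must be binary 0/1. `validateLabels()` additionally checks
#' alignment with a paired count table and that both classes are present.
#'
#' @param path file path.
#' @return named integer vector of 0/1 labels.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c("character", "integer"))
  y <- df[[2L]]
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  stats::setNames(as.integer(y), df[[1L]])
}

#' @rdname readLabels
#' @param labels named 0/1 vector.
#' @export
writeLabels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels), label = as.integer(labels))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readLabels
#' @param table a [CountTable-class] the labels must pair with.
#' @export
validateLabels <- function(labels, table) {
  if (!identical(names(labels), sampleIds(table))) {
    stop("labels are not aligned with the count table's samples", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read an image stack container
#'
#' The stack is written as a single compressed serialized container with
#' named members (`images`, `mask`, `meta` holding epsilon, grid size,
#' scheme and sample ids); the round trip is bit-exact, preserving full
#' float fidelity for training. With `preview = TRUE` an 8-bit grayscale PNG
#' per sample is additionally written next to the container, min–max
#' rescaled for visibility. Previews are cosmetic only and are never the
#' training input (segmented images are intentionally dark: foreground
#' pixels sit just above zero).
#'
#' @param stack an [ImageStack-class].
#' @param path destination file (conventionally `.rds`).
#' @param preview also write per-sample preview PNGs.
#' @return invisibly, `path`.
#' @export
writeImageStack <- function(stack, path, preview = FALSE) {
  stopifnot(methods::is(stack, "ImageStack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  obj <- list(images = stack@images, mask = stack@foregroundMask,
              meta = list(epsilon = stack@epsilon,
                          grid = dim(stack@images)[2:3],
                          scheme = stack@scheme,
                          sampleIds = dimnames(stack@images)[[1L]]))
  saveRDS(obj, path, compress = "gzip")
  if (preview) {
    pdir <- paste0(tools::file_path_sans_ext(path), "_previews")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_len(dim(stack@images)[1L])) {
      im <- stack@images[i, , ]
      rg <- range(im)
      im <- if (diff(rg) > 0) (im - rg[1]) / diff(rg) else im * 0 + as.numeric(rg[1] > 0)
      png::writePNG(im, file.path(pdir, sprintf("%s.png",
                                                dimnames(stack@images)[[1L]][i])))
    }
  }
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- readRDS(path)
  methods::new("ImageStack", images = obj$images, foregroundMask = obj$mask,
               epsilon = obj$meta$epsilon, scheme = obj$meta$scheme)
}
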