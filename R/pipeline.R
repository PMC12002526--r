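#' @include classification.R
NULL

#' Pipeline configuration
#'
#' Options for the end-to-end run: whether to apply the segmentation offset
#' (`segment = FALSE` reproduces the original-DeepInsight control arm), the
#' offset `epsilon`, the layout embedding and its seed, the grid size
#' (224 x 224 is the full-scale convention; 32 x 32 is the desk-scale
#' default here), the normalization scheme (or `"select_by_validation"` to
#' pick per fold by inner validation error), and the collision aggregation.
#'
#' @param segment logical; apply the foreground offset.
#' @param epsilon offset in `[0, 1)`, default `1/255`.
#' @param layoutMethod `"pca"`, `"kpca"` or `"tsne"`.
#' @param layoutParams list of embedding parameters.
#' @param gridH,gridW image grid size.
#' @param normScheme `"independent"`, `"topology_preserving"` or
#'   `"select_by_validation"`.
#' @param aggregate `"mean"` or `"max"` collision aggregation.
#' @return a named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(segment = TRUE, epsilon = 1 / 255,
                           layoutMethod = c("pca", "kpca", "tsne"),
                           layoutParams = list(), gridH = 32L, gridW = 32L,
                           normScheme = c("independent", "topology_preserving",
                                          "select_by_validation"),
                           aggregate = c("mean", "max")) {
  structure(list(segment = isTRUE(segment), epsilon = as.numeric(epsilon),
                 layoutMethod = match.arg(layoutMethod),
                 layoutParams = layoutParams,
                 gridH = as.integer(gridH), gridW = as.integer(gridW),
                 normScheme = match.arg(normScheme),
                 aggregate = match.arg(aggregate)),
            class = "PipelineConfig")
}

#' Run the end-to-end classification pipeline
#'
#' Executes the full sequence — closure to the simplex, square-root
#' transform to the sphere, tangent projection at the Fréchet mean,
#' DeepInsight-style image generation (with or without the segmentation
#' offset), and cross-validated CNN evaluation — and optionally writes
#' reproducible artifacts: the fold report (JSON), an image stack rendered
#' from the full data with its layout sidecar, and a run manifest recording
#' every seed, the configuration and a content hash.
#'
#' @param table a [CountTable-class]; alternatively pass `preset` to
#'   simulate.
#' @param labels binary labels aligned with `table`.
#' @param preset a [syntheticParams()] object used when `table` is `NULL`.
#' @param pipeline a [pipelineConfig()].
#' @param train a [trainConfig()].
#' @param k folds.
#' @param seed master seed (fans out to folds, layouts, training).
#' @param outputDir directory for artifacts, or `NULL` to skip writing.
#' @return a [CVReport-class]; written artifacts listed in the manifest.
#' @export
runPipeline <- function(table = NULL, labels = NULL, preset = NULL,
                        pipeline = pipelineConfig(), train = trainConfig(),
                        k = 5L, seed = 1L, outputDir = NULL) {
  if (is.null(table)) {
    if (is.null(preset)) stop("either a count table or a preset is required",
                              call. = FALSE)
    sim <- generateDataset(preset)
    table <- sim$counts
    labels <- sim$labels
  }
  validateLabels(labels, table)
  siLog("INFO", sprintf("pipeline start: %d samples, %d taxa, segment=%s",
                        nrow(counts(table)), ncol(counts(table)),
                        pipeline$segment))
  report <- crossValidate(table, labels, k = k, seed = seed,
                          pipeline = pipeline, train = train)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    # full-data render for inspection (not used for CV scoring)
    sphere <- sqrtTransform(closure(table))
    tc <- tangentProjection(sphere)
    tang <- values(tc)
    layout <- featureLayout(tang, method = pipeline$layoutMethod,
                            seed = as.integer(seed),
                            params = pipeline$layoutParams, fittedOn = "all")
    rect <- minAreaRectangle(layout)
    pmap <- pixelAssignment(layout, rect$angle, pipeline$gridH, pipeline$gridW)
    scheme <- if (pipeline$normScheme == "select_by_validation")
      report@details$schemes[1L] else pipeline$normScheme
    norm <- normalizeValues(tang, scheme = scheme)
    stack <- renderImages(norm, pmap, epsilon = pipeline$epsilon,
                          segment = pipeline$segment,
                          aggregate = pipeline$aggregate)
    writeImageStack(stack, file.path(outputDir, "image_stack.rds"),
                    preview = TRUE)
    saveRDS(list(layout = layout, rect = rect, pixelMap = pmap),
            file.path(outputDir, "layout_sidecar.rds"))
    cfg <- list(pipeline = unclass(pipeline), train = unclass(train),
                k = as.integer(k), seed = as.integer(seed))
    tmp <- tempfile(); saveRDS(cfg, tmp, compress = FALSE)
    hash <- unname(tools::md5sum(tmp)); unlink(tmp)
    jsonlite::write_json(
      list(foldAucs = report@foldAucs, meanAuc = mean(report@foldAucs),
           schemes = report@details$schemes,
           folds = report@folds),
      file.path(outputDir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(seed = as.integer(seed), k = as.integer(k),
           configHash = hash, config = cfg,
           packageVersion = as.character(utils::packageVersion("sphereInsight")),
           nSamples = nrow(counts(table)), nTaxa = ncol(counts(table)),
           zeroFraction = empiricalZeroFraction(table),
           artifacts = c("image_stack.rds", "layout_sidecar.rds",
                         "cv_report.json")),
      file.path(outputDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    siLog("INFO", sprintf("artifacts written to %s", outputDir))
  }
  report
}
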