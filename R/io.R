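#' @include AllClasses.R synthetic.R preprocess.R encoding.R stats.R
NULL

.BUNDLE_SCHEMA <- "laglayer-bundle-1"

## full-precision numeric CSV (round-trips doubles bit-for-bit)
.writeNumericCSV <- function(m, path) {
    m <- as.matrix(m)
    ch <- matrix(sprintf("%.17g", m), nrow(m))
    writeLines(do.call(paste, c(as.data.frame(ch), sep = ",")), path)
}

.readNumericCSV <- function(path, nrow, ncol, what) {
    v <- scan(path, what = numeric(), sep = ",", quiet = TRUE)
    if (length(v) != nrow * ncol)
        stop("schemaError: ", what, " in '", basename(path), "' has ",
             length(v), " values; expected ", nrow * ncol,
             " (truncated or corrupt bundle?)")
    matrix(v, nrow = nrow, byrow = TRUE)
}

#' Write a dataset bundle to disk
#'
#' Serializes events (CSV), embeddings and signal (full-precision
#' numeric CSV) and metadata/ground truth (JSON) into a directory. The
#' round trip through [readBundle()] is bit-identical for finite
#' arrays.
#'
#' @param events A [WordEventTable-class].
#' @param embeddings A [LayeredEmbeddingSet-class].
#' @param recording A [NeuralRecording-class].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list (e.g. from
#'   [syntheticTruth()]).
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(events, embeddings, recording, dir,
                        truth = NULL) {
    stopifnot(is(events, "WordEventTable"),
              is(embeddings, "LayeredEmbeddingSet"),
              is(recording, "NeuralRecording"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    n <- nWords(events)
    L <- nLayers(embeddings)
    d <- embeddingDim(embeddings)
    meta <- list(schema = .BUNDLE_SCHEMA,
                 nWords = n, nLayers = L, embedDim = d,
                 nElectrodes = nElectrodes(recording),
                 nSamples = nSamples(recording),
                 samplingRate = samplingRate(recording),
                 electrodeIds = electrodeIds(recording),
                 roiLabels = roiLabels(recording),
                 layerIds = layerIds(embeddings),
                 wordIndex = embeddings@wordIndex)
    if (!is.null(truth)) {
        truth$readout <- list(dim = dim(truth$readout),
                              values = as.numeric(truth$readout))
        meta$truth <- truth
    }
    jsonlite::write_json(meta, file.path(dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    ev <- data.frame(word = events@word,
                     onset = sprintf("%.17g", onsets(events)),
                     rank = ranks(events), foldId = foldIds(events))
    write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
    .writeNumericCSV(matrix(aperm(embeddingArray(embeddings),
                                  c(1L, 3L, 2L)), n, d * L),
                     file.path(dir, "embeddings.csv"))
    .writeNumericCSV(signalMatrix(recording), file.path(dir, "signal.csv"))
    invisible(dir)
}

#' Read a dataset bundle from disk
#'
#' @param dir Directory written by [writeBundle()].
#' @return List with `events`, `embeddings`, `recording` and (when
#'   present) `truth`. A missing or mismatched schema raises a named
#'   `schemaError` condition message.
#' @export
readBundle <- function(dir) {
    metaPath <- file.path(dir, "meta.json")
    if (!file.exists(metaPath))
        stop("schemaError: no meta.json under '", dir, "'")
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    if (!identical(meta$schema, .BUNDLE_SCHEMA))
        stop("schemaError: expected schema '", .BUNDLE_SCHEMA,
             "', found '", meta$schema, "'")
    ev <- read.csv(file.path(dir, "events.csv"),
                   colClasses = c(word = "character", onset = "character",
                                  rank = "integer", foldId = "integer"))
    events <- WordEventTable(ev$word, as.numeric(ev$onset), ev$rank,
                             ev$foldId)
    n <- meta$nWords; L <- meta$nLayers; d <- meta$embedDim
    embM <- .readNumericCSV(file.path(dir, "embeddings.csv"), n, d * L,
                            "embeddings")
    emb <- LayeredEmbeddingSet(aperm(array(embM, c(n, d, L)),
                                     c(1L, 3L, 2L)),
                               layerIds = meta$layerIds,
                               wordIndex = meta$wordIndex)
    sig <- .readNumericCSV(file.path(dir, "signal.csv"),
                           meta$nElectrodes, meta$nSamples, "signal")
    rec <- NeuralRecording(sig, meta$samplingRate, meta$electrodeIds,
                           meta$roiLabels)
    out <- list(events = events, embeddings = emb, recording = rec)
    if (!is.null(meta$truth)) {
        tr <- meta$truth
        tr$readout <- array(tr$readout$values, dim = tr$readout$dim)
        out$truth <- tr
    }
    out
}

## stable hash of a configuration (serialize to canonical JSON, md5)
.configHash <- function(x) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                             digits = NA)), tmp)
    unname(tools::md5sum(tmp))
}

.configAsList <- function(cfg) {
    sl <- methods::slotNames(class(cfg))
    out <- lapply(sl, function(s) {
        v <- methods::slot(cfg, s)
        if (is.function(v)) paste(deparse(v), collapse = "") else v
    })
    names(out) <- sl
    out
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> preprocess -> encode -> stats in order, writing
#' each stage's outputs under `outDir` and a `manifest.json` recording
#' the configuration hash, seed, stage file list and checksums. Stages
#' whose outputs already exist are skipped unless `force = TRUE` or the
#' configuration hash changed since the previous run. A stage failure
#' aborts with the failing stage named; earlier outputs are retained.
#'
#' @param outDir Output directory.
#' @param synthetic A [SyntheticConfig-class] describing the simulated
#'   study.
#' @param encoding An [EncodingConfig-class].
#' @param preprocessOps Character subset of
#'   `c("despike", "car", "highgamma", "smooth")` applied in order.
#'   The default (despike + smoothing) matches synthetic bundles, whose
#'   signal is already on the referenced band-power scale; add `"car"`
#'   and `"highgamma"` for raw-voltage recordings.
#' @param permutations Layer-index permutations for the stats stage.
#' @param seed Overrides `synthetic@seed` when given; recorded in the
#'   manifest and reused for the stats stage.
#' @param roi Optional ROI restriction for the stats stage.
#' @param force Recompute all stages even if outputs exist.
#' @return The manifest, invisibly.
#' @export
runPipeline <- function(outDir, synthetic = SyntheticConfig(),
                        encoding = EncodingConfig(),
                        preprocessOps = c("despike", "smooth"),
                        permutations = 10000, seed = NULL, roi = NULL,
                        force = FALSE) {
    if (!is.null(seed)) synthetic@seed <- as.integer(seed)
    validObject(synthetic); validObject(encoding)
    bad <- setdiff(preprocessOps, c("despike", "car", "highgamma",
                                    "smooth"))
    if (length(bad))
        stop("unknown preprocess op(s): ", paste(bad, collapse = ", "))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgHash <- .configHash(list(synthetic = .configAsList(synthetic),
                                encoding = .configAsList(encoding),
                                preprocessOps = preprocessOps,
                                permutations = permutations, roi = roi))
    manifestPath <- file.path(outDir, "manifest.json")
    prev <- if (file.exists(manifestPath))
        jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
    if (!is.null(prev) && !identical(prev$configHash, cfgHash))
        force <- TRUE                       # configuration changed: rerun
    stages <- list()
    runStage <- function(name, outputs, fn) {
        if (!force && all(file.exists(outputs))) {
            stages[[name]] <<- list(status = "skipped", outputs = outputs)
            return(invisible())
        }
        ok <- tryCatch({ fn(); TRUE },
                       error = function(e) {
                           stop("stage '", name, "' failed: ",
                                conditionMessage(e), call. = FALSE)
                       })
        stages[[name]] <<- list(status = "run", outputs = outputs)
        invisible(ok)
    }

    bundleDir <- file.path(outDir, "bundle")
    runStage("simulate", file.path(bundleDir, "meta.json"), function() {
        ds <- generateNeuralDataset(synthetic)
        writeBundle(syntheticEvents(ds), syntheticEmbeddings(ds),
                    syntheticRecording(ds), bundleDir,
                    truth = syntheticTruth(ds))
    })

    prepPath <- file.path(outDir, "preprocessed_signal.csv")
    runStage("preprocess", prepPath, function() {
        b <- readBundle(bundleDir)
        rec <- b$recording
        for (op in preprocessOps)
            rec <- switch(op, despike = despike(rec),
                          car = rereferenceCAR(rec),
                          highgamma = highGammaPower(rec),
                          smooth = smoothHamming(rec))
        .writeNumericCSV(signalMatrix(rec), prepPath)
    })

    encPath <- file.path(outDir, "encoding_tensor.csv")
    encMeta <- file.path(outDir, "encoding_meta.json")
    runStage("encode", c(encPath, encMeta), function() {
        b <- readBundle(bundleDir)
        sig <- .readNumericCSV(prepPath, nElectrodes(b$recording),
                               nSamples(b$recording), "signal")
        rec <- NeuralRecording(sig, samplingRate(b$recording),
                               electrodeIds(b$recording),
                               roiLabels(b$recording))
        tens <- encodeLayerwise(rec, b$events, b$embeddings, encoding)
        .writeNumericCSV(matrix(tensorValues(tens),
                                nElectrodes(tens)), encPath)
        jsonlite::write_json(list(dim = dim(tensorValues(tens)),
                                  lags = lagGrid(tens),
                                  layerIds = layerIds(tens),
                                  electrodeIds = electrodeIds(tens),
                                  roiLabels = roiLabels(tens)),
                             encMeta, auto_unbox = TRUE, digits = NA)
    })

    statsPath <- file.path(outDir, "stats.json")
    runStage("stats", statsPath, function() {
        em <- jsonlite::read_json(encMeta, simplifyVector = TRUE)
        v <- .readNumericCSV(encPath, em$dim[1L],
                             em$dim[2L] * em$dim[3L], "tensor")
        tens <- new("EncodingTensor",
                    values = array(v, em$dim), lags = em$lags,
                    layerIds = as.integer(em$layerIds),
                    electrodeIds = em$electrodeIds,
                    roiLabels = em$roiLabels)
        m <- averageOverElectrodes(tens, roi)
        res <- lagLayerStats(m, lags = lagGrid(tens),
                             layerIds = layerIds(tens), K = permutations,
                             seed = synthetic@seed)
        jsonlite::write_json(
            list(peakLags = peakLags(res), layerIds = layerIds(res),
                 rPearson = rPearson(res), rSpearman = rSpearman(res),
                 pExact = pExact(res), pPermutation = pPermutation(res)),
            statsPath, auto_unbox = TRUE, digits = NA)
    })

    outFiles <- unlist(lapply(stages, `[[`, "outputs"))
    sums <- tools::md5sum(outFiles)
    names(sums) <- basename(outFiles)
    manifest <- list(configHash = cfgHash, seed = synthetic@seed,
                     stages = stages, checksums = as.list(sums))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    invisible(manifest)
}
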