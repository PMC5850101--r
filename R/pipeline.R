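## End-to-end orchestration: read/align -> prefilter -> balanced split (or a
## supplied partition) -> model ladder -> final model -> validation battery
## -> applicability domain -> classification, with a single summary mirroring
## the conventional QSAR statistics block.

#' Pipeline configuration
#'
#' Collects every tunable of \code{\link{runPipeline}} with its default.
#' The master \code{seed} is propagated to each stochastic stage
#' (splitting, subset search, cross-validation draws, Y-randomization)
#' through fixed per-stage sub-seeds, so a run is fully reproducible.
#'
#' @param nearConstFrac,collinearR2 prefilter thresholds; see
#'   \code{\link{prefilterPool}}.
#' @param fractions,kClusters,standardize,nInit splitting controls; see
#'   \code{\link{bsmSplit}}.
#' @param dRange,nStarts,maxSweeps,selectTol search controls; see
#'   \code{\link{modelLadder}}.
#' @param l30Pct,l30Cases leave-n\%-out controls.
#' @param yRandCases Y-randomization permutation count.
#' @param thresholdNM classification threshold (nM).
#' @param seed master seed.
#' @return Named list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(nearConstFrac = 0.95, collinearR2 = 0.998,
                           fractions = c(0.5, 0.25, 0.25), kClusters = NULL,
                           standardize = TRUE, nInit = 10L,
                           dRange = 1:9, nStarts = 10L, maxSweeps = 25L,
                           selectTol = 0.01, l30Pct = 0.30,
                           l30Cases = 5000L, yRandCases = 2000L,
                           thresholdNM = 1000, seed = 1L) {
    cfg <- list(nearConstFrac = nearConstFrac, collinearR2 = collinearR2,
                fractions = fractions, kClusters = kClusters,
                standardize = standardize, nInit = nInit, dRange = dRange,
                nStarts = nStarts, maxSweeps = maxSweeps,
                selectTol = selectTol, l30Pct = l30Pct,
                l30Cases = l30Cases, yRandCases = yRandCases,
                thresholdNM = thresholdNM, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

.stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full QSAR modelling pipeline
#'
#' Aligns descriptors and activities, prefilters the pool, splits the
#' compounds (balanced subsets unless a partition is supplied), runs the
#' replacement-method model ladder, and subjects the selected model to the
#' validation battery, applicability-domain assessment and
#' regression-to-classification scoring. All reports are returned in one
#' bundle; \code{\link{writeBundle}} serializes them.
#'
#' @param descriptors a \linkS4class{DescriptorMatrix} (raw pool).
#' @param activities an \linkS4class{ActivitySet}.
#' @param partition optional \linkS4class{SubsetPartition}; when supplied
#'   it overrides the balanced split (e.g. to reproduce a published split).
#' @param config a \code{\link{pipelineConfig}}.
#' @param outputDir optional directory; when given, all reports are
#'   written there via \code{\link{writeBundle}}.
#' @return A list bundle: \code{config}, \code{prefilterReport},
#'   \code{partition}, \code{clusters}, \code{ladder}, \code{model},
#'   \code{validation}, \code{ad}, \code{classification}, \code{summary}
#'   (named numeric vector mirroring the statistics block),
#'   \code{balance}.
#' @export
runPipeline <- function(descriptors, activities, partition = NULL,
                        config = pipelineConfig(), outputDir = NULL) {
    if (!inherits(config, "PipelineConfig"))
        stop("'config' must come from pipelineConfig()")
    seed <- config$seed

    al <- .stageTry("align", alignCompounds(descriptors, activities))
    dm <- al$descriptors; act <- al$activities

    pf <- .stageTry("prefilter",
                    prefilterPool(dm, config$nearConstFrac,
                                  config$collinearR2))
    pool <- pf$descriptors
    message(sprintf("prefilter: pool %d -> %d descriptors",
                    pf$report$poolSizeBefore, pf$report$poolSizeAfter))

    clusters <- NULL
    if (is.null(partition)) {
        sp <- .stageTry("split",
                        bsmSplit(pool, fractions = config$fractions,
                                 kClusters = config$kClusters,
                                 standardize = config$standardize,
                                 seed = .stageSeed(seed, "split"),
                                 nInit = config$nInit))
        partition <- sp$partition
        clusters <- sp$clusters
    } else if (!all(compoundIds(pool) %in% compoundIds(partition))) {
        stop("supplied partition does not cover all compounds")
    }
    lab <- partitionLabels(partition)
    y <- logIC50(act)
    trainIds <- names(lab)[lab == "train"]
    valIds <- names(lab)[lab == "val"]
    testIds <- names(lab)[lab == "test"]

    ladder <- .stageTry("search",
                        modelLadder(pool, act, partition,
                                    dRange = config$dRange,
                                    nStarts = config$nStarts,
                                    maxSweeps = config$maxSweeps,
                                    seed = seed,
                                    selectTol = config$selectTol))
    model <- ladder$selectedModel
    d <- length(descriptorNames(model))
    st <- fitStats(model)
    Xpool <- descriptorValues(pool)
    Xtr <- Xpool[trainIds, , drop = FALSE]
    ytr <- as.numeric(y[trainIds])

    val <- .stageTry("validation", {
        loo <- looCV(Xtr, ytr, descriptorNames(model))
        lno <- leaveNPctOut(Xtr, ytr, descriptorNames(model),
                            pct = config$l30Pct, nCases = config$l30Cases,
                            seed = .stageSeed(seed, "lno"))
        yr <- yRandomization(Xtr, ytr, descriptorNames(model),
                             nPermutations = config$yRandCases,
                             seed = .stageSeed(seed, "yrand"))
        o3 <- if (st$s > 0) countOutliers(st$residuals, st$s)
              else list(count = 0L, ids = character(0))
        predTest <- predict(model, Xpool[testIds, , drop = FALSE])
        gt <- golbraikhTropsha(y[testIds], predTest)
        vc <- if (d >= 2) vifAndCorr(Xtr, descriptorNames(model))
              else list(vifMax = 1, r2Max = NA_real_)
        list(loo = loo, lno = lno, yRand = yr, o3 = o3, gt = gt,
             vif = vc)
    })

    ad <- .stageTry("ad", {
        lev <- leverageAD(model, Xtr, Xpool[testIds, , drop = FALSE])
        std <- standardizationAD(Xtr, Xpool[testIds, , drop = FALSE],
                                 descriptorNames(model))
        wil <- williamsTable(model, pool, act, partition)
        agree <- mean(lev$table$inside == std$inside)
        list(leverage = lev, standardization = std, williams = wil,
             agreement = agree)
    })

    cls <- .stageTry("classification", {
        predTest <- predict(model, Xpool[testIds, , drop = FALSE])
        classifyAndScore(y[testIds], predTest, config$thresholdNM)
    })

    valStats <- subsetStats(y[valIds],
                            predict(model, Xpool[valIds, , drop = FALSE]), d)
    testStats <- subsetStats(y[testIds],
                             predict(model, Xpool[testIds, , drop = FALSE]), d)
    balance <- balanceDiagnostics(partition, act)

    summary <- c(
        nTrain = st$n, d = d, r2Train = st$r2, sTrain = st$s,
        rij2Max = val$vif$r2Max, vifMax = val$vif$vifMax,
        o3 = val$o3$count,
        r2Rand = val$yRand$r2Rand, sRand = val$yRand$sRand,
        r2Loo = val$loo$r2, sLoo = val$loo$s,
        r2L30o = val$lno$r2, sL30o = val$lno$s,
        nVal = valStats$n, r2Val = valStats$r2, sVal = valStats$s,
        nTest = testStats$n, r2Test = testStats$r2, sTest = testStats$s,
        gtK = val$gt$k, gtKPrime = val$gt$kPrime,
        gtR02 = val$gt$r02, gtR02Prime = val$gt$r02prime,
        gtRm2 = val$gt$rm2,
        hStar = ad$leverage$hStar, adAgreement = ad$agreement,
        accuracyPct = cls$accuracyPct, sensitivity = cls$sensitivity,
        specificity = cls$specificity, mcc = cls$mcc)

    bundle <- list(config = config, prefilterReport = pf$report,
                   partition = partition, clusters = clusters,
                   ladder = ladder, model = model, validation = val,
                   ad = ad, classification = cls, summary = summary,
                   balance = balance)
    if (!is.null(outputDir)) writeBundle(bundle, outputDir)
    bundle
}

#' Generate synthetic data and run the pipeline
#'
#' Convenience wrapper: \code{\link{generateSynthetic}} followed by
#' \code{\link{runPipeline}}; the bundle additionally carries the planted
#' \code{truth} and a \code{recovery} block (how many planted descriptors
#' the selected model contains).
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @param config a \code{\link{pipelineConfig}}; defaults to one seeded
#'   from the spec.
#' @param outputDir optional output directory.
#' @return The \code{\link{runPipeline}} bundle plus \code{truth} and
#'   \code{recovery}.
#' @export
runSynthetic <- function(spec, config = NULL, outputDir = NULL) {
    gen <- .stageTry("generate", generateSynthetic(spec))
    if (is.null(config)) config <- pipelineConfig(seed = spec$seed)
    bundle <- runPipeline(gen$descriptors, gen$activities, config = config,
                          outputDir = outputDir)
    sel <- descriptorNames(bundle$model)
    bundle$truth <- gen$truth
    bundle$recovery <- list(
        selected = sel,
        planted = gen$truth$signalNames,
        nRecovered = length(intersect(sel, gen$truth$signalNames)),
        nPlanted = length(gen$truth$signalNames))
    bundle
}

#' Write a pipeline bundle to disk
#'
#' Serializes the reports of a \code{\link{runPipeline}} bundle into a
#' directory: key-value summary, ladder and prefilter CSVs, partition,
#' model equation and table, Williams and AD tables, confusion statistics.
#' Deterministic: identical bundles produce byte-identical files.
#'
#' @param bundle a pipeline bundle.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    .writeKeyValue(as.list(bundle$summary), p("summary.txt"))
    utils::write.csv(bundle$ladder$table, p("ladder.csv"),
                     row.names = FALSE)
    writePrefilterReport(bundle$prefilterReport, p("prefilter.csv"))
    writePartition(bundle$partition, p("partition.csv"))
    writeModelEquation(bundle$model, p("model_equation.txt"))
    writeModelTable(bundle$model, p("model.csv"))
    utils::write.csv(bundle$ad$williams$table, p("williams.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$ad$leverage$table, p("ad_leverage.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$ad$standardization, p("ad_standardization.csv"),
                     row.names = FALSE)
    writeClassificationReport(bundle$classification, p("classification.csv"))
    utils::write.csv(bundle$balance, p("balance.csv"), row.names = FALSE)
    invisible(dir)
}
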