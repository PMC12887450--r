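## End-to-end orchestration: simulate -> call lesions -> kinetics ->
## profiles -> nucleosome -> structure -> regression, with a manifest.

#' Read a pipeline run configuration
#'
#' The configuration is a YAML file whose keys are passed to
#' [simulationConfig()] (unknown keys are rejected), plus optional
#' \code{pairsFile} (TSV with context/damage/mutation columns for the
#' regression stage) and \code{testContext} (default \code{"TCG"}).
#'
#' @param path YAML file path.
#' @return A list with \code{sim} (a \code{dcpdSimConfig}) and the extra
#'   keys.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    extra <- y[names(y) %in% c("pairsFile", "testContext")]
    simArgs <- y[!(names(y) %in% names(extra))]
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(simArgs), known)
    if (length(bad) > 0L)
        stop("unknown config keys: ", paste(bad, collapse = ", "))
    list(sim = do.call(simulationConfig, simArgs),
         pairsFile = extra$pairsFile,
         testContext = if (is.null(extra$testContext)) "TCG"
                       else extra$testContext)
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes every stage in order -- simulation (cellular and naked modes),
#' lesion calling from the emitted reads, per-context kinetics with
#' gel-equivalent absolute scaling, gene/TFBS profiles with
#' cellular-vs-naked enrichment, nucleosome dyad profiling with
#' rotational and backbone group comparisons, structural analysis of a
#' synthetic duplex, and the damage-vs-mutation outlier regression --
#' writing TSV outputs and a JSON manifest (seeds, input hashes, stage
#' outputs) to \code{outdir}. All randomness derives from the config
#' seed, so reruns with the same config are byte-identical for the
#' deterministic stages.
#'
#' @param config a \code{dcpdSimConfig} from [simulationConfig()], a
#'   config list from [readRunConfig()], or a YAML path.
#' @param outdir output directory.
#' @param quiet suppress stage messages.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir, quiet = FALSE) {
    if (is.character(config)) config <- readRunConfig(config)
    if (inherits(config, "dcpdSimConfig"))
        config <- list(sim = config, pairsFile = NULL,
                       testContext = "TCG")
    cfg <- config$sim
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    say <- function(...) if (!quiet) message("[dcpd] ", ...)
    manifest <- list(seed = cfg$seed, stages = list(),
                     started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    addStage <- function(name, files, info = list()) {
        manifest$stages[[name]] <<- c(list(
            outputs = as.list(files),
            md5 = as.list(tools::md5sum(unlist(files)))), info)
    }
    stage <- "simulate"
    res <- tryCatch({
        say("stage simulate")
        sim <- simulateGenomeAndFeatures(cfg)
        truthC <- simulateDamageAndDeamination(sim, cfg, "cellular")
        truthN <- simulateDamageAndDeamination(sim, cfg, "naked")
        simDir <- file.path(outdir, "simulate")
        pC <- writeSimulation(truthC, simDir, readSeedBase = cfg$seed * 13L)
        pN <- writeSimulation(truthN, simDir, readSeedBase = cfg$seed * 17L)
        addStage("simulate", c(unlist(pC), unlist(pN)),
                 list(nSites = length(truthC@sites)))

        stage <- "call-lesions"
        say("stage call-lesions")
        tps <- cfg$timepoints
        lesC <- lesN <- list()
        lesDir <- file.path(outdir, "lesions")
        dir.create(lesDir, showWarnings = FALSE)
        lesFiles <- character(0)
        for (i in seq_along(tps)) {
            for (md in c("cellular", "naked")) {
                truth <- if (md == "cellular") truthC else truthN
                base <- if (md == "cellular") cfg$seed * 13L
                        else cfg$seed * 17L
                nDeam <- length(deaminatedSites(truth, tps[i]))
                if (nDeam == 0L) {
                    les <- annotateContext(
                        GRanges(seqlengths = c(chrS = cfg$genomeLength)),
                        sim$genome)
                } else {
                    reads <- emitReads(truth, tps[i],
                                       cfg$readsPerTimepoint,
                                       seed = base + i)
                    les <- annotateContext(callLesions(reads, sim$genome),
                                           sim$genome)
                }
                f <- file.path(lesDir,
                               sprintf("lesions_%s_t%g.bed", md, tps[i]))
                writeLesionsBed(les, f)
                lesFiles <- c(lesFiles, f)
                if (md == "cellular") lesC[[i]] <- les else lesN[[i]] <- les
            }
        }
        addStage("call-lesions", lesFiles)

        stage <- "kinetics"
        say("stage kinetics")
        kb <- cfg$genomeLength / 1000
        bulkC <- vapply(tps, function(t)
            length(deaminatedSites(truthC, t)) / kb, numeric(1))
        kin <- contextKinetics(lesC, tps, bulkC, sim$genome,
                               fitContexts = intersect(
                                   c("TCG", "TCA", "TCT", "TCC"),
                                   names(cfg$kCtx)))
        kinFile <- file.path(outdir, "kinetics.tsv")
        fitRows <- do.call(rbind, lapply(kin$fits, function(f)
            data.frame(context = f@context, k = f@k, plateau = f@plateau,
                       tHalf = f@tHalf, converged = f@converged)))
        write.table(kin$table, kinFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        fitFile <- file.path(outdir, "kinetic_fits.tsv")
        write.table(fitRows, fitFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addStage("kinetics", c(kinFile, fitFile))

        stage <- "profile"
        say("stage profile")
        iLast <- length(tps)
        totC <- totalDipyLesions(lesC[[iLast]])
        totN <- totalDipyLesions(lesN[[iLast]])
        gpC <- geneMetaprofile(lesC[[iLast]], sim$genes, sim$genome)
        gpN <- geneMetaprofile(lesN[[iLast]], sim$genes, sim$genome)
        gpE <- enrichmentRatio(gpC, gpN, totC, totN)
        spC <- siteProfile(lesC[[iLast]], sim$tfbs, sim$genome)
        spN <- siteProfile(lesN[[iLast]], sim$tfbs, sim$genome)
        spE <- enrichmentRatio(spC, spN, totC, totN)
        geneFile <- file.path(outdir, "gene_profile.tsv")
        siteFile <- file.path(outdir, "tfbs_profile.tsv")
        writeProfileTsv(gpE, geneFile)
        writeProfileTsv(spE, siteFile)
        addStage("profile", c(geneFile, siteFile))

        stage <- "nucleosome"
        say("stage nucleosome")
        dpC <- dyadProfile(lesC[[iLast]], sim$dyads, sim$genome,
                           mode = "strand")
        dpN <- dyadProfile(lesN[[iLast]], sim$dyads, sim$genome,
                           mode = "strand")
        dpE <- enrichmentRatio(dpC, dpN, totC, totN)
        rotCmp <- phaseGroupCompare(dpE, cfg$phaseTable, "rotational")
        bbCmp <- phaseGroupCompare(dpE, cfg$phaseTable, "backbone")
        dyadFile <- file.path(outdir, "dyad_profile.tsv")
        writeProfileTsv(dpE, dyadFile)
        cmpFile <- file.path(outdir, "phase_comparison.tsv")
        write.table(data.frame(
            grouping = c("rotational", "backbone"),
            classA = c(rotCmp$classA, bbCmp$classA),
            classB = c(rotCmp$classB, bbCmp$classB),
            medianA = c(rotCmp$medianA, bbCmp$medianA),
            medianB = c(rotCmp$medianB, bbCmp$medianB),
            U = c(rotCmp$U, bbCmp$U), p = c(rotCmp$p, bbCmp$p)),
            cmpFile, sep = "\t", quote = FALSE, row.names = FALSE)
        addStage("nucleosome", c(dyadFile, cmpFile))

        stage <- "structure"
        say("stage structure")
        atoms <- syntheticDuplexStructure()
        omap <- duplexOffsetMap()
        sasa <- c4SasaByClass(atoms, 1.4, omap, cfg$phaseTable,
                              nPoints = 240L)
        bprof <- backboneBfactorProfile(atoms, omap, cfg$phaseTable)
        sasaFile <- file.path(outdir, "c4_sasa.tsv")
        write.table(sasa$table, sasaFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        bFile <- file.path(outdir, "backbone_bfactor.tsv")
        write.table(bprof$profile, bFile, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addStage("structure", c(sasaFile, bFile))

        stage <- "regression"
        say("stage regression")
        if (!is.null(config$pairsFile)) {
            pairs <- read.table(config$pairsFile, header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
        } else {
            ## derive from simulation truth: damage = context share of
            ## CPDs; mutation proxy = context share of 48 h deaminations
            st <- truthSites(truthC)
            deam <- deaminatedSites(truthC, tps[length(tps)])
            ctxAll <- sort(unique(mcols(st)$context))
            pairs <- data.frame(context = ctxAll,
                damage = as.numeric(table(factor(mcols(st)$context,
                    ctxAll))) / length(st),
                mutation = as.numeric(table(factor(mcols(deam)$context,
                    ctxAll))) / max(1L, length(deam)))
        }
        rep <- outlierReport(pairs, config$testContext)
        regFile <- file.path(outdir, "mutation_regression.tsv")
        write.table(data.frame(context = rep$context,
            observed = rep$observed, predicted = rep$predicted,
            halfWidth = rep$halfWidth, fold = rep$fold,
            outsideInterval = rep$outsideInterval,
            rWithout = rep$rWithout, pWithout = rep$pWithout),
            regFile, sep = "\t", quote = FALSE, row.names = FALSE)
        addStage("regression", regFile)
        TRUE
    }, error = function(e) e)
    if (inherits(res, "error")) {
        manifest$failedStage <- stage
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(res))
    }
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    say("done")
    invisible(manifest)
}
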