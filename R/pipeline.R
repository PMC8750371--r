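#' @include AllClasses.R phantom.R segeval.R response.R
NULL

#' Pipeline configuration
#'
#' Bundles every tunable of the study replica. The defaults reproduce the
#' standard analysis constants: 1.2-cm SULpeak sphere, 50 percent
#' detection overlap, strict-majority organ assignment, significance
#' level 0.001, 26-connectivity.
#'
#' @param nPatients cohort size.
#' @param seed master seed (drives phantom generation and the simulated
#'   automatic segmentations).
#' @param spec a [PhantomSpec-class] (ignored when `cohortDir` is given).
#' @param cohortDir optional directory with a pre-generated cohort
#'   (`manifest.csv` + NIfTI tree) to analyse instead of generating one.
#' @param connectivity lesion component connectivity.
#' @param sphereDiameterMM SULpeak VOI diameter, mm.
#' @param overlapThreshold lesion detection overlap fraction.
#' @param majority organ-assignment majority fraction.
#' @param alpha significance level at the reporting layer.
#' @param volumeWithin PBI/PLI numerator rule.
#' @param outDir report bundle destination (NULL: results only returned).
#' @param verbose log per-stage progress to stderr.
#' @return object of class `pipelineConfig`.
#' @export
pipelineConfig <- function(nPatients = 20, seed = 1, spec = phantomSpec(),
                           cohortDir = NULL, connectivity = 26L,
                           sphereDiameterMM = 12.0, overlapThreshold = 0.5,
                           majority = 0.5, alpha = 0.001,
                           volumeWithin = "full", outDir = NULL,
                           verbose = FALSE) {
  structure(list(nPatients = nPatients, seed = seed, spec = spec,
                 cohortDir = cohortDir, connectivity = as.integer(connectivity),
                 sphereDiameterMM = sphereDiameterMM,
                 overlapThreshold = overlapThreshold, majority = majority,
                 alpha = alpha, volumeWithin = volumeWithin, outDir = outDir,
                 verbose = verbose),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; a `phantom` block
#' holds [phantomSpec()] arguments.
#'
#' @param path .yaml path.
#' @return object of class `pipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  specArgs <- y$phantom %||% list()
  y$phantom <- NULL
  y$spec <- do.call(phantomSpec, specArgs)
  do.call(pipelineConfig, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

logStage <- function(verbose, fmt, ...) {
  if (verbose)
    message(sprintf("[petResponse %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

configHash <- function(config) {
  # hash the analysis parameters only, not where results are written
  cfg <- unclass(config)
  cfg$outDir <- NULL
  cfg$verbose <- NULL
  s <- jsonlite::toJSON(lapply(cfg, function(x)
    if (isS4(x)) capture_spec(x) else x),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

capture_spec <- function(x) {
  sl <- methods::slotNames(class(x))
  stats::setNames(lapply(sl, function(s) methods::slot(x, s)), sl)
}

timelineFromManifest <- function(rows) {
  rows <- rows[order(rows$timepoint), ]
  bl <- rows[rows$timepoint == "BL", ]
  fu <- rows[rows$timepoint != "BL", ]
  if (nrow(bl) != 1)
    stop(sprintf("patient %s: exactly one baseline row required",
                 rows$patient_id[1]), call. = FALSE)
  if (nrow(fu) < 1)
    stop(sprintf("patient %s has no follow-up acquisitions: response %s",
                 rows$patient_id[1],
                 "assessment requires at least one follow-up"), call. = FALSE)
  loadAcq <- function(r) {
    vol <- readVolume(r$pet_path, r$value_kind)
    if (valueKind(vol) == "activity_Bq_per_mL")
      vol <- toSUVbw(vol, manifestMeta(r))
    list(volume = vol, mask = readMask(r$mask_path), meta = manifestMeta(r))
  }
  new("PatientTimeline",
      baseline = loadAcq(bl[1, ]),
      followups = lapply(seq_len(nrow(fu)), function(i) loadAcq(fu[i, ])),
      organMasks = list(bone = readMask(bl$bone_path[1]),
                        liver = readMask(bl$liver_path[1])))
}

panelRow <- function(panel, meta, source) {
  data.frame(patient_id = meta@patientId, timepoint = meta@timepoint,
             source = source,
             percist = ifelse(is.na(meta@percist), "", meta@percist),
             sul_peak = panel@sulPeak, mtv_total_ml = panel@mtvTotal,
             tlg_total = panel@tlgTotal, pbi = panel@pbi, pli = panel@pli,
             n_lesions = nrow(panel@perLesion))
}

deltaOrCollapse <- function(bl, fu, fuEmpty) {
  # empty follow-up segmentation: the biomarker vanished; for SULpeak
  # (NA on an empty mask) treat disappearance as a -100 percent change
  if (is.na(fu) && fuEmpty) fu <- 0
  if (is.na(bl) || is.na(fu)) return(NA_real_)
  as.numeric(deltaBiomarker(bl, fu))
}

#' Run the full synthetic study replica
#'
#' Generates (or loads) a cohort, computes biomarker panels per
#' acquisition on both the ground-truth ("manual") and simulated
#' automatic segmentations, evaluates the simulated segmentations
#' (mean/global Dice, lesion detection), forms baseline-to-follow-up
#' biomarker changes from the automatic panels, assesses treatment
#' response against the planted PERCIST labels (ROC/AUC, Youden cutoff,
#' DeLong comparisons, Mann-Whitney), and measures manual/automatic
#' agreement (Lin's CCC, Spearman, Wilcoxon). With `outDir` set, writes
#' `panels.csv`, `deltas.csv`, `segeval.csv`, `response.csv`,
#' `delong.csv`, `concordance.csv` and `run_config.json` (config echo
#' with a hash); reruns with an identical config are byte-identical.
#'
#' @param config a `pipelineConfig` (or YAML path understood by
#'   [readPipelineConfig()]).
#' @return list(panels, deltas, segeval, response, delong, concordance,
#'   truth, configHash).
#' @export
runStudy <- function(config = pipelineConfig()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "pipelineConfig"))
  verbose <- isTRUE(config$verbose)
  t0 <- Sys.time()

  panels <- list(); deltas <- list(); segRows <- list(); truthRows <- list()
  segPooledInter <- 0; segPooledTot <- 0
  failures <- character()

  processPatient <- function(timeline, truth, pidx) {
    tl <- timeline
    organs <- tl@organMasks
    body <- binaryMask(
      tl@baseline$volume@values > 0.5 * config$spec@backgroundSUV,
      spacing(tl@baseline$volume), worldOrigin(tl@baseline$volume))
    acqs <- c(list(tl@baseline), tl@followups)
    for (a in acqs) {
      sul <- suvToSul(a$volume, a$meta)
      manual <- biomarkerPanel(sul, a$volume, a$mask, organs,
                               connectivity = config$connectivity,
                               sphereDiameterMM = config$sphereDiameterMM,
                               majority = config$majority,
                               volumeWithin = config$volumeWithin)
      pseed <- patientSeed(config$seed + 1, pidx * 11 +
                             match(a$meta@timepoint, TIMEPOINTS))
      pred <- perturbMask(a$mask, body, pseed)
      auto <- biomarkerPanel(sul, a$volume, pred, organs,
                             connectivity = config$connectivity,
                             sphereDiameterMM = config$sphereDiameterMM,
                             majority = config$majority,
                             volumeWithin = config$volumeWithin)
      panels[[length(panels) + 1]] <<- panelRow(manual, a$meta, "manual")
      panels[[length(panels) + 1]] <<- panelRow(auto, a$meta, "auto")
      d <- diceScore(a$mask, pred)
      dc <- detectionCounts(a$mask, pred, config$overlapThreshold,
                            config$connectivity)
      segPooledInter <<- segPooledInter + sum(a$mask@values & pred@values)
      segPooledTot <<- segPooledTot + sum(a$mask@values) + sum(pred@values)
      segRows[[length(segRows) + 1]] <<- data.frame(
        id = sprintf("%s_%s", a$meta@patientId, a$meta@timepoint),
        dice = as.numeric(d), dice_sd = NA_real_, tp = dc$tp, fn = dc$fn,
        fp = dc$fp, recall = dc$recall, precision = dc$precision,
        global_dice = NA_real_)
    }
  }

  if (!is.null(config$cohortDir)) {
    logStage(verbose, "loading cohort from %s", config$cohortDir)
    manifest <- readManifest(file.path(config$cohortDir, "manifest.csv"))
    pids <- unique(manifest$patient_id)
    for (i in seq_along(pids)) {
      rows <- manifest[manifest$patient_id == pids[i], ]
      res <- tryCatch(
        processPatient(timelineFromManifest(rows), NULL, i),
        error = function(e) conditionMessage(e))
      if (is.character(res)) failures <- c(failures, res)
    }
    truth <- NULL
  } else {
    logStage(verbose, "generating %d-patient phantom cohort (seed %d)",
             config$nPatients, config$seed)
    plan <- cohortPlan(config$spec, config$nPatients, config$seed)
    for (i in seq_len(config$nPatients)) {
      pt <- generatePatient(config$spec, plan$seed[i], plan$patient_id[i],
                            responder = plan$responder[i])
      for (tp in names(pt$truth$acquisitions)) {
        t <- pt$truth$acquisitions[[tp]]
        truthRows[[length(truthRows) + 1]] <- data.frame(
          patient_id = plan$patient_id[i], timepoint = tp,
          responder = pt$truth$responder, category = pt$truth$category,
          n_lesions = t$n_lesions, mtv_ml = t$mtv_ml, tlg = t$tlg,
          pbi = t$pbi, pli = t$pli)
      }
      processPatient(pt$timeline, pt$truth, i)
      logStage(verbose, "patient %s done (%s)", plan$patient_id[i],
               pt$truth$category)
    }
    truth <- do.call(rbind, truthRows)
  }
  if (length(failures))
    stop(sprintf("cohort processing failed for %d patient(s):\n%s",
                 length(failures), paste(failures, collapse = "\n")),
         call. = FALSE)

  panels <- do.call(rbind, panels)
  segTab <- do.call(rbind, segRows)
  tp <- sum(segTab$tp); fn <- sum(segTab$fn); fp <- sum(segTab$fp)
  segTab <- rbind(segTab, data.frame(
    id = "ALL", dice = mean(segTab$dice), dice_sd = stats::sd(segTab$dice),
    tp = tp, fn = fn, fp = fp,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    global_dice = if (segPooledTot > 0) 2 * segPooledInter / segPooledTot
                  else 1))

  logStage(verbose, "assembling baseline/follow-up deltas")
  auto <- panels[panels$source == "auto", ]
  for (pid in unique(auto$patient_id)) {
    pa <- auto[auto$patient_id == pid, ]
    bl <- pa[pa$timepoint == "BL", ]
    if (nrow(bl) != 1) next
    for (tpn in setdiff(pa$timepoint, "BL")) {
      fu <- pa[pa$timepoint == tpn, ]
      if (fu$percist == "")
        stop(sprintf("follow-up %s/%s has no PERCIST label", pid, tpn),
             call. = FALSE)
      fuEmpty <- fu$n_lesions == 0
      deltas[[length(deltas) + 1]] <- data.frame(
        patient_id = pid, timepoint = tpn, percist = fu$percist,
        responder = binarizePercist(fu$percist),
        d_sulpeak = deltaOrCollapse(bl$sul_peak, fu$sul_peak, fuEmpty),
        d_tlg = deltaOrCollapse(bl$tlg_total, fu$tlg_total, fuEmpty),
        d_pbi = deltaOrCollapse(bl$pbi, fu$pbi, fuEmpty),
        d_pli = deltaOrCollapse(bl$pli, fu$pli, fuEmpty))
    }
  }
  if (length(deltas) == 0)
    stop("no baseline/follow-up pairs available: response assessment ",
         "requires at least one follow-up acquisition", call. = FALSE)
  deltas <- do.call(rbind, deltas)

  logStage(verbose, "response assessment and concordance")
  resp <- assessResponse(deltas[, c("d_sulpeak", "d_tlg", "d_pbi", "d_pli")],
                         deltas$responder, alpha = config$alpha)
  man <- panels[panels$source == "manual",
                c("sul_peak", "tlg_total", "pbi", "pli")]
  aut <- panels[panels$source == "auto",
                c("sul_peak", "tlg_total", "pbi", "pli")]
  conc <- concordancePanel(man, aut)

  out <- list(panels = panels, deltas = deltas, segeval = segTab,
              response = resp$table, delong = resp$delong,
              concordance = conc, truth = truth,
              configHash = configHash(config))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeReport(panels, file.path(config$outDir, "panels.csv"))
    writeReport(deltas, file.path(config$outDir, "deltas.csv"))
    writeReport(segTab, file.path(config$outDir, "segeval.csv"))
    writeReport(resp$table, file.path(config$outDir, "response.csv"))
    writeReport(resp$delong, file.path(config$outDir, "delong.csv"))
    writeReport(conc, file.path(config$outDir, "concordance.csv"))
    if (!is.null(truth))
      writeReport(truth, file.path(config$outDir, "truth.csv"))
    cfgOut <- lapply(unclass(config), function(x)
      if (isS4(x)) capture_spec(x) else x)
    cfgOut$hash <- out$configHash
    jsonlite::write_json(cfgOut, file.path(config$outDir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  logStage(verbose, "done in %.1f s",
           as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}
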