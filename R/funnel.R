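#' Ingest an external docking-score table
#'
#' Docking is an external stage by design: scores (e.g. from a
#' commercial docking engine) enter as a CSV with `id` and `score`
#' columns, more negative meaning better.
#'
#' @param x CSV path or data.frame with columns `id`, `score`.
#' @param control_id id of the control/reference compound.
#' @return data.frame of non-control records, with the control score as
#'   attribute `control_score`.
#' @export
ingest_docking_scores <- function(x, control_id = "Control") {
  tab <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
         else as.data.frame(x)
  if (!all(c("id", "score") %in% names(tab)))
    stop("docking table needs columns id, score")
  if (anyDuplicated(tab$id))
    stop("duplicate ids in docking table")
  if (!control_id %in% tab$id)
    stop("control id '", control_id, "' absent from docking table")
  ctrl <- tab$score[tab$id == control_id]
  out <- tab[tab$id != control_id, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "control_score") <- ctrl
  out
}

#' Select records scoring at least as well as the control
#'
#' By default the cut is non-strict (score <= control), which keeps
#' compounds tied with the control; `strict = TRUE` requires a strictly
#' better (more negative) score.
#'
#' @param records data.frame with `id`, `score`.
#' @param control_score the control's docking score.
#' @param strict require strictly better than control?
#' @return the selected subset (input order preserved).
#' @export
select_better_than_control <- function(records, control_score,
                                       strict = FALSE) {
  keep <- if (strict) records$score < control_score
          else records$score <= control_score
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full virtual-screening funnel
#'
#' Stages, in order: library (load or generate) -> pharmacophore screen
#' -> ML triage -> external docking-score cut -> novelty filter ->
#' energetics ranking. Stages without configuration are skipped; stage
#' counts are monotone non-increasing. Deterministic for a fixed config
#' and seed.
#'
#' @param config nested list (or YAML path) with optional entries:
#'   \describe{
#'     \item{seed}{integer seed (default 1).}
#'     \item{outdir}{directory for per-stage CSV artifacts (optional).}
#'     \item{library}{`list(clouds=, labels=)` as from
#'       [make_feature_library()], a path to a cloud CSV, or
#'       `list(generate = list(n_actives=, n_decoys=, noise=))`.}
#'     \item{model}{a [pharm_model()] or YAML path (default packaged
#'       model).}
#'     \item{triage}{`list(activity = <data.frame or CSV>, family =,
#'       threshold_nM =)`; needs library labels with scaffold SMILES.}
#'     \item{docking}{`list(scores = <CSV or data.frame>, control_id =,
#'       strict =)`.}
#'     \item{novelty}{`list(references = <SMILES vector>, threshold =)`.}
#'     \item{energetics}{`list(ledger = <CSV or data.frame>,
#'       control_id =)`.}
#'   }
#' @return `funnel_report`: `stages` (stage/count/retention table),
#'   `records` (per-compound flags), `final` (ranked final table),
#'   `seed`.
#' @export
run_funnel <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  outdir <- config$outdir
  if (!is.null(outdir))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, df) {
    if (!is.null(outdir))
      utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  stages <- list()
  log_stage <- function(stage, n) {
    stages[[length(stages) + 1L]] <<- data.frame(stage = stage, count = n)
    message(sprintf("funnel | %-12s %6d compounds", stage, n))
  }

  # stage 0: library
  lib <- config$library
  if (is.null(lib)) stop("funnel config lacks the 'library' stage input")
  if (is.character(lib)) lib <- list(clouds = read_cloud_csv(lib))
  if (!is.null(lib$generate)) {
    g <- lib$generate
    lib <- make_feature_library(g$n_actives, g$n_decoys,
                                model = config$model %||% default_pharm_model(),
                                geometric_noise_sd = g$noise %||% 0,
                                seed = seed)
  }
  clouds <- lib$clouds
  labels <- lib$labels
  log_stage("library", length(clouds))

  model <- config$model %||% default_pharm_model()
  if (is.character(model)) model <- read_model_yaml(model)

  # stage 1: pharmacophore screen
  hits <- screen_library(model, clouds)
  emit("pharm_hits", hits)
  records <- data.frame(id = hits$id, pharm_score = hits$score,
                        stringsAsFactors = FALSE)
  log_stage("pharm_screen", nrow(records))

  # stage 2: ML triage
  if (!is.null(config$triage) && nrow(records) > 0L) {
    tcfg <- config$triage
    act <- tcfg$activity
    if (is.character(act)) act <- utils::read.csv(act,
                                                  stringsAsFactors = FALSE)
    act <- label_activities(act, tcfg$threshold_nM %||% 1000)
    X <- featurize_molecules(molecules_from_smiles(act$smiles,
                                                   ids = act$id))
    y <- act$label[match(rownames(X), act$id)]
    fit <- triage_fit(X, y, tcfg$family %||% "gradient_boosting",
                      seed = seed)
    if (is.null(labels) || is.null(labels$smiles))
      stop("triage stage needs library labels with scaffold SMILES")
    smi <- labels$smiles[match(records$id, labels$id)]
    mols <- molecules_from_smiles(smi, ids = records$id)
    cls <- classify_library(fit, mols)
    records <- records[records$id %in% cls$kept, , drop = FALSE]
    emit("ml_active", records)
    log_stage("ml_triage", nrow(records))
  }

  # stage 3: docking-score cut (external scores)
  if (!is.null(config$docking) && nrow(records) > 0L) {
    dcfg <- config$docking
    sc <- ingest_docking_scores(dcfg$scores,
                                dcfg$control_id %||% "Control")
    sel <- select_better_than_control(sc, attr(sc, "control_score"),
                                      strict = isTRUE(dcfg$strict))
    records <- merge(records, sel, by = "id")
    names(records)[names(records) == "score"] <- "docking_score"
    emit("docking_pass", records)
    log_stage("docking", nrow(records))
  }

  # stage 4: novelty filter
  if (!is.null(config$novelty) && nrow(records) > 0L) {
    ncfg <- config$novelty
    if (is.null(labels) || is.null(labels$smiles))
      stop("novelty stage needs library labels with scaffold SMILES")
    smi <- labels$smiles[match(records$id, labels$id)]
    mols <- molecules_from_smiles(smi, ids = records$id)
    rep <- similarity_report(mols, ncfg$references,
                             ncfg$threshold %||% 0.85)
    records <- merge(records, rep, by = "id")
    records <- records[records$flag == "novel", , drop = FALSE]
    emit("novelty_pass", records)
    log_stage("novelty", nrow(records))
  }

  # stage 5: energetics ranking
  if (!is.null(config$energetics) && nrow(records) > 0L) {
    ecfg <- config$energetics
    led <- ecfg$ledger
    if (is.character(led)) led <- read_ledger_csv(led)
    ctrl_id <- ecfg$control_id %||% "Control"
    ctrl <- led[led$id == ctrl_id, , drop = FALSE]
    if (nrow(ctrl) != 1L)
      stop("energetics stage: control '", ctrl_id, "' not in ledger")
    led <- led[led$id %in% records$id, , drop = FALSE]
    rk <- rank_against_control(led, ctrl)
    records <- merge(records, led[, c("id", "total")], by = "id",
                     all.x = TRUE)
    names(records)[names(records) == "total"] <- "mmpbsa_total"
    records <- records[records$id %in% rk$better_than_control, ,
                       drop = FALSE]
    emit("energetics_pass", records)
    log_stage("energetics", nrow(records))
  }

  final <- final_report(records)
  emit("final_report", final)
  stages <- do.call(rbind, stages)
  stages$retention_pct <- retention_percentage(stages$count,
                                               stages$count[1])
  structure(list(stages = stages, records = records, final = final,
                 seed = seed),
            class = "funnel_report")
}

#' Rank funnel survivors into the final report table
#'
#' Sorted by docking score (ascending, best first) where available, then
#' by MM-PBSA total, then id. Missing optional columns render as NA.
#'
#' @param records funnel record data.frame (column `id` required).
#' @return ranked data.frame.
#' @export
final_report <- function(records) {
  if (nrow(records) == 0L) return(records)
  ds <- records$docking_score %||% rep(NA_real_, nrow(records))
  mt <- records$mmpbsa_total %||% rep(NA_real_, nrow(records))
  ord <- order(ds, mt, records$id, na.last = TRUE)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report> seed", x$seed, "\n")
  print(x$stages, row.names = FALSE)
  if (nrow(x$final)) {
    cat("final ranked compounds:\n")
    print(utils::head(x$final, 10), row.names = FALSE)
  } else cat("no compounds survived the funnel\n")
  invisible(x)
}
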