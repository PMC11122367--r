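#' Simulate a longitudinal macula-off RRD cohort
#'
#' Generates eye-level visit records mimicking the study structure: `n_eyes`
#' patients, each contributing a detached (RRD) eye and a healthy fellow
#' eye, followed preoperatively (fellow eye only for the vascular metrics —
#' the detached macula cannot be scanned) and at months 1, 3 and 6.
#'
#' The construction encodes one true functional effect and null vascular
#' effects:
#' \itemize{
#'   \item Preoperative BCVA of the RRD eye is drawn from the cohort
#'     distribution N(0.83, 0.29) logMAR (clamped to \[0.2, 2\]); month-6
#'     BCVA follows the mechanistic recovery model
#'     `0.30 + 0.25 * preop + N(0, 0.25)`, so worse preoperative vision
#'     leaves more room for a >= 0.3 logMAR gain — preop BCVA truly drives
#'     functional success.
#'   \item All OCTA metrics (VDI/VAD/VSD per plexus, FAZ) are drawn around
#'     the cohort means independently of the visual outcome: null effects.
#'     A per-subject random effect shared by both eyes induces the
#'     inter-eye correlation the fellow-eye-surrogate design relies on.
#' }
#'
#' @param n_eyes Number of patients (one RRD + one fellow eye each).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @return Data frame with one row per eye x visit: `eye_id`, `group`
#'   (`"RRD"`/`"fellow"`), `visit` (`"preop"`, `"m1"`, `"m3"`, `"m6"`),
#'   `bcva_logmar`, `vdi_scp`, `vad_scp`, `vsd_scp`, `vdi_dcp`, `vad_dcp`,
#'   `vsd_dcp`, `faz_mm2`, `quality_score`. RRD preop rows carry BCVA but
#'   `NA` metrics (no preoperative OCTA is possible in a detached macula).
#' @export
simulate_rrd_cohort <- function(n_eyes = 44L, seed = 1L) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  visits <- c("preop", "m1", "m3", "m6")
  # cohort-scale metric distributions (mean, SD = SE * sqrt(44))
  metric_mu <- c(vdi_scp = 19.2, vad_scp = 0.43, vsd_scp = 0.16,
                 vdi_dcp = 18.9, vad_dcp = 0.40, vsd_dcp = 0.15,
                 faz_mm2 = 0.24)
  metric_sd <- c(vdi_scp = 0.66, vad_scp = 0.02, vsd_scp = 0.013,
                 vdi_dcp = 0.66, vad_dcp = 0.03, vsd_dcp = 0.013,
                 faz_mm2 = 0.10)
  rows <- vector("list", n_eyes * 8L)
  k <- 0L
  for (i in seq_len(n_eyes)) {
    id <- sprintf("E%02d", i)
    # per-subject effect shared by both eyes and all visits (inter-eye corr.)
    subj <- rnorm(length(metric_mu), 0, 0.6 * metric_sd)
    preop_rrd <- min(2, max(0.2, rnorm(1, 0.83, 0.29)))
    bcva_m6 <- max(-0.1, 0.30 + 0.25 * preop_rrd + rnorm(1, 0, 0.25))
    bcva_m1 <- max(-0.1, bcva_m6 + 0.25 + rnorm(1, 0, 0.10))
    bcva_m3 <- max(-0.1, (bcva_m1 + bcva_m6) / 2 + rnorm(1, 0, 0.05))
    bcva_rrd <- c(preop = preop_rrd, m1 = bcva_m1, m3 = bcva_m3, m6 = bcva_m6)
    bcva_fel <- pmax(-0.1, rnorm(4, 0.05, 0.08))
    for (g in c("RRD", "fellow")) {
      for (vi in seq_along(visits)) {
        k <- k + 1L
        if (g == "RRD" && visits[vi] == "preop") {
          met <- setNames(rep(NA_real_, length(metric_mu)), names(metric_mu))
        } else {
          met <- metric_mu + subj + rnorm(length(metric_mu), 0, 0.8 * metric_sd)
          met <- pmax(met, c(1, 0.01, 0.01, 1, 0.01, 0.01, 0.02))
        }
        rows[[k]] <- data.frame(
          eye_id = id, group = g, visit = visits[vi],
          bcva_logmar = if (g == "RRD") unname(bcva_rrd[vi]) else bcva_fel[vi],
          t(met),
          quality_score = round(runif(1, 55, 90)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Eye-level analysis frame for the functional-success model
#'
#' Collapses visit records to one row per RRD eye: the success outcome
#' (month-6 BCVA improvement >= `threshold` from the eye's own preoperative
#' BCVA) plus the preoperative covariates, with the fellow eye's
#' preoperative metrics serving as surrogates for the unmeasurable
#' preoperative metrics of the detached eye.
#'
#' @param records Visit records as produced by [simulate_rrd_cohort()] (or
#'   real data in the same layout).
#' @param threshold Success cut-off in logMAR improvement (default 0.3).
#' @return One row per eye: `eye_id`, `success`, `preop_bcva`, `bcva_m6`,
#'   `improvement`, and the surrogate preoperative metric columns.
#' @export
functional_success_frame <- function(records, threshold = 0.3) {
  metric_cols <- intersect(
    c("vdi_scp", "vad_scp", "vsd_scp", "vdi_dcp", "vad_dcp", "vsd_dcp",
      "faz_mm2"), names(records))
  ids <- unique(records$eye_id[records$group == "RRD"])
  rows <- lapply(ids, function(id) {
    rrd <- records[records$eye_id == id & records$group == "RRD", ]
    fel <- records[records$eye_id == id & records$group == "fellow", ]
    pre <- rrd$bcva_logmar[rrd$visit == "preop"]
    post <- rrd$bcva_logmar[rrd$visit == "m6"]
    if (!length(pre) || !length(post)) return(NULL)
    surro <- fel[fel$visit == "preop", metric_cols, drop = FALSE]
    if (nrow(surro) == 0L) {
      surro <- as.data.frame(as.list(setNames(rep(NA_real_, length(metric_cols)),
                                              metric_cols)))
    }
    cbind(data.frame(eye_id = id,
                     success = classify_success(pre, post, threshold),
                     preop_bcva = pre, bcva_m6 = post,
                     improvement = bcva_change(pre, post),
                     stringsAsFactors = FALSE),
          surro, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Subject-by-visit matrix for repeated-measures analysis
#'
#' Extracts one variable as a complete subjects x visits matrix for
#' [rm_anova()]. Two documented analysis variants of the preoperative value
#' exist for RRD eyes, whose metrics cannot be measured preoperatively:
#' with `use_surrogate_preop = TRUE` the fellow eye's preoperative value is
#' substituted (variant "a"); with `FALSE` the preop visit is omitted and
#' only months 1, 3, 6 enter (variant "b").
#'
#' @param records Visit records (layout of [simulate_rrd_cohort()]).
#' @param variable Metric column name.
#' @param group Eye group to analyse (default `"RRD"`).
#' @param use_surrogate_preop See above.
#' @return Numeric matrix, eyes in rows, visits in columns.
#' @export
visit_matrix <- function(records, variable, group = "RRD",
                         use_surrogate_preop = TRUE) {
  stopifnot(variable %in% names(records))
  visits <- c(if (use_surrogate_preop) "preop", "m1", "m3", "m6")
  ids <- unique(records$eye_id[records$group == group])
  m <- matrix(NA_real_, length(ids), length(visits),
              dimnames = list(ids, visits))
  for (i in seq_along(ids)) {
    for (j in seq_along(visits)) {
      src_group <- if (visits[j] == "preop" && group == "RRD" &&
                       use_surrogate_preop) "fellow" else group
      val <- records[[variable]][records$eye_id == ids[i] &
                                 records$group == src_group &
                                 records$visit == visits[j]]
      if (length(val) == 1L) m[i, j] <- val
    }
  }
  m
}
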