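sidakAdjust <- function(p, m = length(p)) pmin(1, 1 - (1 - p)^m)

# Dunn's rank-sum post hoc z tests (with tie correction), Sidak-adjusted.
dunnPosthoc <- function(samples) {
  g <- rep(names(samples), lengths(samples))
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tieCorr
  prs <- utils::combn(names(samples), 2)
  z <- vapply(seq_len(ncol(prs)), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    (rbar[[a]] - rbar[[b]]) / sqrt(s2 * (1 / n[[a]] + 1 / n[[b]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = prs[1, ], group2 = prs[2, ], statistic = z,
             p_adj = sidakAdjust(p))
}

#' Normality-gated group comparison
#'
#' Compares two or more groups of observations the way locomotor tuning
#' and decoding metrics are compared across brain areas: each group is
#' first tested for normality (Lilliefors test at p < 0.05; groups too
#' small for the test count as non-normal). If every group passes, the
#' parametric branch runs — one-way ANOVA with Tukey post hoc for
#' independent groups, repeated-measures ANOVA with Sidak-adjusted paired
#' t post hocs for paired designs. Otherwise the non-parametric branch
#' runs — Kruskal-Wallis with Dunn-Sidak post hoc, or the Friedman test
#' with Sidak-adjusted signed-rank post hocs when paired. Groups with
#' fewer than 3 observations are excluded with a notice. All omnibus
#' tests are standard library routines.
#'
#' @param samples named list of numeric vectors (independent design) or a
#'   numeric matrix with subjects in rows and named group columns (paired
#'   design).
#' @param paired treat columns as repeated measures on the same subjects.
#' @return list with \code{test}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{normal}, \code{posthoc} (data.frame of
#'   adjusted pairwise comparisons) and \code{excluded} group names.
#' @export
compareGroups <- function(samples, paired = FALSE) {
  if (paired && is.matrix(samples)) {
    mat <- samples
    samples <- lapply(seq_len(ncol(mat)), function(j) mat[, j])
    names(samples) <- colnames(mat)
  } else mat <- NULL
  stopifnot(!is.null(names(samples)))
  small <- names(samples)[lengths(samples) < 3]
  if (length(small)) {
    message("excluding group(s) with n < 3: ", paste(small, collapse = ", "))
    samples <- samples[lengths(samples) >= 3]
    if (!is.null(mat)) mat <- mat[, names(samples), drop = FALSE]
  }
  if (length(samples) < 2) stop("need at least 2 groups of n >= 3")

  isNormal <- vapply(samples, function(v) {
    if (length(v) < 5 || stats::sd(v) < 1e-12) return(FALSE)
    nortest::lillie.test(v)$p.value >= 0.05
  }, logical(1))
  normal <- all(isNormal)
  gn <- names(samples)

  if (!paired) {
    g <- factor(rep(gn, lengths(samples)), levels = gn)
    x <- unlist(samples, use.names = FALSE)
    if (normal) {
      fit <- stats::aov(x ~ g)
      sm <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$g
      ph <- data.frame(
        group1 = sub("-.*$", "", rownames(tk)),
        group2 = sub("^[^-]*-", "", rownames(tk)),
        statistic = tk[, "diff"], p_adj = tk[, "p adj"])
      out <- list(test = "one-way ANOVA + Tukey",
                  statistic = sm[["F value"]][1],
                  df = sm[["Df"]], p_value = sm[["Pr(>F)"]][1])
    } else {
      kw <- stats::kruskal.test(x, g)
      ph <- dunnPosthoc(samples)
      out <- list(test = "Kruskal-Wallis + Dunn-Sidak",
                  statistic = unname(kw$statistic),
                  df = unname(kw$parameter), p_value = kw$p.value)
    }
  } else {
    if (is.null(mat)) stop("paired design needs a subjects x groups matrix")
    nSub <- nrow(mat)
    long <- data.frame(y = as.vector(mat),
                       grp = factor(rep(gn, each = nSub), levels = gn),
                       subj = factor(rep(seq_len(nSub), times = ncol(mat))))
    prs <- utils::combn(gn, 2)
    if (normal) {
      fit <- stats::aov(y ~ grp + Error(subj), data = long)
      sm <- summary(fit)[["Error: Within"]][[1]]
      p <- vapply(seq_len(ncol(prs)), function(k)
        stats::t.test(mat[, prs[1, k]], mat[, prs[2, k]],
                      paired = TRUE)$p.value, numeric(1))
      ph <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                       statistic = NA_real_, p_adj = sidakAdjust(p))
      out <- list(test = "repeated-measures ANOVA + Sidak paired t",
                  statistic = sm[["F value"]][1], df = sm[["Df"]],
                  p_value = sm[["Pr(>F)"]][1])
    } else {
      fr <- stats::friedman.test(mat)
      p <- vapply(seq_len(ncol(prs)), function(k)
        suppressWarnings(stats::wilcox.test(mat[, prs[1, k]],
                                            mat[, prs[2, k]],
                                            paired = TRUE))$p.value,
        numeric(1))
      ph <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                       statistic = NA_real_, p_adj = sidakAdjust(p))
      out <- list(test = "Friedman + Sidak signed-rank",
                  statistic = unname(fr$statistic),
                  df = unname(fr$parameter), p_value = fr$p.value)
    }
  }
  rownames(ph) <- NULL
  c(out, list(normal = normal, posthoc = ph, excluded = small))
}

#' Pairwise chi-squared comparison of proportions
#'
#' Compares per-group proportions (e.g. percent speed-correlated or
#' phase-locked units per area) by 2x2 chi-squared tests for every pair of
#' groups, Sidak-adjusted for the number of comparisons (6 for four
#' groups).
#'
#' @param successes named integer vector of counts of interest.
#' @param totals integer vector of group sizes (same names).
#' @return data.frame with the pairwise \code{statistic} and \code{p_adj}.
#' @export
compareProportions <- function(successes, totals) {
  stopifnot(length(successes) == length(totals),
            !is.null(names(successes)))
  gn <- names(successes)
  prs <- utils::combn(gn, 2)
  m <- ncol(prs)
  rows <- lapply(seq_len(m), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    tb <- rbind(c(successes[[a]], totals[[a]] - successes[[a]]),
                c(successes[[b]], totals[[b]] - successes[[b]]))
    ct <- suppressWarnings(stats::chisq.test(tb))
    data.frame(group1 = a, group2 = b, statistic = unname(ct$statistic),
               p_raw = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidakAdjust(out$p_raw, m)
  out
}

#' Run the full analysis over a cohort of sessions
#'
#' Executes segmentation, per-unit statistics and the three decoding tasks
#' for every region represented in the cohort, then compares regions on
#' draw-level decoding accuracies and on tuning proportions. Fully
#' deterministic under a fixed seed; re-running writes byte-identical
#' outputs.
#'
#' @param cohort list of \linkS4class{GaitSession} objects, or a directory
#'   whose sub-directories are sessions readable by [readSession()].
#' @param config configuration list (see [defaultConfig()]); reduce
#'   quotas, draw counts and jitter iterations for small cohorts.
#' @param out optional output directory for \code{report.json} and
#'   per-stage TSV tables.
#' @param tasks decoding tasks to run.
#' @param limb decoded limb for the phase task.
#' @return The report: a nested list with per-region unit counts,
#'   modulated-fraction curves, tuning percentages, decoding summaries and
#'   the group-comparison tables.
#' @export
runAll <- function(cohort, config = defaultConfig(), out = NULL,
                   tasks = c("time", "speed", "phase"), limb = "LR") {
  seed <- config$random_seed
  if (is.character(cohort)) {
    dirs <- list.dirs(cohort, recursive = FALSE)
    cohort <- lapply(dirs, readSession)
  }
  stopifnot(length(cohort) >= 1)
  regions <- unique(unlist(lapply(cohort, function(s)
    vapply(units(s), region, character(1)))))

  segs <- lapply(cohort, function(s) {
    res <- try(segmentSession(s, config), silent = TRUE)
    if (inherits(res, "try-error"))
      stop("segmentation failed for session '", sessionId(s), "': ",
           attr(res, "condition")$message)
    res
  })
  names(segs) <- vapply(cohort, sessionId, character(1))

  statsTab <- do.call(rbind, lapply(seq_along(cohort), function(i)
    unitStats(cohort[[i]], segs[[i]], config, seed = seed,
              jitterIterations = config$jitter_iterations)))

  report <- list(config = config, regions = list(), comparisons = list())
  draws <- list(pre = list(), post = list(), phase = list(), speed = list())
  for (rg in regions) {
    sel <- vapply(cohort, function(s)
      any(vapply(units(s), region, character(1)) == rg), logical(1))
    rSessions <- cohort[sel]; rSegs <- segs[sel]
    rStats <- statsTab[statsTab$region == rg, , drop = FALSE]

    # peri-onset modulation, units pooled across the region's sessions
    rms <- list(); centers <- NULL
    for (i in seq_along(rSessions)) {
      fps <- frameRate(rSessions[[i]])
      onsets <- (rSegs[[i]]$bouts$onset_frame + 1) / fps
      onsets <- onsets[onsets > config$mod_window &
                       onsets < duration(rSessions[[i]]) - config$mod_window]
      if (length(onsets) < 2) next
      for (u in units(rSessions[[i]])) {
        rm <- estimateRates(u, onsets,
                            window = c(-config$mod_window, config$mod_window),
                            kernelSd = config$kernel_sd,
                            baseBin = config$base_bin, outBin = config$mod_bin)
        rms <- c(rms, list(rm$rates)); centers <- rm$centers
      }
    }
    modFrac <- if (length(rms) >= 1)
      modulatedFraction(rms, centers, config$baseline_window, config$alpha)
    else NULL

    entry <- list(
      n_units = nrow(rStats),
      pct_speed_correlated = 100 * mean(rStats$speed_p < config$alpha,
                                        na.rm = TRUE),
      pct_phase_locked = 100 * mean(rStats$locked_any),
      modulated_fraction = if (is.null(modFrac)) NULL else
        list(centers = modFrac$centers, fraction = modFrac$fraction),
      decoding = list())

    for (task in tasks) {
      tensor <- tryCatch(
        buildTrials(rSessions, rSegs, task, config,
                    seed = deriveSeed(seed, paste0(rg, "/trials")),
                    limb = limb),
        error = function(e) NULL)
      if (is.null(tensor)) next
      U <- dim(tensor@rates)[2]
      nU <- min(U, switch(task, time = config$n_units_time,
                          speed = config$n_units_speed,
                          phase = config$n_units_phase))
      res <- evaluateDecoder(tensor, config, nUnits = nU,
                             seed = deriveSeed(seed, paste0(rg, "/", task)))
      sn <- shuffleNull(tensor, config, nShuffles = config$n_shuffles,
                        nUnits = nU, nIterations = min(5, config$n_eval_iterations),
                        seed = deriveSeed(seed, paste0(rg, "/", task, "/null")))
      res@shuffleBand <- sn$band
      summary <- list(overall_accuracy = res@overallAccuracy,
                      class_accuracy = res@classAccuracy,
                      class_values = res@classValues,
                      error_metric = res@errorMetric,
                      draw_accuracy = res@drawAccuracy,
                      shuffle_band = res@shuffleBand,
                      n_units = res@nUnits)
      if (task == "time") {
        pp <- prePostSummary(res)
        summary$pre_start <- pp$pre; summary$post_start <- pp$post
        draws$pre[[rg]] <- pp$pre_draws; draws$post[[rg]] <- pp$post_draws
      }
      if (task == "phase") draws$phase[[rg]] <- res@drawAccuracy
      if (task == "speed") draws$speed[[rg]] <- res@drawAccuracy
      entry$decoding[[task]] <- summary
    }
    report$regions[[rg]] <- entry
  }

  if (length(regions) >= 2) {
    for (what in names(draws)) if (length(draws[[what]]) >= 2)
      report$comparisons[[paste0(what, "_accuracy")]] <-
        compareGroups(draws[[what]])
    lockedN <- vapply(regions, function(rg)
      sum(statsTab$locked_any[statsTab$region == rg]), numeric(1))
    totalN <- vapply(regions, function(rg)
      sum(statsTab$region == rg), numeric(1))
    names(lockedN) <- names(totalN) <- regions
    if (all(totalN >= 3))
      report$comparisons$phase_locked_proportion <-
        compareProportions(lockedN, totalN)
    report$comparisons$note <- paste(
      "group comparisons use draw-level decoding accuracies as samples;",
      "draws share units and trials and are not independent")
  } else {
    report$comparisons$note <- "single region: group comparisons skipped"
  }

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    data.table::fwrite(statsTab, file.path(out, "unit_stats.tsv"), sep = "\t")
    for (i in seq_along(segs)) {
      d <- file.path(out, names(segs)[i])
      dir.create(d, showWarnings = FALSE)
      data.table::fwrite(segs[[i]]$bouts, file.path(d, "bouts.tsv"), sep = "\t")
      data.table::fwrite(segs[[i]]$strides, file.path(d, "strides.tsv"),
                         sep = "\t")
    }
  }
  report
}
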