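# Orchestration: simulate -> segment -> vdm -> depths -> extract -> stats,
# as one reproducible run with a single config and a provenance report.

.rbind_list <- function(x) {
  x <- x[!vapply(x, is.null, TRUE)]
  if (!length(x)) return(NULL)
  out <- do.call(rbind, x)
  rownames(out) <- NULL
  out
}

#' Run the full statistical battery on a condition table
#'
#' Per metric (qT1, pQSM, nQSM):
#' * mixed ANOVA (group x area x compartment x distance) on four distance
#'   conditions (excluding the closest bin), complete-case;
#' * the same ANOVA on five distance conditions with the closest-bin cells
#'   completed by monotone multiple imputation, pooled by the D2 rule;
#' * post hoc families: consecutive-bin paired t-tests (overall and per
#'   area; Holm-adjusted within family, Hedges d with bootstrap CI) and
#'   per-bin between-group Welch tests with Monte-Carlo permutation
#'   analogues;
#' * random-intercept model comparisons in the old group (per area):
#'   value ~ bin (+ risk (+ bin:risk)) with participant intercepts;
#' * Pearson correlations of pQSM vs qT1 per (group, area, bin).
#'
#' Post hoc tests and the descriptive bin means use the average of the
#' completed datasets so every participant contributes to every bin, as in
#' an imputed repeated-measures analysis.
#'
#' @param tab condition table for the whole cohort.
#' @param config a [study_config()].
#' @return Named list of result data.frames (`anova`, `posthoc`,
#'   `permutation`, `lmm`, `correlations`) plus a `notes` list (dropped
#'   subjects, imputation counts).
#' @export
run_statistics <- function(tab, config = study_config()) {
  bins_all <- bin_labels(config$bin_edges)
  bins_far <- bins_all[-1]
  seeds <- config$seeds
  anova_rows <- list()
  posthoc <- list()
  perm <- list()
  lmm_rows <- list()
  notes <- list()

  collapse_bins <- function(Y, cond) {
    vapply(split(seq_len(ncol(Y)), cond$distance_bin)[unique(cond$distance_bin)],
           function(ix) rowMeans(Y[, ix, drop = FALSE]), numeric(nrow(Y)))
  }

  completed <- list()
  for (metric in .metric_levels) {
    cells5 <- cell_means_matrix(tab, metric, bins = bins_all)
    # subjects missing cells outside the closest bin cannot be completed by
    # the monotone scheme and are dropped from the ANOVA input
    far_cols <- cells5$conditions$distance_bin != bins_all[1]
    ok_subj <- !apply(is.na(cells5$Y[, far_cols, drop = FALSE]), 1, any)
    if (!all(ok_subj)) {
      notes[[paste0(metric, "_dropped")]] <- cells5$participants[!ok_subj]
      cells5$Y <- cells5$Y[ok_subj, , drop = FALSE]
      cells5$group <- droplevels(cells5$group[ok_subj])
      cells5$risk <- cells5$risk[ok_subj]
      cells5$participants <- cells5$participants[ok_subj]
    }
    n_missing <- sum(is.na(cells5$Y))
    notes[[paste0(metric, "_missing_cells")]] <- n_missing

    within <- cells5$conditions[, c("area", "compartment", "distance_bin")]
    names(within) <- c("area", "depth", "distance")

    # four distance conditions, no imputation
    keep4 <- cells5$conditions$distance_bin %in% bins_far
    a4 <- mixed_anova(cells5$Y[, keep4, drop = FALSE], cells5$group,
                      within[keep4, ])
    a4$metric <- metric; a4$analysis <- "4bins"
    anova_rows[[paste0(metric, "_4")]] <- a4

    # five distance conditions with monotone imputation
    comp <- monotone_impute(cells5, m = config$m_imputations,
                            seed = seeds[["imputation"]])
    a5 <- lapply(comp, function(Yl) mixed_anova(Yl, cells5$group, within))
    pooled <- pool_imputed_anova(a5)
    pooled$metric <- metric; pooled$analysis <- "5bins_imputed"
    anova_rows[[paste0(metric, "_5")]] <- pooled

    Ybar <- Reduce(`+`, comp) / length(comp)
    completed[[metric]] <- list(Ybar = Ybar, cells = cells5)
    binY <- collapse_bins(Ybar, cells5$conditions)

    # consecutive-bin paired families (overall and per area)
    fam_defs <- c(list(overall = seq_len(ncol(cells5$Y))),
                  stats::setNames(
                    lapply(unique(cells5$conditions$area), function(a)
                      which(cells5$conditions$area == a)),
                    unique(cells5$conditions$area)))
    for (fam in names(fam_defs)) {
      ix <- fam_defs[[fam]]
      bY <- collapse_bins(Ybar[, ix, drop = FALSE],
                          cells5$conditions[ix, , drop = FALSE])
      res <- lapply(seq_len(ncol(bY) - 1L), function(b) {
        tt <- paired_t(bY[, b], bY[, b + 1L])
        hd <- hedges_d(bY[, b], bY[, b + 1L], paired = TRUE,
                       B_boot = config$B_boot, seed = seeds[["bootstrap"]])
        data.frame(metric = metric, family = paste0("distance_", fam),
                   comparison = paste(colnames(bY)[b], "vs",
                                      colnames(bY)[b + 1L]),
                   t = tt$t, df = tt$df, p = tt$p, p_holm = NA_real_,
                   d = hd$d, d_lo = hd$ci[1], d_hi = hd$ci[2],
                   n1 = tt$n[1], n2 = tt$n[2], stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      res$p_holm <- holm_bonferroni(res$p)
      posthoc[[paste(metric, fam, sep = "_")]] <- res
    }

    # between-group Welch per bin (one family of 5), with permutation analog;
    # skipped (with a note) when a group has fewer than 3 retained subjects
    if (nlevels(cells5$group) == 2L &&
        all(table(cells5$group) >= 3L)) {
      gl <- levels(cells5$group)
      res <- lapply(seq_len(ncol(binY)), function(b) {
        a <- binY[cells5$group == gl[1], b]
        bb <- binY[cells5$group == gl[2], b]
        tt <- welch_t(a, bb)
        hd <- hedges_d(a, bb, paired = FALSE, B_boot = config$B_boot,
                       seed = seeds[["bootstrap"]])
        pp <- permutation_welch(a, bb, B = config$B_perm,
                                seed = seeds[["permutation"]])
        data.frame(metric = metric, family = "group_by_bin",
                   comparison = colnames(binY)[b],
                   t = tt$t, df = tt$df, p = tt$p, p_holm = NA_real_,
                   d = hd$d, d_lo = hd$ci[1], d_hi = hd$ci[2],
                   n1 = tt$n[1], n2 = tt$n[2], p_perm = pp$p,
                   stringsAsFactors = FALSE)
      })
      res <- do.call(rbind, res)
      res$p_holm <- holm_bonferroni(res$p)
      perm[[metric]] <- res
    } else {
      notes[[paste0(metric, "_group_tests_skipped")]] <-
        "fewer than 3 retained subjects in a group"
    }

    # random-intercept models in the old group, per area
    old_tab <- tab[tab$metric == metric & tab$group == "old" &
                     !is.na(tab$value), , drop = FALSE]
    for (a in unique(old_tab$area)) {
      at <- old_tab[old_tab$area == a, , drop = FALSE]
      agg <- stats::aggregate(value ~ participant_id + distance_bin + risk,
                              data = at, FUN = mean)
      agg$distance_bin <- droplevels(factor(agg$distance_bin,
                                            levels = bins_all))
      enough <- names(which(table(agg$participant_id) >= 2))
      agg <- agg[agg$participant_id %in% enough, , drop = FALSE]
      if (length(unique(agg$participant_id)) < 3L ||
          length(unique(agg$risk)) < 2L) next
      fits <- tryCatch({
        f0 <- fit_random_intercept(value ~ distance_bin, agg)
        f1 <- fit_random_intercept(value ~ distance_bin + risk, agg)
        f2 <- fit_random_intercept(value ~ distance_bin * risk, agg)
        list(f0 = f0, f1 = f1, f2 = f2)
      }, error = function(e) NULL)
      if (is.null(fits)) {
        notes[[paste(metric, a, "lmm_skipped", sep = "_")]] <-
          "singular fixed-effect design at this cohort size"
        next
      }
      f0 <- fits$f0; f1 <- fits$f1; f2 <- fits$f2
      c1 <- lrt_compare(f1, f0)
      c2 <- lrt_compare(f2, f0)
      lmm_rows[[paste(metric, a)]] <- data.frame(
        metric = metric, area = a,
        comparison = c("risk_vs_null", "risk_interaction_vs_null"),
        chisq = c(c1$chisq, c2$chisq), df = c(c1$df, c2$df),
        p = c(c1$p, c2$p),
        sigma_b2 = f2$sigma_b2, sigma2 = f2$sigma2,
        stringsAsFactors = FALSE)
    }
  }

  # Pearson correlations pQSM vs qT1 per (group, area, bin)
  corr_rows <- list()
  if (all(c("qT1", "pQSM") %in% names(completed))) {
    cq <- completed[["qT1"]]; cp <- completed[["pQSM"]]
    common <- intersect(cq$cells$participants, cp$cells$participants)
    iq <- match(common, cq$cells$participants)
    ip <- match(common, cp$cells$participants)
    bq <- list(); bp <- list()
    for (a in unique(cq$cells$conditions$area)) {
      ixq <- which(cq$cells$conditions$area == a)
      ixp <- which(cp$cells$conditions$area == a)
      Bq <- collapse_bins(cq$Ybar[iq, ixq, drop = FALSE],
                          cq$cells$conditions[ixq, , drop = FALSE])
      Bp <- collapse_bins(cp$Ybar[ip, ixp, drop = FALSE],
                          cp$cells$conditions[ixp, , drop = FALSE])
      grp <- cq$cells$group[iq]
      for (g in levels(grp)) for (b in colnames(Bq)) {
        sel <- grp == g
        if (sum(sel) < 4L) next
        ct <- tryCatch(pearson_corr(Bp[sel, b], Bq[sel, b]),
                       error = function(e) NULL)
        if (is.null(ct)) next
        corr_rows[[paste(a, g, b)]] <- data.frame(
          area = a, group = g, distance_bin = b, r = ct$r, p = ct$p,
          n = ct$n, stringsAsFactors = FALSE)
      }
    }
  }

  list(anova = anova_rows,
       posthoc = .rbind_list(posthoc),
       permutation = .rbind_list(perm),
       lmm = .rbind_list(lmm_rows),
       correlations = .rbind_list(corr_rows),
       notes = notes)
}

#' Run a complete study end to end
#'
#' simulate -> segment veins -> distance transform -> equi-volume depths ->
#' condition extraction -> statistics, writing all tabular outputs and a
#' JSON provenance report (seeds, thresholds, vein counts, missingness,
#' timings) to `out_dir`. Two runs with the same config produce bit-identical
#' TSVs; per-subject processing is independent of subject order.
#'
#' @param config a [study_config()].
#' @param out_dir writable output directory (created if needed).
#' @return The run report, invisibly.
#' @export
run_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  spec <- config$phantom
  spec$seed <- unname(config$seeds[["cohort"]])

  subj_info <- list()
  stage_time <- c(simulate_extract = NA_real_, stats = NA_real_)
  t0 <- proc.time()[3]
  rows <- generate_cohort(spec, callback = function(subj) {
    out <- tryCatch(
      subject_condition_table(subj, config, use = "measured"),
      error = function(e) stop("stage extract failed for subject ",
                               subj$id, ": ", conditionMessage(e),
                               call. = FALSE))
    seg <- attr(out, "segmentation")
    subj_info[[subj$id]] <<- c(list(id = subj$id, group = subj$group,
                                    risk = subj$risk, seed = subj$seed),
                               seg)
    if (isTRUE(config$save_volumes)) {
      write_volume(subj$qt1, file.path(out_dir,
                                       paste0(subj$id, "_qt1.nii.gz")))
      write_volume(subj$qsm, file.path(out_dir,
                                       paste0(subj$id, "_qsm.nii.gz")))
    }
    out
  })
  manifest <- attr(rows, "manifest")
  tab <- .rbind_list(rows)
  stage_time["simulate_extract"] <- proc.time()[3] - t0
  write_condition_table(tab, file.path(out_dir, "condition_table.tsv"),
                        min_voxels = config$min_voxels_per_bin)
  utils::write.table(manifest, file.path(out_dir, "cohort_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  t0 <- proc.time()[3]
  stats <- run_statistics(tab, config)
  stage_time["stats"] <- proc.time()[3] - t0

  for (metric in .metric_levels) {
    a4 <- stats$anova[[paste0(metric, "_4")]]
    a5 <- stats$anova[[paste0(metric, "_5")]]
    utils::write.table(a4, file.path(out_dir,
                                     paste0("anova_", tolower(metric),
                                            "_4bins.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(a5, file.path(out_dir,
                                     paste0("anova_", tolower(metric),
                                            "_5bins_imputed.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (nm in c("posthoc", "permutation", "lmm", "correlations")) {
    x <- stats[[nm]]
    if (is.null(x) || !NROW(x)) next
    utils::write.table(x, file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("venalamina")),
    seed = config$seed,
    seeds = as.list(config$seeds),
    n_subjects = nrow(manifest),
    bin_edges = config$bin_edges,
    min_voxels_per_bin = config$min_voxels_per_bin,
    depth_mode = config$depth_mode,
    subjects = unname(subj_info),
    notes = stats$notes,
    stage_seconds = as.list(round(stage_time, 2)),
    outputs = list.files(out_dir),
    finished = format(t_start, "%Y-%m-%dT%H:%M:%S")
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       force = TRUE)
  invisible(report)
}

#' Reference worked-example p-value families for the Holm procedure
#'
#' Raw post hoc p-values reported by the source study for its two internally
#' consistent step-down families (the overall distance family and the M1
#' distance family for qT1), used as fixed inputs for validating
#' [holm_bonferroni()] against the study's printed adjusted values. The
#' unreported largest member of each four-comparison family does not affect
#' the adjusted values of the smaller ranks and is entered as 1.
#'
#' @return List of numeric vectors (named by comparison) and the printed
#'   adjusted values for the reported members.
#' @export
reference_posthoc_families <- function() {
  list(
    qt1_distance = list(
      raw = c("0-2 vs 2-4" = 9.353e-5, "2-4 vs 4-6" = 0.010,
              "4-6 vs 6-8" = 0.024, "6-8 vs 8-10" = 1),
      printed_holm = c("0-2 vs 2-4" = 3.74e-4, "2-4 vs 4-6" = 0.03,
                       "4-6 vs 6-8" = 0.048)),
    qt1_distance_m1 = list(
      raw = c("0-2 vs 2-4" = 1.871e-5, "2-4 vs 4-6" = 8.952e-5,
              "4-6 vs 6-8" = 0.012, "6-8 vs 8-10" = 1),
      printed_holm = c("0-2 vs 2-4" = 7.484e-5, "2-4 vs 4-6" = 2.686e-4,
                       "4-6 vs 6-8" = 0.024))
  )
}
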