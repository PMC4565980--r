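## Group-level comparisons and report generation across conditions.

#' Compare two groups of per-nucleus or per-telomere measurements
#'
#' Two-sided two-sample t-test, Welch (unequal variances) by default with a
#' pooled-variance option, reporting group means with SEM.
#'
#' @param group_a,group_b numeric vectors (each of length at least 2).
#' @param var_equal use the pooled-variance (classical Student) test.
#' @return object of class \code{group_comparison}.
#' @export
compare_means <- function(group_a, group_b, var_equal = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  eff <- data.frame(
    group = c("a", "b"),
    n = c(length(group_a), length(group_b)),
    mean = c(mean(group_a), mean(group_b)),
    sem = c(sd(group_a) / sqrt(length(group_a)),
            sd(group_b) / sqrt(length(group_b))))
  structure(list(statistic_name = "t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 group_sizes = c(length(group_a), length(group_b)),
                 effect_summary = eff,
                 welch = !var_equal),
            class = "group_comparison")
}

#' Compare category histograms between two conditions
#'
#' Chi-square test of homogeneity on a k x 2 contingency table of category
#' counts (no continuity correction).
#'
#' @param hist_a,hist_b integer vectors of category counts (same length,
#'   typically 3: low/average/high).
#' @return object of class \code{group_comparison}.
#' @export
compare_categories <- function(hist_a, hist_b) {
  stopifnot(length(hist_a) == length(hist_b))
  if (sum(hist_a) == 0 || sum(hist_b) == 0)
    stop("both histograms need positive totals")
  tab <- rbind(a = as.numeric(hist_a), b = as.numeric(hist_b))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]  # absent categories carry no information
  if (ncol(tab) < 2) stop("need at least two non-empty categories")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    stop("expected cell count below 1; pool sparse categories before testing")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  eff <- data.frame(group = c("a", "b"),
                    rbind(hist_a / sum(hist_a), hist_b / sum(hist_b)))
  structure(list(statistic_name = "chi2", statistic = unname(ct$statistic),
                 p_value = ct$p.value, df = unname(ct$parameter),
                 group_sizes = c(sum(hist_a), sum(hist_b)),
                 effect_summary = eff),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s = %.4f (df = %.4g), p = %.3g; group sizes %s\n",
              x$statistic_name, x$statistic, x$df, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Plot aggregated radial profiles
#'
#' Mean normalized intensity versus distance per condition with SEM bands.
#'
#' @param summary a \code{\link{aggregate_profiles}} result.
#' @param ... passed to \code{matplot}.
#' @export
plot_profiles <- function(summary, ...) {
  stopifnot(inherits(summary, "profile_summary"))
  conds <- unique(summary$condition)
  cols <- grDevices::hcl.colors(max(2L, length(conds)), "Dark 2")
  first <- TRUE
  for (i in seq_along(conds)) {
    s <- summary[summary$condition == conds[i], ]
    if (first) {
      graphics::plot(s$distance_nm, s$mean_norm, type = "l", col = cols[i],
                     xlab = "distance from telomere center (nm)",
                     ylab = "normalized intensity",
                     ylim = c(0, max(summary$mean_norm + summary$sem,
                                     na.rm = TRUE)), ...)
      first <- FALSE
    } else graphics::lines(s$distance_nm, s$mean_norm, col = cols[i])
    graphics::lines(s$distance_nm, s$mean_norm + s$sem, lty = 3, col = cols[i])
    graphics::lines(s$distance_nm, s$mean_norm - s$sem, lty = 3, col = cols[i])
  }
  graphics::legend("topright", legend = conds, col = cols[seq_along(conds)],
                   lty = 1, bty = "n")
  invisible(summary)
}

#' Build a summary report from per-telomere and per-nucleus tables
#'
#' Writes per-condition summary tables: mean normalized profile curves,
#' LAP2c statistics, category proportions and the fraction of telomeres
#' within the lamina proximity threshold, plus a JSON overview. An empty
#' telomere table produces a report with an explicit no-telomeres marker.
#'
#' @param telomere_table data.frame with columns \code{condition},
#'   \code{nucleus_id}, \code{telomere_id}, \code{coverage_percent},
#'   \code{category}, \code{distance_nm}, \code{within_threshold} and
#'   optionally normalized profile sample columns named \code{norm_<dist>}.
#' @param nucleus_table data.frame with columns \code{condition},
#'   \code{nucleus_id}, \code{lap2c_percent}, \code{sigma_percent},
#'   \code{n_telomeres}.
#' @param out_dir output directory (created if needed).
#' @param comparisons optional named list of \code{group_comparison} objects
#'   to include in the JSON overview.
#' @param plots also write PNG figures.
#' @return invisibly, a list with the written paths and the summary tables.
#' @export
build_report <- function(telomere_table, nucleus_table, out_dir,
                         comparisons = NULL, plots = FALSE) {
  need_tel <- c("condition", "nucleus_id", "telomere_id", "coverage_percent",
                "category", "distance_nm", "within_threshold")
  need_nuc <- c("condition", "nucleus_id", "lap2c_percent", "sigma_percent",
                "n_telomeres")
  miss <- setdiff(need_tel, names(telomere_table))
  if (length(miss))
    stop("telomere_table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(need_nuc, names(nucleus_table))
  if (length(miss))
    stop("nucleus_table is missing column(s): ", paste(miss, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  summaries <- list()

  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0

  # per-condition nucleus summary
  nuc_sum <- do.call(rbind, lapply(split(nucleus_table,
                                         nucleus_table$condition), function(g)
    data.frame(condition = g$condition[1], n_nuclei = nrow(g),
               lap2c_mean = mean(g$lap2c_percent),
               lap2c_sem = sem(g$lap2c_percent),
               n_telomeres = sum(g$n_telomeres))))
  paths$nuclei <- file.path(out_dir, "summary_nuclei.csv")
  write_records(nuc_sum, paths$nuclei)
  summaries$nuclei <- nuc_sum

  if (nrow(telomere_table) == 0L) {
    overview <- list(no_telomeres = TRUE, n_conditions =
                       length(unique(nucleus_table$condition)))
    paths$overview <- file.path(out_dir, "report.json")
    jsonlite::write_json(overview, paths$overview, auto_unbox = TRUE)
    return(invisible(list(paths = paths, summaries = summaries)))
  }

  # profile curves
  prof_cols <- grep("^norm_", names(telomere_table), value = TRUE)
  if (length(prof_cols)) {
    dists <- as.numeric(sub("^norm_", "", prof_cols))
    prof_sum <- do.call(rbind, lapply(split(telomere_table,
                                            telomere_table$condition),
      function(g) {
        mat <- as.matrix(g[, prof_cols, drop = FALSE])
        data.frame(condition = g$condition[1], distance_nm = dists,
                   mean_norm = colMeans(mat, na.rm = TRUE),
                   sem = apply(mat, 2, function(v)
                     sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
      }))
    paths$profiles <- file.path(out_dir, "summary_profiles.csv")
    write_records(prof_sum, paths$profiles)
    summaries$profiles <- prof_sum
  }

  # category proportions
  cat_sum <- do.call(rbind, lapply(split(telomere_table,
                                         telomere_table$condition),
    function(g) {
      tab <- table(factor(g$category, levels = c("low", "average", "high")))
      data.frame(condition = g$condition[1], category = names(tab),
                 count = as.integer(tab),
                 proportion = as.numeric(tab) / sum(tab))
    }))
  paths$categories <- file.path(out_dir, "summary_categories.csv")
  write_records(cat_sum, paths$categories)
  summaries$categories <- cat_sum

  # lamina proximity fractions (within + outside sum to 1 per condition)
  lam_sum <- do.call(rbind, lapply(split(telomere_table,
                                         telomere_table$condition),
    function(g) {
      w <- mean(g$within_threshold)
      data.frame(condition = g$condition[1], n = nrow(g),
                 fraction_within = w, fraction_outside = 1 - w,
                 mean_distance_nm = mean(g$distance_nm))
    }))
  paths$lamina <- file.path(out_dir, "summary_lamina.csv")
  write_records(lam_sum, paths$lamina)
  summaries$lamina <- lam_sum

  overview <- list(no_telomeres = FALSE,
                   n_conditions = length(unique(telomere_table$condition)),
                   n_telomeres = nrow(telomere_table),
                   n_nuclei = nrow(nucleus_table))
  if (!is.null(comparisons))
    overview$comparisons <- lapply(comparisons, function(cmp)
      list(statistic_name = cmp$statistic_name, statistic = cmp$statistic,
           p_value = cmp$p_value))
  paths$overview <- file.path(out_dir, "report.json")
  jsonlite::write_json(overview, paths$overview, auto_unbox = TRUE, digits = NA)

  if (plots && length(prof_cols)) {
    paths$profile_plot <- file.path(out_dir, "profiles.png")
    grDevices::png(paths$profile_plot, width = 800, height = 600)
    ps <- summaries$profiles
    class(ps) <- c("profile_summary", "data.frame")
    plot_profiles(ps)
    grDevices::dev.off()
  }
  invisible(list(paths = paths, summaries = summaries))
}
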