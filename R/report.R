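#' Assemble the full study report
#'
#' Reassembles the evaluation a method-validation study reports: per-method
#' descriptive summaries of measurements and volumes, measurement-volume
#' Spearman correlations with CIs, mean-split subgroup correlations, one-way
#' inter-rater ICCs (when ratings are supplied), and exact binomial
#' feasibility proportions (when counts are supplied). Optionally written as
#' CSV tables plus a human-readable text report.
#'
#' @param table study table (see [simulate_cohort()]): columns `subject_id`,
#'   `breath_id`, `method`, `value`, `units`, `volume_l`.
#' @param ratings optional named list of targets x raters matrices (one per
#'   method) for [icc_oneway()]; NULL omits the agreement section.
#' @param proportions optional data.frame with columns `label`, `k`, `n` for
#'   [clopper_pearson()]; NULL omits the feasibility section.
#' @param out_dir optional directory; when given, writes `summary.csv`,
#'   `correlations.csv`, `split_correlations.csv`, `icc.csv`,
#'   `proportions.csv` (sections present only when computed) and
#'   `report.txt`.
#' @return A `dia_report` list with the computed sections, invisibly when
#'   `out_dir` is given.
#' @export
study_report <- function(table, ratings = NULL, proportions = NULL,
                         out_dir = NULL) {
  stopifnot(is.data.frame(table),
            all(c("method", "value", "units", "volume_l") %in% names(table)))
  methods <- unique(table$method)

  summarize <- function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v),
                             max = max(v), n = length(v))
  summary_df <- do.call(rbind, lapply(methods, function(m) {
    rec <- table[table$method == m, ]
    rbind(
      data.frame(method = m, quantity = "measurement",
                 units = rec$units[1], t(summarize(rec$value))),
      data.frame(method = m, quantity = "expired volume", units = "l",
                 t(summarize(rec$volume_l)))
    )
  }))

  cors <- lapply(methods, function(m) {
    rec <- table[table$method == m, ]
    spearman_ci(rec$value, rec$volume_l)
  })
  names(cors) <- methods
  cor_df <- do.call(rbind, lapply(methods, function(m) {
    cr <- cors[[m]]
    data.frame(method = m, r_s = cr$r_s, ci_low = cr$ci_low,
               ci_high = cr$ci_high, p = cr$p, n = cr$n)
  }))

  splits <- lapply(methods, function(m) split_by_mean(table, m))
  names(splits) <- methods
  split_df <- do.call(rbind, lapply(methods, function(m) {
    sp <- splits[[m]]
    data.frame(method = m, mean_cut_l = sp$mean_cut,
               stratum = c("low", "high"),
               r_s = c(sp$low$r_s, sp$high$r_s),
               ci_low = c(sp$low$ci_low, sp$high$ci_low),
               ci_high = c(sp$low$ci_high, sp$high$ci_high),
               p = c(sp$low$p, sp$high$p),
               n = c(sp$n_low, sp$n_high))
  }))

  icc_df <- NULL
  iccs <- NULL
  if (!is.null(ratings) && length(ratings) > 0) {
    iccs <- lapply(ratings, icc_oneway)
    icc_df <- do.call(rbind, lapply(names(iccs), function(m) {
      ic <- iccs[[m]]
      data.frame(method = m, icc = ic$icc, p = ic$p,
                 n_targets = ic$n_targets, n_raters = ic$n_raters)
    }))
  }

  prop_df <- NULL
  if (!is.null(proportions) && nrow(proportions) > 0) {
    prop_df <- do.call(rbind, lapply(seq_len(nrow(proportions)), function(i) {
      ci <- clopper_pearson(proportions$k[i], proportions$n[i])
      data.frame(label = proportions$label[i], k = ci$k, n = ci$n,
                 point = ci$point, ci_low = ci$ci_low, ci_high = ci$ci_high)
    }))
  }

  rep <- structure(
    list(summary = summary_df, correlations = cor_df, splits = split_df,
         icc = icc_df, proportions = prop_df),
    class = "dia_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    wr(summary_df, "summary.csv")
    wr(cor_df, "correlations.csv")
    wr(split_df, "split_correlations.csv")
    wr(icc_df, "icc.csv")
    wr(prop_df, "proportions.csv")
    txt <- utils::capture.output(print(rep))
    writeLines(txt, file.path(out_dir, "report.txt"))
    return(invisible(rep))
  }
  rep
}

#' @export
print.dia_report <- function(x, ...) {
  fmt_num <- function(v) formatC(v, digits = 2, format = "f")
  cat("== Measurement summary ==\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %-15s %5s: mean %7.1f  sd %6.1f  range %6.1f-%6.1f  n %d\n",
                s$method[i], s$quantity[i], s$units[i], s$mean[i], s$sd[i],
                s$min[i], s$max[i], s$n[i]))
  cat("== Correlation with expired volume (Spearman) ==\n")
  cdf <- x$correlations
  for (i in seq_len(nrow(cdf)))
    cat(sprintf("  %-6s r_s = %s (95%% CI %s-%s), p = %.3g, n = %d\n",
                cdf$method[i], fmt_num(cdf$r_s[i]), fmt_num(cdf$ci_low[i]),
                fmt_num(cdf$ci_high[i]), cdf$p[i], cdf$n[i]))
  cat("== Mean-split subgroup correlations ==\n")
  sp <- x$splits
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-6s %-4s volume (cut %.2f l): r_s = %s (95%% CI %s-%s), p = %.3g, n = %d\n",
                sp$method[i], sp$stratum[i], sp$mean_cut_l[i],
                fmt_num(sp$r_s[i]), fmt_num(sp$ci_low[i]),
                fmt_num(sp$ci_high[i]), sp$p[i], sp$n[i]))
  if (!is.null(x$icc)) {
    cat("== Inter-rater agreement, one-way ICC(1,1) ==\n")
    ic <- x$icc
    for (i in seq_len(nrow(ic)))
      cat(sprintf("  %-6s ICC = %s, p = %.3g (%d targets, %d raters)\n",
                  ic$method[i], fmt_num(ic$icc[i]), ic$p[i],
                  ic$n_targets[i], ic$n_raters[i]))
  }
  if (!is.null(x$proportions)) {
    cat("== Feasibility (exact binomial CIs) ==\n")
    pr <- x$proportions
    for (i in seq_len(nrow(pr)))
      cat(sprintf("  %-28s %d/%d = %3.0f%% (95%% CI %s-%s)\n",
                  pr$label[i], pr$k[i], pr$n[i], 100 * pr$point[i],
                  fmt_num(pr$ci_low[i]), fmt_num(pr$ci_high[i])))
  }
  invisible(x)
}
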