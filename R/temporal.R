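#' Temporal metrics of a hard state path
#'
#' Fractional occupancy, visit lifetimes, and between-visit intervals
#' per state. Lifetimes below `min_lifetime_ms` are dropped from the
#' filtered lists used for statistical comparison (very short visits are
#' unlikely to reflect sustained neural states); raw lists are kept too.
#' Intervals are not filtered.
#'
#' @param state_path integer vector of hard state assignments.
#' @param fs sampling rate, Hz.
#' @param min_lifetime_ms lifetime filter threshold (default 100 ms,
#'   strictly-greater comparison).
#' @param n_states total number of states (defaults to `max(state_path)`);
#'   states never visited get empty entries and zero occupancy.
#' @return object of class `temporal_metrics`: `fractional_occupancy`
#'   (sums to 1), `lifetimes`, `lifetimes_filtered`, `intervals` (ms,
#'   lists per state), `n_visits`.
#' @export
compute_temporal_metrics <- function(state_path, fs, min_lifetime_ms = 100,
                                     n_states = NULL) {
  if (!length(state_path)) stopf("empty state path")
  path <- as.integer(state_path)
  K <- n_states %||% max(path)
  runs <- rle(path)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ms <- 1000 / fs
  fo <- numeric(K)
  lt <- vector("list", K)
  iv <- vector("list", K)
  nv <- integer(K)
  for (k in seq_len(K)) {
    sel <- which(runs$values == k)
    fo[k] <- sum(runs$lengths[sel]) / length(path)
    lt[[k]] <- runs$lengths[sel] * ms
    nv[k] <- length(sel)
    if (length(sel) > 1) {
      iv[[k]] <- (starts[sel[-1]] - ends[sel[-length(sel)]] - 1L) * ms
    } else {
      iv[[k]] <- numeric(0)
    }
  }
  structure(list(
    fractional_occupancy = fo,
    lifetimes = lt,
    lifetimes_filtered = lapply(lt, function(x) x[x > min_lifetime_ms]),
    intervals = iv,
    n_visits = nv,
    fs = fs, min_lifetime_ms = min_lifetime_ms),
    class = "temporal_metrics")
}

#' @export
print.temporal_metrics <- function(x, ...) {
  cat("<temporal_metrics>\n")
  for (k in seq_along(x$fractional_occupancy))
    cat(sprintf("  state %d: FO %.3f, %d visits, mean lifetime %.1f ms\n",
                k, x$fractional_occupancy[k], x$n_visits[k],
                mean(x$lifetimes[[k]])))
  invisible(x)
}

## Long tables from per-condition lists of temporal_metrics.
temporal_tables <- function(metrics_by_condition) {
  fo_rows <- list(); visit_rows <- list()
  for (cond in names(metrics_by_condition)) {
    mets <- metrics_by_condition[[cond]]
    for (s in seq_along(mets)) {
      m <- mets[[s]]
      K <- length(m$fractional_occupancy)
      fo_rows[[length(fo_rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), condition = cond,
        state = factor(seq_len(K), levels = seq_len(K)),
        fo = m$fractional_occupancy)
      for (k in seq_len(K)) {
        lf <- m$lifetimes_filtered[[k]]
        if (length(lf))
          visit_rows[[length(visit_rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), condition = cond,
            state = k, metric = "lifetime", value = lf)
        if (length(m$intervals[[k]]))
          visit_rows[[length(visit_rows) + 1L]] <- data.frame(
            subject = sprintf("S%02d", s), condition = cond,
            state = k, metric = "interval", value = m$intervals[[k]])
      }
    }
  }
  list(fo = do.call(rbind, fo_rows), visits = do.call(rbind, visit_rows))
}

extract_aov_terms <- function(fit) {
  tabs <- summary(fit)
  out <- list()
  collect <- function(df) {
    for (i in seq_len(nrow(df))) {
      term <- trimws(rownames(df)[i])
      if (term == "Residuals") next
      out[[term]] <<- data.frame(
        term = term, df = df$Df[i],
        df_resid = df$Df[nrow(df)],
        F = df$`F value`[i], p = df$`Pr(>F)`[i])
    }
  }
  if (inherits(fit, "aovlist")) {
    for (stratum in tabs) collect(as.data.frame(stratum[[1]]))
  } else {
    collect(as.data.frame(tabs[[1]]))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Factorial comparison of temporal metrics across conditions
#'
#' Fractional occupancy is analysed at the subject level with a two-way
#' repeated-measures ANOVA (state x condition within subject); lifetimes
#' and intervals are analysed at the visit level with a two-way
#' fixed-effects ANOVA on the pooled visits, whose residual degrees of
#' freedom therefore run into the number of visits. Post hoc pairwise
#' state comparisons use Tukey's HSD at the visit level and
#' Bonferroni-corrected paired t-tests for occupancy.
#'
#' @param metrics_a,metrics_b per-condition lists of
#'   [compute_temporal_metrics()] results (same subjects in both for the
#'   repeated-measures analysis).
#' @param conditions names for the two conditions.
#' @return object of class `anova_result`: per metric an ANOVA table
#'   (term, df, F, p) plus post hoc tables and the underlying long
#'   tables.
#' @export
anova_temporal <- function(metrics_a, metrics_b,
                           conditions = c("A", "B")) {
  if (length(metrics_a) < 2 || length(metrics_b) < 2)
    stopf("need at least 2 subjects per condition")
  byc <- stats::setNames(list(metrics_a, metrics_b), conditions)
  tabs <- temporal_tables(byc)
  fo <- tabs$fo
  fo$condition <- factor(fo$condition)
  fo$subject <- factor(fo$subject)
  fo_fit <- aov(fo ~ state * condition +
                  Error(subject / (state * condition)), data = fo)
  fo_tab <- extract_aov_terms(fo_fit)
  fo_post <- tryCatch(
    with(fo, pairwise.t.test(fo, state, paired = TRUE,
                             p.adjust.method = "bonferroni")),
    error = function(e) NULL)   # degenerate (constant) occupancies

  visit_out <- list()
  for (met in c("lifetime", "interval")) {
    vt <- tabs$visits[tabs$visits$metric == met, ]
    present <- table(vt$state)
    empty <- setdiff(unique(tabs$fo$state), names(present))
    if (length(empty))
      warning(sprintf("%s: state(s) %s have no qualifying visits and are excluded",
                      met, paste(empty, collapse = ", ")))
    vt$state <- factor(vt$state)
    vt$condition <- factor(vt$condition)
    fit <- aov(value ~ state * condition, data = vt)
    visit_out[[met]] <- list(
      anova = extract_aov_terms(fit),
      posthoc = TukeyHSD(fit, which = "state"),
      n = nrow(vt))
  }
  structure(list(
    fo = list(anova = fo_tab, posthoc = fo_post),
    lifetime = visit_out$lifetime,
    interval = visit_out$interval,
    tables = tabs, conditions = conditions), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result>\n  fractional occupancy (repeated measures):\n")
  print(x$fo$anova)
  cat(sprintf("  lifetime: visit-level n = %d\n", x$lifetime$n))
  print(x$lifetime$anova)
  cat(sprintf("  interval: visit-level n = %d\n", x$interval$n))
  print(x$interval$anova)
  invisible(x)
}
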