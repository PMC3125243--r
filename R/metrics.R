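#' Mid-parent regression heritability
#'
#' Narrow-sense heritability h2 estimated as the ordinary least-squares slope
#' of offspring phenotype on mid-parent phenotype (the mean of the two
#' parents' trait values). Values outside `[0, 1]` are returned as estimated;
#' they simply indicate sampling noise or non-additive transmission.
#'
#' @param offspring_phenotypes,midparent_phenotypes paired numeric vectors,
#'   at least 3 pairs.
#' @return the slope, or `NA_real_` when the mid-parent variance is
#'   degenerate.
#' @export
midparent_heritability <- function(offspring_phenotypes,
                                   midparent_phenotypes) {
  if (length(offspring_phenotypes) != length(midparent_phenotypes))
    stop("offspring and mid-parent vectors must be paired")
  ok <- is.finite(offspring_phenotypes) & is.finite(midparent_phenotypes)
  if (sum(ok) < 3L) return(NA_real_)
  vm <- stats::var(midparent_phenotypes[ok])
  if (!is.finite(vm) || vm < 1e-12) return(NA_real_)
  stats::cov(midparent_phenotypes[ok], offspring_phenotypes[ok]) / vm
}

#' Coexistence flag of a run
#'
#' `TRUE` exactly when both species are present in the regional community
#' (regional census > 0) at the final scheduled generation; `NA` for
#' single-species runs.
#'
#' @param run a `run_record`.
#' @return logical flag.
#' @export
coexistence <- function(run) {
  stopifnot(inherits(run, "run_record"))
  attr(run, "coexist")
}

#' Persistence time of a run
#'
#' The generation of the first regional species-level extinction, or the
#' scheduled run length (750 by default) if both species persist throughout.
#'
#' @param run a `run_record`.
#' @return generations.
#' @export
persistence_time <- function(run) {
  stopifnot(inherits(run, "run_record"))
  ext <- attr(run, "extinction")[attr(run, "tracked")]
  if (all(is.na(ext)))
    attr(run, "params")$config$generations
  else min(ext, na.rm = TRUE)
}

#' Critical population size (0.9 K threshold)
#'
#' 0.9 times the maximum regional census observed across all supplied runs
#' and generations. The same threshold is applied to every arm being
#' contrasted (metapopulation and metacommunity).
#'
#' @param ... `nc_experiment`s, `run_record`s, and/or numeric regional-census
#'   trajectories.
#' @return the census threshold.
#' @export
critical_population <- function(...) {
  args <- list(...)
  if (!length(args)) stop("at least one run is required")
  maxima <- vapply(args, function(a) {
    if (inherits(a, "nc_experiment"))
      max(vapply(a$regional, max, numeric(1)))
    else if (inherits(a, "run_record")) max(regional_census(a))
    else if (is.numeric(a)) max(a)
    else stop("unsupported input to critical_population()")
  }, numeric(1))
  0.9 * max(maxima)
}

#' Time to reach, and proportion of time above, the 0.9 K threshold
#'
#' `time_to_09k` is the first generation at which the regional census (both
#' species pooled) exceeds the threshold, `NA` if it never does;
#' `prop_above_09k` is the fraction of recorded generations spent above the
#' threshold. Both are computed over the realized run length (runs terminate
#' at the first extinction).
#'
#' @param run a `run_record` or a numeric regional-census trajectory whose
#'   first element is generation 0.
#' @param threshold census threshold from [critical_population()].
#' @return generations (`time_to_09k`) or a fraction in `[0, 1]`
#'   (`prop_above_09k`).
#' @export
time_to_09k <- function(run, threshold) {
  if (threshold <= 0) stop("`threshold` must be positive")
  reg <- if (inherits(run, "run_record")) regional_census(run) else run
  hit <- which(reg > threshold)
  if (!length(hit)) NA_integer_ else as.integer(hit[1L] - 1L)
}

#' @rdname time_to_09k
#' @export
prop_above_09k <- function(run, threshold) {
  if (threshold <= 0) stop("`threshold` must be positive")
  reg <- if (inherits(run, "run_record")) regional_census(run) else run
  mean(reg > threshold)
}

#' Census-weighted trait-environment mismatch
#'
#' The absolute gap between the mean trait value and the resource quality in
#' each patch, weighted by the number of individuals in the patch and
#' averaged over species, patches and post-canalization generations. Empty
#' patches carry zero weight; weights normalize to 1 over the whole run.
#'
#' @param run a `run_record`.
#' @param from first generation included (default: the generation after the
#'   canalization period of the run's configuration).
#' @return the weighted mean mismatch in trait units, `NA` if no occupied
#'   patch-generations fall in range.
#' @export
mismatch <- function(run, from = NULL) {
  stopifnot(inherits(run, "run_record"))
  if (is.null(from))
    from <- attr(run, "params")$config$canalization_gens + 1L
  rows <- run$generation >= from
  if (!any(rows)) return(NA_real_)
  ns <- length(attr(run, "species"))
  total_w <- 0; total <- 0
  for (s in seq_len(ns)) {
    for (p in 1:3) {
      w <- run[rows, sprintf("census_sp%d_p%d", s, p)]
      mp <- run[rows, sprintf("mphen_sp%d_p%d", s, p)]
      q <- run[rows, sprintf("quality_p%d", p)]
      ok <- w > 0 & !is.na(mp)
      total <- total + sum(w[ok] * abs(mp[ok] - q[ok]))
      total_w <- total_w + sum(w[ok])
    }
  }
  if (total_w == 0) NA_real_ else total / total_w
}

#' One-row summary of a run
#'
#' @param run a `run_record`.
#' @return data.frame with coexistence, persistence time, mismatch, maximum
#'   regional census, realized length and per-species extinction generations.
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "run_record"))
  ext <- attr(run, "extinction")
  out <- data.frame(coexist = coexistence(run),
                    persistence = persistence_time(run),
                    mismatch = mismatch(run),
                    max_regional = max(regional_census(run)),
                    generations = max(run$generation))
  for (i in seq_along(ext))
    out[[paste0("extinct_sp", i)]] <- unname(ext[i])
  out
}

#' Add 0.9 K metrics to an experiment summary
#'
#' @param experiment an `nc_experiment`.
#' @param threshold shared census threshold (see [critical_population()]).
#' @return the experiment with `t09k` and `prop09k` columns added to
#'   `$summary`.
#' @export
add_09k_metrics <- function(experiment, threshold) {
  stopifnot(inherits(experiment, "nc_experiment"))
  experiment$summary$t09k <-
    vapply(experiment$regional, time_to_09k, integer(1), threshold = threshold)
  experiment$summary$prop09k <-
    vapply(experiment$regional, prop_above_09k, numeric(1),
           threshold = threshold)
  experiment
}

#' Metacommunity-minus-metapopulation contrasts
#'
#' For each metacommunity run, subtracts the mean of the matched
#' metapopulation runs — matched on landscape arrangement — for the two 0.9 K
#' metrics. Both summaries must already carry `t09k`/`prop09k` columns
#' computed against the shared threshold.
#'
#' @param metacomm_summary,metapop_summary experiment summary data.frames
#'   with `landscape`, `t09k` and `prop09k` columns.
#' @return the metacommunity summary with `d_t09k` and `d_prop09k` columns
#'   (one row per metacommunity run).
#' @export
metapop_contrast <- function(metacomm_summary, metapop_summary) {
  need <- c("landscape", "t09k", "prop09k")
  stopifnot(all(need %in% names(metacomm_summary)),
            all(need %in% names(metapop_summary)))
  if (!all(metacomm_summary$landscape %in% metapop_summary$landscape))
    stop("unmatched landscape arrangement between arms")
  base_t <- tapply(metapop_summary$t09k, metapop_summary$landscape,
                   mean, na.rm = TRUE)
  base_p <- tapply(metapop_summary$prop09k, metapop_summary$landscape,
                   mean, na.rm = TRUE)
  out <- metacomm_summary
  out$d_t09k <- out$t09k - base_t[out$landscape]
  out$d_prop09k <- out$prop09k - base_p[out$landscape]
  out
}

#' Fit the standard summary models
#'
#' Convenience layer over [stats::glm()] and [stats::lm()]: a binomial-logit
#' model of coexistence on competitor dispersal, competitor network size and
#' landscape heterogeneity (with the size-by-heterogeneity interaction), and
#' a linear model of persistence time on competitor dispersal, network size
#' and mutation rate. Reports sequential deviance per term for the logistic
#' model and percent variance explained per term for the linear model.
#'
#' @param summary_table an experiment summary with columns `coexist`,
#'   `persistence`, `comp_d`, `comp_n`, `comp_mu`, `heterogeneity`.
#' @return a list of class `nc_model_report` with elements `coexistence`
#'   (term, df, deviance, p) and `persistence` (term, pct_var, p), plus the
#'   fitted model objects.
#' @export
fit_summary_models <- function(summary_table) {
  need <- c("coexist", "persistence", "comp_d", "comp_n", "comp_mu",
            "heterogeneity")
  miss <- setdiff(need, names(summary_table))
  if (length(miss))
    stop("summary table lacks columns: ", paste(miss, collapse = ", "))
  tab <- summary_table[!is.na(summary_table$coexist), ]
  for (v in c("comp_d", "comp_n", "comp_mu", "heterogeneity"))
    if (length(unique(tab[[v]])) < 2L)
      warning("factor `", v, "` has a single level; its effect is not ",
              "estimable (rank-deficient design)")
  gfit <- stats::glm(coexist ~ comp_d + comp_n + heterogeneity +
                       comp_n:heterogeneity,
                     family = stats::binomial("logit"), data = tab)
  ga <- stats::anova(gfit, test = "Chisq")
  co_tab <- data.frame(term = rownames(ga), df = ga$Df,
                       deviance = ga$Deviance, p = ga$`Pr(>Chi)`,
                       row.names = NULL)
  lfit <- stats::lm(persistence ~ comp_d + comp_n + comp_mu, data = tab)
  la <- stats::anova(lfit)
  pct <- 100 * la$`Sum Sq` / sum(la$`Sum Sq`)
  pe_tab <- data.frame(term = rownames(la), pct_var = pct,
                       p = la$`Pr(>F)`, row.names = NULL)
  structure(list(coexistence = co_tab, persistence = pe_tab,
                 glm_fit = gfit, lm_fit = lfit),
            class = "nc_model_report")
}

#' @export
print.nc_model_report <- function(x, ...) {
  cat("Coexistence (binomial GLM, logit link): sequential deviance\n")
  print(x$coexistence, digits = 3)
  cat("\nPersistence time (linear model): percent variance explained\n")
  print(x$persistence, digits = 3)
  invisible(x)
}
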