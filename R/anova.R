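#' Mixed repeated-measures (split-plot) ANOVA
#'
#' Balanced mixed-model ANOVA with repeated measures: within-subject
#' factors (e.g. area and hemisphere) and one between-subject factor
#' (e.g. sex). The split-plot sums-of-squares decomposition is fitted with
#' [stats::aov()] and the error strata `Error(subject/(within factors))`:
#' the between effect is tested against subject-within-group error, each
#' within effect and its interaction with the between factor against the
#' corresponding effect x subject-within-group error. Partial eta squared
#' is SS_effect / (SS_effect + SS_error-of-stratum). No sphericity
#' correction is applied by default.
#'
#' @param data data frame in long format.
#' @param dv name of the dependent-variable column.
#' @param subject name of the subject id column.
#' @param between name of the between-subject factor column.
#' @param within character vector of within-subject factor columns.
#' @return an object of class `mixed_anova`: tibble with columns `effect`,
#'   `df1`, `df2`, `sumsq`, `sumsq_error`, `statistic` (F), `p_value`,
#'   `partial_eta_sq`, plus a `fit` attribute carrying the aov object.
#' @export
mixed_anova <- function(data, dv, subject = "brain", between = "sex",
                        within = c("area", "hemisphere")) {
  cols <- c(dv, subject, between, within)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[cols])
  for (v in c(subject, between, within)) df[[v]] <- factor(df[[v]])

  # balance: every subject has exactly one row per within-cell, and one
  # between level; equal group sizes
  tab <- table(df[c(subject, within)])
  if (any(tab != 1)) {
    abort("unbalanced design: every subject needs exactly one observation per within-factor cell.")
  }
  grp <- unique(df[c(subject, between)])
  if (any(duplicated(grp[[subject]]))) {
    abort("each subject must have a single between-factor level.")
  }
  if (length(unique(table(grp[[between]]))) != 1L) {
    abort("unbalanced design: between-factor groups must have equal size.")
  }

  fe <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste0("`", dv, "` ~ ", fe, " + ", err))
  fit <- stats::aov(form, data = df)

  sm <- summary(fit)
  out <- purrr::map_dfr(sm, function(stratum) {
    st <- stratum[[1]]
    terms <- trimws(rownames(st))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) return(tibble())
    ss_err <- st[resid_i, "Sum Sq"]
    df_err <- st[resid_i, "Df"]
    eff <- setdiff(seq_len(nrow(st)), resid_i)
    if (!length(eff)) return(tibble())
    tibble(effect = terms[eff],
           df1 = st[eff, "Df"], df2 = df_err,
           sumsq = st[eff, "Sum Sq"], sumsq_error = ss_err,
           statistic = st[eff, "F value"], p_value = st[eff, "Pr(>F)"],
           partial_eta_sq = st[eff, "Sum Sq"] / (st[eff, "Sum Sq"] + ss_err))
  })
  # degenerate strata (e.g. all cells equal): report F = 0, p = 1 rather
  # than the 0/0 form of the raw decomposition
  data_scale <- max(sum(df[[dv]]^2), 1e-300)
  tiny <- out$sumsq <= 1e-16 * data_scale
  out$statistic[tiny] <- 0
  out$p_value[tiny] <- 1
  attr(out, "fit") <- fit
  attr(out, "design") <- list(dv = dv, subject = subject, between = between,
                              within = within,
                              n_subjects = length(unique(df[[subject]])))
  class(out) <- c("mixed_anova", class(out))
  out
}

#' @export
tidy.mixed_anova <- function(x, ...) {
  out <- x
  attr(out, "fit") <- NULL
  attr(out, "design") <- NULL
  class(out) <- setdiff(class(out), "mixed_anova")
  as_tibble(out)
}

#' @export
glance.mixed_anova <- function(x, ...) {
  d <- attr(x, "design")
  tibble(n_subjects = d$n_subjects, dv = d$dv, between = d$between,
         within = paste(d$within, collapse = ":"), n_effects = nrow(x))
}

#' Compare mean GLI values across hemispheres, areas and sexes
#'
#' Applies the mixed repeated-measures ANOVA to per-brain x hemisphere x
#' area mean GLI values (each typically based on 15-20 profiles from three
#' sections), testing for volume-fraction-of-cell-bodies differences.
#'
#' @param records data frame with columns `brain`, `sex`, `hemisphere`,
#'   `area`, `mean_gli` (fractions in \[0, 1\]).
#' @param within within-subject factors (default area and hemisphere).
#' @return a [mixed_anova()] result.
#' @export
compare_gli <- function(records, within = c("area", "hemisphere")) {
  if (!"mean_gli" %in% names(records)) abort("`records` needs a `mean_gli` column.")
  if (any(records$mean_gli < 0 | records$mean_gli > 1)) {
    abort("`mean_gli` values must lie in [0, 1].")
  }
  mixed_anova(records, dv = "mean_gli", subject = "brain", between = "sex",
              within = within)
}
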