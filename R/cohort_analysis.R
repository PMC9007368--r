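# Cohort-level statistics: linear mixed models, fitted by REML, for the
# effect of magnification correction, its interaction with axial length,
# and myope/non-myope contrasts, on paired raw/corrected sector tables.

#' Assemble the long cohort table
#'
#' Joins the tidy per-eye sector table (from [extract_eye()] /
#' [simulate_sector_table()]) with the biometry covariates into the
#' long-format table the mixed models consume: one row per eye x
#' correction state x sector.
#'
#' @param sector_df Data frame with `participant_id`, `eye`, `corrected`,
#'   `sector`, `mean_um`.
#' @param biometry Data frame with `participant_id`, `eye`,
#'   `axial_length_mm`, `sphere_d`, `cylinder_d`, `sex`, `ethnicity`.
#' @return A data frame of class `cohort_table` with columns
#'   `participant_id`, `eye`, `sector`, `corrected`, `thickness_um`,
#'   `axial_length_mm`, `refractive_group`, `sex`, `ethnicity`.
#' @export
make_cohort_table <- function(sector_df, biometry) {
  need <- c("participant_id", "eye", "corrected", "sector", "mean_um")
  stopifnot(all(need %in% names(sector_df)))
  bio <- biometry[, c("participant_id", "eye", "axial_length_mm",
                      "sphere_d", "cylinder_d", "sex", "ethnicity")]
  out <- merge(sector_df[, need], bio, by = c("participant_id", "eye"),
               sort = FALSE)
  names(out)[names(out) == "mean_um"] <- "thickness_um"
  out$refractive_group <- classify_refractive_group(
    spherical_equivalent(out$sphere_d, out$cylinder_d))
  out$sphere_d <- NULL
  out$cylinder_d <- NULL
  out$sector <- factor(as.character(out$sector), levels = ETDRS_SECTORS)
  out$sex <- factor(out$sex)
  out$ethnicity <- factor(out$ethnicity)
  out$corrected <- as.logical(out$corrected)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# covariate terms that actually vary in this subset
.covariate_terms <- function(data) {
  terms <- character(0)
  if (nlevels(droplevels(data$sex)) > 1) terms <- c(terms, "sex")
  if (nlevels(droplevels(data$ethnicity)) > 1) terms <- c(terms, "ethnicity")
  terms
}

# Fit by REML with the fallback ladder: random intercept + slope ->
# random intercept only -> fixed-effects lm with cluster-robust (by
# participant) standard errors. Returns coef row for `term` plus metadata.
.fit_lmm <- function(data, response, fixed_terms, term, slope_term = NULL,
                     max_iter = 200) {
  data <- droplevels(data)
  fx <- paste(c(fixed_terms, .covariate_terms(data)), collapse = " + ")
  res <- NULL
  used <- NULL

  try_fit <- function(re) {
    fml <- stats::as.formula(paste(response, "~", fx, "+", re))
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = data, REML = TRUE,
                     control = lme4::lmerControl(
                       optCtrl = list(maxfun = max_iter * 10),
                       check.conv.singular = "ignore"))))
    fit
  }

  if (!is.null(slope_term)) {
    fit <- tryCatch(try_fit(sprintf("(1 + %s | participant_id)", slope_term)),
                    error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      res <- fit
      used <- "intercept_and_slope"
    }
  }
  if (is.null(res)) {
    fit <- tryCatch(try_fit("(1 | participant_id)"), error = function(e) NULL)
    if (!is.null(fit)) {
      res <- fit
      used <- if (is.null(slope_term)) "intercept" else "intercept_only_fallback"
    }
  }

  if (!is.null(res)) {
    co <- stats::coef(summary(res)) # lmerTest: Satterthwaite df and p
    if (!term %in% rownames(co)) {
      stop("model term '", term, "' not estimable (rank-deficient design)",
           call. = FALSE)
    }
    est <- co[term, "Estimate"]
    se <- co[term, "Std. Error"]
    df <- co[term, "df"]
    p <- co[term, "Pr(>|t|)"]
  } else {
    # last resort: plain least squares with cluster-robust errors
    fml <- stats::as.formula(paste(response, "~", fx))
    fit <- stats::lm(fml, data = data)
    vc <- sandwich::vcovCL(fit, cluster = data$participant_id)
    ct <- lmtest::coeftest(fit, vcov. = vc)
    if (!term %in% rownames(ct)) {
      stop("model term '", term, "' not estimable (rank-deficient design)",
           call. = FALSE)
    }
    est <- ct[term, "Estimate"]
    se <- ct[term, "Std. Error"]
    df <- stats::df.residual(fit)
    p <- ct[term, "Pr(>|t|)"]
    used <- "robust_lm_fallback"
  }

  tq <- stats::qt(0.975, df = max(df, 1))
  list(estimate = unname(est), se = unname(se),
       ci_lo = unname(est - tq * se), ci_hi = unname(est + tq * se),
       df = unname(df), p_value = unname(p), model = used)
}

.effect_row <- function(sector, term_label, fit, data) {
  data.frame(
    sector = sector,
    term = term_label,
    estimate = fit$estimate,
    ci_lo = fit$ci_lo,
    ci_hi = fit$ci_hi,
    p_value = fit$p_value,
    p_adjusted = NA_real_,
    n_eyes = length(unique(paste(data$participant_id, data$eye))),
    n_participants = length(unique(data$participant_id)),
    model = fit$model,
    stringsAsFactors = FALSE
  )
}

.sector_subset <- function(table, sector) {
  stopifnot(sector %in% ETDRS_SECTORS)
  sub <- table[table$sector == sector, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for sector ", sector, call. = FALSE)
  sub
}

#' Main effect of magnification correction in one sector
#'
#' REML linear mixed model of thickness on the correction flag, adjusted
#' for sex and ethnicity, with random intercepts and random
#' correction-slopes for participants (the correction flag is the repeated
#' within-eye factor both eyes share, and the random intercept carries the
#' correlation between a participant's two eyes). The reported coefficient
#' is the mean corrected-minus-raw difference: positive where raw
#' measurements underestimate, negative where they overestimate.
#'
#' Singular or failed fits fall back to a random-intercept-only model and,
#' as a last resort, to fixed-effects least squares with cluster-robust
#' standard errors; the model actually used is recorded in the `model`
#' column.
#'
#' @param table A [make_cohort_table()] result.
#' @param sector One of [ETDRS_SECTORS].
#' @return One-row data frame: `sector`, `term`, `estimate` (um), `ci_lo`,
#'   `ci_hi` (95 percent CI), `p_value`, `p_adjusted` (filled by
#'   [adjust_pvalues()]), `n_eyes`, `n_participants`, `model`.
#' @export
fit_correction_effect <- function(table, sector) {
  sub <- .sector_subset(table, sector)
  stopifnot(length(unique(sub$participant_id)) >= 2,
            length(unique(sub$corrected)) == 2)
  fit <- .fit_lmm(sub, "thickness_um", "corrected", "correctedTRUE",
                  slope_term = "corrected")
  .effect_row(sector, "correction", fit, sub)
}

#' Axial-length-by-correction interaction in one sector
#'
#' Adds axial length and its interaction with the correction flag to the
#' correction model. The interaction coefficient is the change in
#' (corrected - raw) per mm of axial length; its negative is the per-mm
#' over-estimation of the sector by raw measurements. The simple slopes of
#' axial length on the raw and corrected data (fitted separately per
#' correction state, with random participant intercepts) are returned as
#' additional rows.
#'
#' @inheritParams fit_correction_effect
#' @return Three-row data frame with terms `al_x_correction`,
#'   `al_slope_raw`, `al_slope_corrected` (um per mm of axial length).
#' @export
fit_al_interaction <- function(table, sector) {
  sub <- .sector_subset(table, sector)
  if (stats::var(sub$axial_length_mm) <= 0) {
    stop("fit_al_interaction: axial length has no variance", call. = FALSE)
  }
  sub$al_c <- sub$axial_length_mm - mean(sub$axial_length_mm)
  inter <- .fit_lmm(sub, "thickness_um", "corrected * al_c",
                    "correctedTRUE:al_c", slope_term = "corrected")
  rows <- .effect_row(sector, "al_x_correction", inter, sub)
  rbind(rows,
        fit_al_slope(table, sector, state = FALSE),
        fit_al_slope(table, sector, state = TRUE))
}

#' Simple slope of axial length on thickness, per correction state
#'
#' The association of thickness with axial length within one correction
#' state (the raw and corrected columns of the axial-length effect table):
#' thickness on centred axial length + sex + ethnicity with random
#' participant intercepts, REML.
#'
#' @inheritParams fit_correction_effect
#' @param state `FALSE` for the raw data, `TRUE` for the corrected data.
#' @return One-row data frame with term `al_slope_raw` or
#'   `al_slope_corrected` (um per mm of axial length).
#' @export
fit_al_slope <- function(table, sector, state = TRUE) {
  sub <- .sector_subset(table, sector)
  ss <- sub[sub$corrected == state, , drop = FALSE]
  if (stats::var(ss$axial_length_mm) <= 0) {
    stop("fit_al_slope: axial length has no variance", call. = FALSE)
  }
  ss$al_c <- ss$axial_length_mm - mean(ss$axial_length_mm)
  sl <- .fit_lmm(ss, "thickness_um", "al_c", "al_c", slope_term = NULL)
  .effect_row(sector, if (state) "al_slope_corrected" else "al_slope_raw",
              sl, ss)
}

#' Myope vs non-myope contrast in one sector
#'
#' Separate REML mixed models per correction state, with refractive group
#' in place of axial length: thickness on group + sex + ethnicity with
#' random participant intercepts. The coefficient is the myope minus
#' non-myope difference (um).
#'
#' @inheritParams fit_correction_effect
#' @param states Which correction states to fit.
#' @return Data frame with terms `group_raw` and/or `group_corrected`.
#' @export
fit_group_contrast <- function(table, sector, states = c(FALSE, TRUE)) {
  sub <- .sector_subset(table, sector)
  rows <- NULL
  for (state in states) {
    ss <- sub[sub$corrected == state, , drop = FALSE]
    if (nlevels(droplevels(ss$refractive_group)) < 2) {
      stop("fit_group_contrast: both refractive groups must be present",
           call. = FALSE)
    }
    fit <- .fit_lmm(ss, "thickness_um", "refractive_group",
                    "refractive_groupmyope", slope_term = NULL)
    rows <- rbind(rows, .effect_row(
      sector, if (state) "group_corrected" else "group_raw", fit, ss))
  }
  rows
}

#' Bonferroni adjustment within term families
#'
#' Adjusts p-values across the sectors of each term family:
#' `p_adjusted = min(1, m * p)` where `m` is the family size (9 when all
#' sectors are present).
#'
#' @param estimates Data frame of effect rows (with `term` and `p_value`).
#' @return The same data frame with `p_adjusted` filled in.
#' @export
adjust_pvalues <- function(estimates) {
  stopifnot(nrow(estimates) > 0, all(c("term", "p_value") %in% names(estimates)))
  for (fam in unique(estimates$term)) {
    i <- estimates$term == fam
    estimates$p_adjusted[i] <- stats::p.adjust(estimates$p_value[i],
                                               method = "bonferroni")
  }
  estimates
}

#' Fit all effect families across the nine sectors
#'
#' Runs [fit_correction_effect()], [fit_al_interaction()] and
#' [fit_group_contrast()] for every sector and Bonferroni-adjusts each term
#' family across sectors.
#'
#' @inheritParams fit_correction_effect
#' @param families Any of `"correction"`, `"al"`, `"group"`.
#' @param sectors Sectors to analyse.
#' @return Combined effect table (see [fit_correction_effect()]).
#' @export
analyze_cohort <- function(table, families = c("correction", "al", "group"),
                           sectors = ETDRS_SECTORS) {
  families <- match.arg(families, several.ok = TRUE)
  if ("group" %in% families &&
      nlevels(droplevels(table$refractive_group)) < 2) {
    warning("analyze_cohort: only one refractive group present; ",
            "skipping the group-contrast family", call. = FALSE)
    families <- setdiff(families, "group")
  }
  rows <- list()
  for (s in sectors) {
    if ("correction" %in% families) {
      rows[[length(rows) + 1]] <- fit_correction_effect(table, s)
    }
    if ("al" %in% families) {
      rows[[length(rows) + 1]] <- fit_al_interaction(table, s)
    }
    if ("group" %in% families) {
      rows[[length(rows) + 1]] <- fit_group_contrast(table, s)
    }
  }
  if (length(rows) == 0) {
    stop("analyze_cohort: no effect family could be fitted", call. = FALSE)
  }
  adjust_pvalues(do.call(rbind, rows))
}
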