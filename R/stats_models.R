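## Linear mixed-effects models of epoch peak range, post-hoc contrasts,
## and multiple-testing helpers.
##
## The model registry mirrors the study design: a full model with a
## locomotor-state x species interaction and nested random intercepts,
## per-species refits after a significant interaction, drug x state models
## for the atropine experiment, and trial-epoch models with Run as the
## reference level.

#' Mixed-model formula registry
#'
#' @param eq one of `"eq1"` ... `"eq9"`
#' @return list: `formula`, `subset` (named filter value or NULL),
#'   `subset_var`
#' @export
lmm_formula <- function(eq) {
  reg <- list(
    eq1 = list(f = PeakRange ~ MovFlag * Species + Chan +
                 (1 | Species / ID / Session), var = NULL, val = NULL),
    eq2 = list(f = PeakRange ~ MovFlag + Chan + (1 | ID / Session),
               var = "Species", val = "rat"),
    eq3 = list(f = PeakRange ~ MovFlag + Chan + (1 | ID / Session),
               var = "Species", val = "ferret"),
    eq4 = list(f = PeakRange ~ MovFlag * DrugFlag +
                 (1 | ID / Chan / Session), var = NULL, val = NULL),
    eq5 = list(f = PeakRange ~ DrugFlag + (1 | ID / Chan / Session),
               var = "MovFlag", val = "moving"),
    eq6 = list(f = PeakRange ~ DrugFlag + (1 | ID / Chan / Session),
               var = "MovFlag", val = "immobile"),
    eq7 = list(f = PeakRange ~ Epoch * Chan + (1 | ID / Session),
               var = NULL, val = NULL),
    eq8 = list(f = PeakRange ~ Epoch + (1 | ID / Session),
               var = "Chan", val = "SO"),
    eq9 = list(f = PeakRange ~ Epoch + (1 | ID / Session),
               var = "Chan", val = "SRSLM")
  )
  if (!eq %in% names(reg)) stop("unknown model id: ", eq, call. = FALSE)
  r <- reg[[eq]]
  list(formula = r$f, subset_var = r$var, subset = r$val)
}

## reference levels recorded in every output
REFERENCE_LEVELS <- c(MovFlag = "immobile", DrugFlag = "none",
                      Species = "rat", Epoch = "Run")

set_references <- function(table) {
  for (v in names(REFERENCE_LEVELS)) {
    if (v %in% names(table)) {
      lv <- REFERENCE_LEVELS[[v]]
      x <- as.factor(table[[v]])
      if (lv %in% levels(x)) x <- stats::relevel(x, ref = lv)
      table[[v]] <- x
    }
  }
  table
}

#' Fit a nested random-intercept mixed model of peak range
#'
#' Restricted-maximum-likelihood fit via `lmerTest::lmer` with
#' Satterthwaite degrees of freedom for fixed-effect p-values (Wald z
#' available as an option; the method is always recorded). Reference
#' levels are Run for Epoch, immobile for MovFlag, none for DrugFlag and
#' rat for Species. Grouping factors with a single level are refused;
#' non-convergence is flagged, never silently simplified.
#'
#' @param table epoch-level data frame containing the model variables
#' @param model a registry id (`"eq1"`...`"eq9"`) or a formula
#' @param df_method `"satterthwaite"` or `"wald"`
#' @return object of class `tq_lmm`: list with `coefficients` (data frame
#'   beta/SE/t/p per fixed effect), `ranef_var` (named variances),
#'   `n_obs`, `converged`, `df_method`, `reference_levels`, `model` (the
#'   fitted lmerMod)
#' @export
fit_lmm <- function(table, model = "eq1",
                    df_method = c("satterthwaite", "wald")) {
  df_method <- match.arg(df_method)
  if (is.character(model)) {
    reg <- lmm_formula(model)
    if (!is.null(reg$subset_var))
      table <- table[table[[reg$subset_var]] == reg$subset, , drop = FALSE]
    formula <- reg$formula
  } else formula <- model
  vars <- all.vars(formula)
  missing <- setdiff(vars, names(table))
  if (length(missing))
    stop("table lacks model variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  table <- set_references(droplevels(as.data.frame(table)))
  bars <- lme4::findbars(formula)
  gvars <- unique(unlist(lapply(bars, function(b) all.vars(b[[3]]))))
  for (g in gvars) {
    if (length(unique(table[[g]])) < 2)
      stop("grouping factor '", g, "' has a single level; ",
           "the nested model is unidentifiable", call. = FALSE)
  }
  fit <- suppressMessages(lmerTest::lmer(formula, data = table, REML = TRUE))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  if (df_method == "satterthwaite") {
    cf <- as.data.frame(stats::coef(summary(fit)))
    names(cf) <- c("beta", "se", "df", "t", "p")
  } else {
    cf <- as.data.frame(stats::coef(summary(fit, ddf = "lme4")))
    names(cf) <- c("beta", "se", "t")
    cf$df <- NA_real_
    cf$p <- 2 * stats::pnorm(-abs(cf$t))
    cf <- cf[, c("beta", "se", "df", "t", "p")]
  }
  cf$term <- rownames(cf)
  rownames(cf) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- stats::setNames(vc$vcov, vc$grp)
  structure(list(coefficients = cf[, c("term", "beta", "se", "df", "t", "p")],
                 ranef_var = rv, n_obs = stats::nobs(fit),
                 converged = conv, df_method = df_method,
                 reference_levels = REFERENCE_LEVELS, model = fit),
            class = "tq_lmm")
}

#' @export
print.tq_lmm <- function(x, ...) {
  cat(sprintf("tq_lmm (%s df, n = %d, converged = %s)\n", x$df_method,
              x$n_obs, x$converged))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Interaction-then-split model protocol
#'
#' Fits the full interaction model; when the interaction is significant
#' at `alpha` the data are split on `split_var` and the reduced model is
#' refitted per stratum, giving single-factor coefficients per stratum.
#' Both stages are returned.
#'
#' @param table epoch-level data frame
#' @param full_model,split_models registry ids (e.g. `"eq1"` then
#'   `c("eq2", "eq3")`)
#' @param interaction_term coefficient name to test (defaults to the
#'   first term containing `:`)
#' @param alpha significance threshold for splitting
#' @return list: `full` (tq_lmm), `interaction_p`, `split` (named list of
#'   tq_lmm or NULL when not significant)
#' @export
lmm_split_protocol <- function(table, full_model = "eq1",
                               split_models = c("eq2", "eq3"),
                               interaction_term = NULL, alpha = 0.05) {
  full <- fit_lmm(table, full_model)
  cf <- full$coefficients
  if (is.null(interaction_term))
    interaction_term <- cf$term[grepl(":", cf$term)][1]
  p_int <- cf$p[cf$term == interaction_term]
  split <- NULL
  if (length(p_int) == 1 && is.finite(p_int) && p_int < alpha) {
    split <- lapply(split_models, function(m) fit_lmm(table, m))
    names(split) <- vapply(split_models,
                           function(m) lmm_formula(m)$subset, character(1))
  }
  list(full = full, interaction_p = p_int, split = split)
}

#' Tukey-adjusted pairwise contrasts for a model factor
#'
#' All pairwise estimated-marginal-mean contrasts via emmeans with Tukey
#' adjustment. For a 2-level factor the model coefficient already is the
#' single contrast; it is passed through with a note.
#'
#' @param fit a `tq_lmm`
#' @param factor factor name (e.g. `"Epoch"`)
#' @return data frame of contrasts (`contrast`, `estimate`, `se`, `p_adj`)
#'   with attribute `note` for the 2-level passthrough
#' @export
tukey_contrasts <- function(fit, factor) {
  stopifnot(inherits(fit, "tq_lmm"))
  em <- emmeans::emmeans(fit$model, stats::as.formula(paste0("~", factor)))
  nlev <- nrow(summary(em))
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  out <- data.frame(contrast = as.character(pr$contrast),
                    estimate = pr$estimate, se = pr$SE,
                    p_adj = pr$p.value)
  if (nlev == 2)
    attr(out, "note") <- "2-level factor: model p passed through (no Tukey)"
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests number of tests in the family (>= 1)
#' @param family_alpha family-wise error rate
#' @return corrected per-test alpha (`family_alpha / n_tests`)
#' @examples
#' bonferroni_alpha(32)   # 0.0015625, reported rounded as 0.0016
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  family_alpha / n_tests
}
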