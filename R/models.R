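#' Equal-count rank bins
#'
#' Bins a continuous predictor into `k` equal-count bins (quintiles by
#' default) by rank, with ties broken by stable (first-occurrence) order.
#' This is the binning used for post-hoc comparisons on continuous
#' within-subject predictors.
#'
#' @param x Numeric vector.
#' @param k Number of bins (5 = quintiles; 4 and 3 give quartiles /
#'   tertiles).
#' @return An integer vector of bin indices in 1..k.
#' @examples
#' table(quantile_bins(1:100, 5)) # 20 per bin, boundaries after rank 20, 40, ...
#' @export
quantile_bins <- function(x, k = 5) {
  ok <- is.finite(x)
  if (sum(ok) < k || length(unique(x[ok])) < k) {
    warning("fewer than ", k, " distinct values; bins degenerate")
  }
  out <- rep(NA_integer_, length(x))
  r <- rank(x[ok], ties.method = "first")
  out[ok] <- as.integer(ceiling(k * r / sum(ok)))
  out
}

#' Center and discretize predictors for mixed-model designs
#'
#' Continuous between-subject predictors are centered on the grand mean;
#' continuous within-subject predictors on the subject mean. Each
#' continuous within-subject predictor additionally gets an equal-count
#' bin column for quintile (or quartile/tertile) post-hocs. Centered
#' columns are suffixed `_c`, bin columns `_q`.
#'
#' @param data Trial-level data frame.
#' @param within,between Character vectors of predictor column names.
#' @param subject Name of the subject identifier column.
#' @param n_bins Number of post-hoc bins for continuous within
#'   predictors.
#' @return `data` with `_c` and `_q` columns appended.
#' @export
prepare_predictors <- function(data, within = character(),
                               between = character(),
                               subject = "subject", n_bins = 5) {
  for (v in between) {
    if (!is.numeric(data[[v]])) next
    if (stats::sd(data[[v]], na.rm = TRUE) == 0) {
      warning("between-subject predictor '", v, "' has zero variance")
    }
    data[[paste0(v, "_c")]] <- data[[v]] - mean(data[[v]], na.rm = TRUE)
  }
  for (v in within) {
    if (!is.numeric(data[[v]])) next
    mu <- stats::ave(data[[v]], data[[subject]],
                     FUN = function(x) mean(x, na.rm = TRUE))
    data[[paste0(v, "_c")]] <- data[[v]] - mu
    data[[paste0(v, "_q")]] <- factor(quantile_bins(data[[v]], n_bins))
  }
  data
}

#' Declarative mixed-model designs
#'
#' Returns the predictor layout of one of the study's fourteen mixed
#' linear models. Models 1a-1c relate performance to subtask, path
#' distance and genotype; 2a-2d to spatial-cue distances (2c/2d use the
#' movement-to-cue distance as criterion); 3-5 add regional gray-matter
#' volume (EC, HC, PC/RSC); model 6 is the exploratory model combining
#' task predictors with fMRI-based representation scores (its predictor
#' set is selected by [model6_buildup()]).
#'
#' @param model_id One of `"1a"`, `"1b"`, `"1c"`, `"2a"`, `"2b"`, `"2c"`,
#'   `"2d"`, `"3a"`, `"3b"`, `"4a"`, `"4b"`, `"5a"`, `"5b"`, `"6"`.
#' @return An object of class `model_spec`: list with `model_id`,
#'   `criterion`, `within`, `between`, `covariates`, `random`,
#'   `interactions` (character vector of `:`-separated term labels).
#' @examples
#' build_model_spec("1b")
#' @export
build_model_spec <- function(model_id) {
  ms <- function(criterion, within = character(), between = character(),
                 covariates = character(), random = c("subject", "site"),
                 interactions = character()) {
    structure(list(model_id = model_id, criterion = criterion,
                   within = within, between = between,
                   covariates = covariates, random = random,
                   interactions = interactions),
              class = "model_spec")
  }
  dist_model <- function(dist) {
    ms("performance", c("subtask", dist), "apoe", c("age", "sex"),
       interactions = c(paste0("subtask:", dist), "apoe:subtask",
                        paste0("apoe:", dist)))
  }
  vol_model <- function(dist, vol) {
    ms("performance", c("subtask", dist), c("apoe", vol), c("age", "sex"),
       random = "subject",
       interactions = c(paste0("subtask:", dist), "apoe:subtask",
                        paste0("apoe:", dist),
                        paste0(vol, ":subtask"), paste0(vol, ":", dist),
                        paste0(vol, ":apoe"),
                        paste0(vol, ":apoe:", dist)))
  }
  switch(
    model_id,
    "1a" = dist_model("outgoing_distance"),
    "1b" = dist_model("incoming_distance"),
    "1c" = ms("performance",
              c("subtask", "path_distance", "distance_type"), "apoe",
              c("age", "sex"),
              interactions = c("subtask:path_distance", "apoe:subtask",
                               "apoe:path_distance", "apoe:distance_type",
                               "path_distance:distance_type",
                               "apoe:path_distance:distance_type")),
    "2a" = ms("performance", "goal_to_boundary", "apoe",
              interactions = "apoe:goal_to_boundary"),
    "2b" = ms("performance", "goal_to_landmark", "apoe",
              interactions = "apoe:goal_to_landmark"),
    "2c" = ms("mean_move_to_boundary", between = "apoe"),
    "2d" = ms("mean_move_to_landmark", between = "apoe"),
    "3a" = vol_model("outgoing_distance", "ec_volume"),
    "3b" = vol_model("incoming_distance", "ec_volume"),
    "4a" = vol_model("outgoing_distance", "hc_volume"),
    "4b" = vol_model("incoming_distance", "hc_volume"),
    "5a" = vol_model("outgoing_distance", "pcrsc_volume"),
    "5b" = vol_model("incoming_distance", "pcrsc_volume"),
    "6" = ms("performance", c("subtask", "incoming_distance"),
             c("ec_ip_incoming", "hc_gp_incoming", "pmec_glr",
               "pcrsc_landmark"),
             random = "subject",
             interactions = c(
               "subtask:incoming_distance",
               as.vector(outer(c("ec_ip_incoming", "hc_gp_incoming",
                                 "pmec_glr", "pcrsc_landmark"),
                               c("subtask", "incoming_distance"),
                               paste, sep = ":")))),
    stop("unknown model id: ", model_id)
  )
}

# Is a variable constant within every subject (between-subject level)?
is_between_var <- function(data, v, subject) {
  if (!v %in% names(data)) return(TRUE)
  all(stats::ave(as.numeric(as.factor(data[[v]])), data[[subject]],
                 FUN = function(x) length(unique(x))) == 1)
}

#' Fit a mixed linear model and test fixed terms with type-II tests
#'
#' Builds the model formula from a [build_model_spec()] layout (random
#' intercepts for the listed random factors), centers continuous
#' predictors (grand mean for between-subject, subject mean for
#' within-subject), fits by REML via \pkg{lme4}, and tests every fixed
#' term with type-II Wald chi-square statistics (via
#' [car::Anova()]), converted to F statistics using a
#' containment-style approximation of the denominator degrees of freedom
#' (between-subject terms are tested against subjects, within-subject
#' terms against within-subject observations). When no usable random
#' structure exists (no random columns, or a single observation per
#' group) the model falls back to ordinary least squares with exact
#' type-II F tests.
#'
#' @param spec A `model_spec`.
#' @param data Trial-level data frame containing all spec variables.
#' @param center Center continuous predictors before fitting?
#' @param n_bins Bins added for continuous within-subject predictors
#'   (post-hoc machinery).
#' @return An object of class `pi_fit`: list with `fit` (the merMod or lm
#'   object), `anova` (data frame: `term`, `df1`, `df2`, `statistic`,
#'   `p_value`), `spec`, `data` (the prepared model frame), `backend`,
#'   and `singular` flag.
#' @export
fit_lmm <- function(spec, data, center = TRUE, n_bins = 5) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$criterion, spec$within, spec$between, spec$covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing variables: ", paste(miss, collapse = ", "))
  subject <- spec$random[1] %||% "subject"
  if (!subject %in% names(data)) subject <- "subject"

  if (center && subject %in% names(data)) {
    data <- prepare_predictors(data, spec$within,
                               c(spec$between, spec$covariates),
                               subject = subject, n_bins = n_bins)
    # model on centered values under the original names
    for (v in c(spec$within, spec$between, spec$covariates)) {
      cc <- paste0(v, "_c")
      if (cc %in% names(data)) data[[v]] <- data[[cc]]
    }
  }

  fixed <- c(spec$within, spec$between, spec$covariates, spec$interactions)
  rand <- spec$random[vapply(spec$random, function(r) {
    r %in% names(data) && length(unique(data[[r]])) >= 2
  }, logical(1))]
  # a grouping factor with one observation per level carries no
  # information beyond the residual: drop it
  rand <- rand[vapply(rand, function(r) {
    any(table(data[[r]]) > 1)
  }, logical(1))]

  f_fixed <- paste(spec$criterion, "~", paste(fixed, collapse = " + "))
  singular <- FALSE
  if (length(rand) == 0L) {
    fit <- stats::lm(stats::as.formula(f_fixed), data = data)
    an <- car::Anova(fit, type = 2)
    keep <- rownames(an) != "Residuals"
    tab <- data.frame(
      term = rownames(an)[keep],
      df1 = an$Df[keep],
      df2 = an$Df[rownames(an) == "Residuals"],
      statistic = an$`F value`[keep],
      p_value = an$`Pr(>F)`[keep]
    )
    backend <- "lm"
  } else {
    f <- paste(f_fixed,
               paste(sprintf("(1 | %s)", rand), collapse = " + "),
               sep = " + ")
    fit <- tryCatch(
      lme4::lmer(stats::as.formula(f), data = data, REML = TRUE,
                 control = lme4::lmerControl(
                   check.conv.singular = lme4::.makeCC(
                     action = "ignore", tol = 1e-4),
                   # predictors keep their task units (vm vs. binary), so
                   # the scale heuristic would fire on every fit
                   check.scaleX = "ignore")),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      # singular / unidentifiable random structure: drop random terms
      warning("mixed fit failed (", conditionMessage(fit),
              "); falling back to fixed-effects model")
      return(fit_lmm(`class<-`(modifyList(unclass(spec),
                                          list(random = character())),
                               "model_spec"),
                     data, center = FALSE, n_bins = n_bins))
    }
    singular <- lme4::isSingular(fit, tol = 1e-4)
    an <- car::Anova(fit, type = 2)
    terms_lab <- rownames(an)
    # containment-style denominator df
    n_obs <- nrow(stats::model.frame(fit))
    n_subj <- length(unique(data[[subject]]))
    term_vars <- strsplit(terms_lab, ":", fixed = TRUE)
    between_term <- vapply(term_vars, function(tv) {
      all(vapply(tv, is_between_var, logical(1),
                 data = data, subject = subject))
    }, logical(1))
    q_b <- sum(an$Df[between_term])
    q_w <- sum(an$Df[!between_term])
    df2 <- ifelse(between_term,
                  max(1, n_subj - q_b - 1),
                  max(1, n_obs - n_subj - q_w))
    f_stat <- an$Chisq / an$Df
    tab <- data.frame(
      term = terms_lab,
      df1 = an$Df,
      df2 = df2,
      statistic = f_stat,
      p_value = stats::pf(f_stat, an$Df, df2, lower.tail = FALSE)
    )
    backend <- "lmer"
  }
  rownames(tab) <- NULL
  structure(list(fit = fit, anova = tab, spec = spec, data = data,
                 backend = backend, singular = singular),
            class = "pi_fit")
}

#' @export
print.pi_fit <- function(x, ...) {
  cat("Mixed-model fit (", x$backend, "), model ",
      x$spec$model_id %||% "?", "\n", sep = "")
  cat("Type-II tests of fixed terms:\n")
  print(format(x$anova, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Tukey adjustment for a family of pairwise contrasts
#'
#' Adjusts p values using the studentized-range distribution, the
#' correction applied to post-hoc families (subtask pairs, or per-level
#' tests on distance quintiles, where the family size is the number of
#' compared levels). Raw two-sided p values are converted back to |t|
#' quantiles, then referred to the studentized range for `n_means`
#' means. A family of one returns the raw p.
#'
#' This uses the classical studentized-range bound rather than the exact
#' multivariate-t integration of the marginal-means machinery, so values
#' agree with the latter for balanced pairwise families and are slightly
#' conservative otherwise.
#'
#' @param p Raw two-sided p values (alternative to `t`).
#' @param t t ratios of the contrasts (alternative to `p`).
#' @param df Error degrees of freedom.
#' @param n_means Number of means in the family (family of
#'   `choose(n_means, 2)` pairwise contrasts).
#' @return Adjusted p values (never smaller than the raw ones).
#' @export
tukey_adjust <- function(p = NULL, t = NULL, df = Inf, n_means) {
  stopifnot(n_means >= 1)
  if (is.null(t)) {
    stopifnot(!is.null(p))
    t <- stats::qt(1 - p / 2, df)
  }
  if (is.null(p)) p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  if (n_means < 2) return(p)
  adj <- stats::ptukey(sqrt(2) * abs(t), nmeans = n_means, df = df,
                       lower.tail = FALSE)
  pmax(adj, p)
}

#' Tukey-adjusted pairwise post-hoc contrasts
#'
#' Thin wrapper over the estimated-marginal-means machinery: computes
#' marginal means for `specs` (optionally within levels of `by`) and the
#' Tukey-adjusted pairwise contrasts, the post-hoc pattern used
#' throughout the behavioral models (e.g. risk vs. control within each
#' subtask).
#'
#' @param fitres A `pi_fit` from [fit_lmm()].
#' @param specs Character name of the factor to compare.
#' @param by Optional conditioning factor name.
#' @return A data frame of contrasts with Tukey-adjusted p values.
#' @export
posthoc_pairwise <- function(fitres, specs, by = NULL) {
  stopifnot(inherits(fitres, "pi_fit"))
  emm <- emmeans::emmeans(fitres$fit, specs = specs, by = by,
                          data = fitres$data,
                          lmer.df = "asymptotic")
  as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                  adjust = "tukey"))
}

# p value of every fixed term involving variable v (from a pi_fit table)
terms_involving <- function(tab, v) {
  hit <- vapply(strsplit(tab$term, ":", fixed = TRUE),
                function(tv) v %in% tv, logical(1))
  tab[hit, , drop = FALSE]
}

#' Exploratory model buildup with collinearity and significance screening
#'
#' Reproduces the three-stage construction of the exploratory
#' ("mechanistic") performance model:
#' 1. Collinearity pruning: candidate predictors are walked in the given
#'    priority order; a candidate significantly correlated (at
#'    `alpha_collinear`, subject level) with an already-kept candidate is
#'    dropped.
#' 2. Screening: each surviving candidate's main effect is added to the
#'    base model; the candidate survives if it is significant at
#'    `alpha_screen` (interactions are only built for survivors).
#' 3. Backward elimination: from the joint model, the highest-order
#'    nonsignificant term (at `alpha_elim`) is removed, the model refit,
#'    and so on; main effects are only removable once none of their
#'    interactions remain. Candidate predictors may interact with the
#'    base predictors (subtask, incoming distance) but never with each
#'    other. The base within-subject main effects are always retained.
#'
#' @param data Trial-level data frame (long format, one row per trial).
#' @param candidates Character vector of between-subject predictor
#'   columns, in priority order.
#' @param criterion Criterion column (default `"performance"`).
#' @param base_within Base within-subject predictors.
#' @param random Random intercept factors.
#' @param covariates Optional covariates.
#' @param alpha_collinear,alpha_screen,alpha_elim Stage thresholds.
#' @param method Correlation type for stage 1 (`"pearson"` or
#'   `"spearman"`).
#' @return A list with `kept` (final predictors), `dropped_collinear`,
#'   `dropped_screen`, `final_terms`, and `fit` (`pi_fit` of the final
#'   model; the base model when no candidate survives).
#' @export
model6_buildup <- function(data, candidates,
                           criterion = "performance",
                           base_within = c("subtask", "incoming_distance"),
                           random = "subject",
                           covariates = character(),
                           alpha_collinear = 0.05,
                           alpha_screen = 0.1,
                           alpha_elim = 0.05,
                           method = "pearson") {
  subject <- random[1]
  subj_vals <- function(v) {
    tapply(data[[v]], data[[subject]], function(x) x[1])
  }

  kept <- character()
  dropped_collinear <- character()
  for (v in candidates) {
    clash <- FALSE
    for (k in kept) {
      ct <- stats::cor.test(subj_vals(v), subj_vals(k), method = method,
                            exact = FALSE)
      if (ct$p.value < alpha_collinear) { clash <- TRUE; break }
    }
    if (clash) dropped_collinear <- c(dropped_collinear, v)
    else kept <- c(kept, v)
  }

  base_inter <- if (length(base_within) >= 2) {
    paste(base_within, collapse = ":")
  } else {
    character()
  }
  cand_inter <- function(v) paste(v, base_within, sep = ":")

  spec_for <- function(betweens, interactions) {
    structure(list(model_id = "6", criterion = criterion,
                   within = base_within, between = betweens,
                   covariates = covariates, random = random,
                   interactions = interactions),
              class = "model_spec")
  }

  dropped_screen <- character()
  survivors <- character()
  for (v in kept) {
    f <- fit_lmm(spec_for(v, base_inter), data)
    if (f$anova$p_value[f$anova$term == v] < alpha_screen) {
      survivors <- c(survivors, v)
    } else {
      dropped_screen <- c(dropped_screen, v)
    }
  }

  if (length(survivors) == 0L) {
    fit <- fit_lmm(spec_for(character(), base_inter), data)
    return(list(kept = character(), dropped_collinear = dropped_collinear,
                dropped_screen = dropped_screen,
                final_terms = c(base_within, base_inter), fit = fit))
  }

  interactions <- c(base_inter,
                    unlist(lapply(survivors, cand_inter), use.names = FALSE))
  betweens <- survivors
  repeat {
    fit <- fit_lmm(spec_for(betweens, interactions), data)
    tab <- fit$anova
    ord <- vapply(strsplit(tab$term, ":", fixed = TRUE), length, integer(1))
    # removable: interactions, or main effects of candidates with no
    # remaining interactions; base within-subject main effects stay
    removable <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      tv <- strsplit(tab$term[i], ":", fixed = TRUE)[[1]]
      if (ord[i] > 1) {
        removable[i] <- TRUE
      } else if (tv %in% betweens) {
        in_higher <- any(vapply(strsplit(tab$term[ord > 1], ":", fixed = TRUE),
                                function(h) tv %in% h, logical(1)))
        removable[i] <- !in_higher
      }
    }
    cand_rm <- which(removable & tab$p_value >= alpha_elim)
    if (length(cand_rm) == 0L) break
    # highest order first, then largest p
    cand_rm <- cand_rm[order(-ord[cand_rm], -tab$p_value[cand_rm])]
    rm_term <- tab$term[cand_rm[1]]
    if (rm_term %in% interactions) {
      interactions <- setdiff(interactions, rm_term)
    } else {
      # term label may have reordered components
      match_i <- vapply(strsplit(interactions, ":", fixed = TRUE),
                        function(tv) setequal(tv, strsplit(rm_term, ":",
                                                           fixed = TRUE)[[1]]),
                        logical(1))
      if (any(match_i)) {
        interactions <- interactions[!match_i]
      } else {
        betweens <- setdiff(betweens, rm_term)
      }
    }
    if (length(betweens) == 0L && length(interactions) <= length(base_inter)) {
      break
    }
  }
  fit <- fit_lmm(spec_for(betweens, interactions), data)
  list(kept = betweens, dropped_collinear = dropped_collinear,
       dropped_screen = dropped_screen,
       final_terms = c(base_within, betweens, interactions),
       fit = fit)
}
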