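#' @title Habitat and latitude models for network metrics
#' @name glm_stage
#' @description
#' Per-network metrics are modelled with Gaussian-error GLMs:
#' `metric ~ habitat + abs_latitude + S + log_m + family (+ interactions)`,
#' where S is species richness (rows + columns) and log_m the natural log
#' of matrix size, both included to control for network-size effects. Term
#' significance is assessed by comparing nested models for their change in
#' deviance on a chi-square distribution; habitat contrasts use Tukey HSD.
#' Richness-versus-latitude trends are fit as linear models with the number
#' of blood meals per network as a sampling-effort covariate.
NULL

.MAIN_TERMS <- c("habitat", "abs_latitude", "S", "log_m", "dominant_family")
.INTERACTION_TERMS <- c("dominant_family:abs_latitude",
                        "dominant_family:habitat")

#' Build the per-network analysis table
#'
#' Assembles metric summaries into the rectangular table the models are fit
#' on. Networks whose metrics are flagged (undefined IE, degenerate H2')
#' are excluded by default and counted in attribute `exclusions`.
#'
#' @param metrics data.frame from [summarise_networks()], or a list of
#'   one-row summaries.
#' @param drop_flagged exclude flagged networks (default TRUE).
#' @return data.frame with columns network_id, IE, H2prime, habitat,
#'   abs_latitude, S, log_m, dominant_family, n_bloodmeals, n_hosts,
#'   n_diptera; attribute `exclusions` gives the dropped rows.
#' @export
metrics_table <- function(metrics, drop_flagged = TRUE) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, metrics)
  if (is.null(metrics) || nrow(metrics) == 0)
    stop("metrics_table needs at least one network")
  flagged <- nzchar(metrics$flags)
  excl <- metrics[flagged & drop_flagged, , drop = FALSE]
  keep <- metrics[!(flagged & drop_flagged), , drop = FALSE]
  out <- data.frame(
    network_id = keep$network_id,
    IE = keep$IE,
    H2prime = keep$H2prime,
    habitat = factor(keep$habitat, levels = HABITAT_LEVELS),
    abs_latitude = keep$abs_latitude,
    S = keep$S,
    log_m = log(keep$m),
    dominant_family = factor(keep$dominant_family),
    n_bloodmeals = keep$m,
    n_hosts = keep$n_hosts,
    n_diptera = keep$n_diptera,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

.model_formula <- function(response, terms) {
  stats::as.formula(paste(response, "~",
                          if (length(terms)) paste(terms, collapse = " + ")
                          else "1"))
}

# single-family tables cannot carry family terms
.usable_terms <- function(table, terms) {
  if (nlevels(droplevels(table$dominant_family)) < 2)
    terms <- terms[!grepl("dominant_family", terms)]
  if (nlevels(droplevels(table$habitat)) < 2)
    terms <- terms[!grepl("habitat", terms)]
  terms
}

#' Fit the full Gaussian GLM for a network metric
#'
#' Full model: `response ~ habitat + abs_latitude + S + log_m + family +
#' family:abs_latitude + family:habitat` with Gaussian errors. Terms whose
#' factor collapses to a single level are dropped; aliased coefficients
#' from rank deficiency are reported as NA by `glm` and the fit proceeds on
#' the estimable terms.
#'
#' @param table analysis table from [metrics_table()].
#' @param response `"IE"` or `"H2prime"`.
#' @param interactions include the family-by-latitude and family-by-habitat
#'   interactions (default TRUE).
#' @return fitted `glm` object.
#' @export
fit_metric_model <- function(table, response = c("IE", "H2prime"),
                             interactions = TRUE) {
  response <- match.arg(response)
  terms <- .usable_terms(table, c(.MAIN_TERMS,
                                  if (interactions) .INTERACTION_TERMS))
  stats::glm(.model_formula(response, terms), family = stats::gaussian(),
             data = table)
}

#' Chi-square deviance test for one model term
#'
#' Compares nested Gaussian GLMs with and without `term`, respecting
#' marginality: main effects are tested in the main-effects model (no
#' interactions present), interactions are tested against the full
#' main-effects model. The statistic reported is the raw change in deviance
#' (for a Gaussian GLM, the change in residual sum of squares). Three
#' p-values are returned, clearly labelled: `p_value`, from the exact
#' Gaussian F test (mean deviance change over the estimated dispersion of
#' the larger model); `p_chisq`, the dispersion-scaled chi-square test
#' (asymptotic, slightly liberal at small n); and `p_raw`, from referring
#' the raw deviance change itself to a chi-square distribution.
#'
#' @param table analysis table.
#' @param response `"IE"` or `"H2prime"`.
#' @param term one of `habitat`, `abs_latitude`, `S`, `log_m`,
#'   `dominant_family`, `dominant_family:abs_latitude`,
#'   `dominant_family:habitat`.
#' @return one-row data.frame: term, deviance_change, df, p_value,
#'   p_chisq, p_raw.
#' @export
term_significance <- function(table, response = c("IE", "H2prime"), term) {
  response <- match.arg(response)
  mains <- .usable_terms(table, .MAIN_TERMS)
  ints <- .usable_terms(table, .INTERACTION_TERMS)
  if (term %in% mains) {
    full_terms <- mains
    red_terms <- setdiff(mains, term)
  } else if (term %in% ints) {
    full_terms <- c(mains, term)
    red_terms <- mains
  } else {
    stop("term ", sQuote(term), " not available in this table ",
         "(or collapsed to a single level)")
  }
  full <- stats::glm(.model_formula(response, full_terms),
                     family = stats::gaussian(), data = table)
  red <- stats::glm(.model_formula(response, red_terms),
                    family = stats::gaussian(), data = table)
  dev <- stats::deviance(red) - stats::deviance(full)
  df <- stats::df.residual(red) - stats::df.residual(full)
  if (df < 1) {
    return(data.frame(term = term, deviance_change = dev, df = df,
                      p_value = NA_real_, p_chisq = NA_real_,
                      p_raw = NA_real_))
  }
  dev <- max(dev, 0)  # guard tiny negative rounding
  phi <- stats::deviance(full) / stats::df.residual(full)
  data.frame(term = term,
             deviance_change = dev,
             df = df,
             p_value = stats::pf(dev / df / phi, df,
                                 stats::df.residual(full),
                                 lower.tail = FALSE),
             p_chisq = stats::pchisq(dev / phi, df, lower.tail = FALSE),
             p_raw = stats::pchisq(dev, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Deviance tests for every model term
#'
#' @param table analysis table.
#' @param response `"IE"` or `"H2prime"`.
#' @return data.frame, one row per available term.
#' @export
term_table <- function(table, response = c("IE", "H2prime")) {
  response <- match.arg(response)
  terms <- c(.usable_terms(table, .MAIN_TERMS),
             .usable_terms(table, .INTERACTION_TERMS))
  do.call(rbind, lapply(terms, function(tm)
    term_significance(table, response, tm)))
}

#' Tukey HSD contrasts between habitat types
#'
#' Pairwise habitat comparisons with the Tukey (studentized-range)
#' adjustment. By default contrasts are between model-adjusted habitat
#' means — estimated marginal means of the main-effects GLM, so the
#' comparison controls for latitude, richness, size and family; `"raw"`
#' compares unadjusted group means via `TukeyHSD(aov(response ~ habitat))`.
#'
#' @param table analysis table with all three habitat levels.
#' @param response `"IE"` or `"H2prime"`.
#' @param method `"model"` (adjusted means, default) or `"raw"`.
#' @return data.frame with columns contrast, estimate, se, p_adj; attribute
#'   `method`.
#' @export
tukey_habitat <- function(table, response = c("IE", "H2prime"),
                          method = c("model", "raw")) {
  response <- match.arg(response)
  method <- match.arg(method)
  if (nlevels(droplevels(table$habitat)) < 2)
    stop("tukey_habitat needs at least two habitat levels")
  if (method == "model") {
    fit <- fit_metric_model(table, response, interactions = FALSE)
    emm <- emmeans::emmeans(fit, "habitat")
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                           adjust = "tukey"))
    out <- data.frame(contrast = as.character(prs$contrast),
                      estimate = prs$estimate, se = prs$SE,
                      p_adj = prs$p.value, stringsAsFactors = FALSE)
  } else {
    fit <- stats::aov(.model_formula(response, "habitat"), data = table)
    tk <- stats::TukeyHSD(fit)$habitat
    out <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                      se = NA_real_, p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
  }
  attr(out, "method") <- method
  out
}

#' Richness-versus-latitude linear model
#'
#' `richness ~ abs_latitude + n_bloodmeals`: does host (or Diptera)
#' richness trend with absolute latitude once sampling effort (total blood
#' meals per network) is controlled for?
#'
#' @param table analysis table.
#' @param response `"host_richness"` or `"diptera_richness"`.
#' @return fitted `lm`; attribute `latitude_test` holds the latitude
#'   slope's estimate, t and p.
#' @export
richness_latitude_model <- function(table,
                                    response = c("host_richness",
                                                 "diptera_richness")) {
  response <- match.arg(response)
  col <- if (response == "host_richness") "n_hosts" else "n_diptera"
  dat <- data.frame(richness = table[[col]],
                    abs_latitude = table$abs_latitude,
                    n_bloodmeals = table$n_bloodmeals)
  fit <- stats::lm(richness ~ abs_latitude + n_bloodmeals, data = dat)
  cf <- summary(fit)$coefficients
  attr(fit, "latitude_test") <-
    data.frame(estimate = cf["abs_latitude", "Estimate"],
               t = cf["abs_latitude", "t value"],
               p = cf["abs_latitude", "Pr(>|t|)"])
  fit
}

#' Coefficient t-statistic of one term in the full model
#'
#' Convenience accessor, e.g. for the matrix-size (log_m) effect on H2'.
#'
#' @param table analysis table.
#' @param response `"IE"` or `"H2prime"`.
#' @param term coefficient name as it appears in the model.
#' @param interactions include interaction terms in the model.
#' @return one-row data.frame: estimate, t, df, p.
#' @export
coefficient_test <- function(table, response, term, interactions = TRUE) {
  fit <- fit_metric_model(table, response, interactions = interactions)
  cf <- summary(fit)$coefficients
  if (!term %in% rownames(cf)) stop("no coefficient named ", sQuote(term))
  data.frame(estimate = cf[term, "Estimate"], t = cf[term, "t value"],
             df = stats::df.residual(fit), p = cf[term, "Pr(>|t|)"])
}
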