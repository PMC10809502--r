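#' Filter a concordance table on annotation flags
#'
#' Removes uptake-transporter substrates and/or low-recovery compounds from
#' an in vitro / in vivo comparison, keeping an exclusion log. Uptake
#' substrates are excluded by convention because the MDCKII-MDR1 monolayer
#' expresses no uptake transporters, so their in vitro values cannot match
#' in vivo behaviour.
#'
#' @param pairs data frame with columns `compound_id`, `in_vitro`,
#'   `in_vivo` and logical flags `uptake_substrate`, `low_recovery`
#'   (missing flag columns are treated as all-`FALSE`).
#' @param exclude_uptake drop compounds flagged as uptake substrates.
#' @param exclude_low_recovery drop compounds flagged as low recovery.
#' @return the filtered data frame, with an `"exclusions"` attribute: a
#'   data frame naming each removed compound and the reason.
#' @export
filter_compounds <- function(pairs, exclude_uptake = FALSE,
                             exclude_low_recovery = FALSE) {
  if (is.null(pairs$uptake_substrate)) pairs$uptake_substrate <- FALSE
  if (is.null(pairs$low_recovery)) pairs$low_recovery <- FALSE
  drop_uptake <- exclude_uptake & pairs$uptake_substrate
  drop_lowrec <- exclude_low_recovery & pairs$low_recovery & !drop_uptake
  excl <- rbind(
    if (any(drop_uptake)) data.frame(compound_id = pairs$compound_id[drop_uptake],
                                     reason = "uptake_substrate",
                                     stringsAsFactors = FALSE),
    if (any(drop_lowrec)) data.frame(compound_id = pairs$compound_id[drop_lowrec],
                                     reason = "low_recovery",
                                     stringsAsFactors = FALSE))
  if (is.null(excl)) {
    excl <- data.frame(compound_id = character(), reason = character(),
                       stringsAsFactors = FALSE)
  }
  out <- pairs[!(drop_uptake | drop_lowrec), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Log-log ordinary least squares between in vitro and in vivo values
#'
#' Fits `log10(y) ~ log10(x)` by OLS. The in vitro dynamic range of a
#' transwell equilibrium assay is compressed relative to in vivo, so with
#' in vitro on the x-axis the slope exceeds 1; that orientation
#' (`"invitro_on_x"`) is the primary one. R-squared (the squared Pearson
#' correlation of the log values) is identical in both orientations; the
#' slope is not.
#'
#' @param pairs data frame with positive columns `in_vitro` and `in_vivo`.
#'   Non-positive values cannot be log-transformed and are dropped with a
#'   warning.
#' @param orientation `"invitro_on_x"` (default, primary) or
#'   `"invivo_on_x"`.
#' @return list with `slope`, `intercept`, `r_squared`, `n` and
#'   `orientation`.
#' @export
loglog_regression <- function(pairs,
                              orientation = c("invitro_on_x", "invivo_on_x")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(pairs$in_vitro) & !is.na(pairs$in_vivo) &
    pairs$in_vitro > 0 & pairs$in_vivo > 0
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) with non-positive or missing values excluded")
  }
  pairs <- pairs[ok, , drop = FALSE]
  stop_if(nrow(pairs) < 3, "log-log regression needs at least 3 valid pairs")
  if (orientation == "invitro_on_x") {
    x <- log10(pairs$in_vitro); y <- log10(pairs$in_vivo)
  } else {
    x <- log10(pairs$in_vivo); y <- log10(pairs$in_vitro)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = stats::cor(x, y)^2,
       n = nrow(pairs), orientation = orientation)
}

#' Fraction of compounds within twofold of the in vivo value
#'
#' Fraction of pairs with 0.5 <= in_vitro/in_vivo <= 2. Symmetric under
#' reciprocal ratios and under exchanging the two assays.
#'
#' @param pairs data frame with positive `in_vitro` and `in_vivo` columns.
#' @return fraction in `[0, 1]`.
#' @export
twofold_fraction <- function(pairs) {
  stop_if(nrow(pairs) < 1, "need at least one pair")
  ratio <- pairs$in_vitro / pairs$in_vivo
  mean(ratio >= 0.5 & ratio <= 2)
}

#' Brain-penetration category agreement between in vitro and in vivo
#'
#' Classifies both Kp,uu values with [classify_brain_penetration()] and
#' reports the fraction of compounds whose categories match, together with
#' the 3x3 confusion table (in vivo category in rows, in vitro in columns).
#'
#' @param pairs data frame with positive `in_vitro` and `in_vivo` Kp,uu
#'   columns.
#' @return list with `agreement` (fraction) and `confusion` (3x3 table).
#' @export
category_agreement <- function(pairs) {
  stop_if(nrow(pairs) < 1, "need at least one pair")
  lev <- c("restricted", "partial", "unrestricted")
  vit <- factor(classify_brain_penetration(pairs$in_vitro), levels = lev)
  viv <- factor(classify_brain_penetration(pairs$in_vivo), levels = lev)
  list(agreement = mean(vit == viv),
       confusion = table(in_vivo = viv, in_vitro = vit))
}

#' Full in vitro / in vivo concordance report
#'
#' Assembles the concordance statistics for one metric (Kp,brain or
#' Kp,uu,brain): log-log OLS in both orientations (the compressed-in-vitro
#' orientation labeled primary), the twofold-agreement fraction, the
#' brain-penetration category agreement with its confusion table, a
#' per-compound table of fold errors and category pairs, and the exclusion
#' log. Fractions are also reported as whole percents.
#'
#' @param pairs data frame with columns `compound_id`, `in_vitro`,
#'   `in_vivo` and optional flags `uptake_substrate`, `low_recovery`.
#' @param exclude_uptake,exclude_low_recovery passed to
#'   [filter_compounds()]; uptake substrates are excluded by default.
#' @return list of class `concordance_report` with elements `n_included`,
#'   `regression_primary`, `regression_secondary`, `twofold_fraction`,
#'   `twofold_pct`, `category_agreement`, `category_agreement_pct`,
#'   `confusion`, `per_compound`, `exclusions`.
#' @export
concordance_report <- function(pairs, exclude_uptake = TRUE,
                               exclude_low_recovery = FALSE) {
  kept <- filter_compounds(pairs, exclude_uptake = exclude_uptake,
                           exclude_low_recovery = exclude_low_recovery)
  excl <- attr(kept, "exclusions")
  # values that cannot enter ratio or log statistics (censored Kp, missing
  # in vivo reference) are excluded and logged, never silently zeroed
  usable <- !is.na(kept$in_vitro) & !is.na(kept$in_vivo) &
    kept$in_vitro > 0 & kept$in_vivo > 0
  if (any(!usable)) {
    excl <- rbind(excl, data.frame(compound_id = kept$compound_id[!usable],
                                   reason = "missing_or_nonpositive_value",
                                   stringsAsFactors = FALSE))
    kept <- kept[usable, , drop = FALSE]
    attr(kept, "exclusions") <- excl
  }
  stop_if(nrow(kept) < 1, "no compounds remain after filtering")
  reg1 <- loglog_regression(kept, "invitro_on_x")
  reg2 <- loglog_regression(kept, "invivo_on_x")
  tf <- twofold_fraction(kept)
  ca <- category_agreement(kept)
  per <- data.frame(
    compound_id = kept$compound_id,
    in_vitro = kept$in_vitro, in_vivo = kept$in_vivo,
    fold_error = pmax(kept$in_vitro / kept$in_vivo,
                      kept$in_vivo / kept$in_vitro),
    within_twofold = kept$in_vitro / kept$in_vivo >= 0.5 &
      kept$in_vitro / kept$in_vivo <= 2,
    class_in_vitro = classify_brain_penetration(kept$in_vitro),
    class_in_vivo = classify_brain_penetration(kept$in_vivo),
    stringsAsFactors = FALSE)
  per$class_match <- per$class_in_vitro == per$class_in_vivo
  structure(
    list(n_included = nrow(kept),
         regression_primary = reg1, regression_secondary = reg2,
         twofold_fraction = tf, twofold_pct = round_half_up(100 * tf, 0),
         category_agreement = ca$agreement,
         category_agreement_pct = round_half_up(100 * ca$agreement, 0),
         confusion = ca$confusion,
         per_compound = per,
         exclusions = attr(kept, "exclusions")),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("In vitro / in vivo concordance (n =", x$n_included, "included)\n")
  cat(sprintf("  log-log OLS (primary, in vitro on x): slope %.2f, R^2 %.2f\n",
              x$regression_primary$slope, x$regression_primary$r_squared))
  cat(sprintf("  log-log OLS (in vivo on x):           slope %.2f, R^2 %.2f\n",
              x$regression_secondary$slope, x$regression_secondary$r_squared))
  cat(sprintf("  within twofold: %d%%   category agreement: %d%%\n",
              x$twofold_pct, x$category_agreement_pct))
  if (nrow(x$exclusions)) {
    cat("  excluded:", paste(x$exclusions$compound_id, collapse = ", "), "\n")
  }
  invisible(x)
}
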