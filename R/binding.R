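#' Equilibrium-dialysis measurement of one compound in one matrix
#'
#' A buffer/matrix concentration pair from a two-chamber equilibrium
#' dialysis device (matrix side spiked with compound, dialysed against
#' protein-free buffer). `matrix_dilution` records the fold-dilution of the
#' protein matrix relative to its physiological concentration (e.g. 20 for
#' 35 uM BSA standing in for 700 uM, or for brain homogenate diluted 1:19).
#'
#' @param compound_id compound identifier.
#' @param matrix one of `"BSA"`, `"brain_homogenate"`, `"plasma"`.
#' @param c_buffer concentration measured on the buffer side (uM), >= 0.
#' @param c_matrix concentration measured on the matrix side (uM), > 0.
#' @param matrix_dilution dilution factor D >= 1.
#' @param recovery_pct optional dialysis mass-balance recovery (percent).
#' @return An object of class `binding_measurement`.
#' @export
binding_measurement <- function(compound_id,
                                matrix = c("BSA", "brain_homogenate", "plasma"),
                                c_buffer, c_matrix,
                                matrix_dilution = 1,
                                recovery_pct = NA_real_) {
  matrix <- match.arg(matrix)
  stop_if(!is_scalar_number(c_matrix) || c_matrix <= 0,
          "c_matrix must be > 0")
  stop_if(!is_scalar_number(c_buffer) || c_buffer < 0,
          "c_buffer must be >= 0")
  stop_if(!is_scalar_number(matrix_dilution) || matrix_dilution < 1,
          "matrix_dilution must be >= 1")
  structure(
    list(compound_id = as.character(compound_id), matrix = matrix,
         c_buffer = c_buffer, c_matrix = c_matrix,
         matrix_dilution = matrix_dilution, recovery_pct = recovery_pct),
    class = "binding_measurement"
  )
}

#' Measured fraction unbound from an equilibrium-dialysis pair
#'
#' fu = C_buffer / C_matrix: at dialysis equilibrium the buffer side holds
#' only unbound drug at the same unbound concentration as the matrix side,
#' so the concentration ratio is the unbound fraction. Assay noise can push
#' the ratio above one for very weakly bound compounds; since fu is a
#' physical fraction such values are clamped to 1 and flagged, and the
#' clamped value is what enters downstream Kp,uu arithmetic.
#'
#' @param m a [binding_measurement()].
#' @param qc_recovery_min minimum acceptable dialysis recovery (percent)
#'   when a recovery is supplied; default 75.
#' @return An object of class `fu_result`: list with `compound_id`,
#'   `matrix`, `fu` in (0, 1], `clamped` (TRUE when the raw ratio exceeded
#'   1), `fu_raw`, `source = "measured"` and `qc_pass` (`NA` when no
#'   recovery was supplied).
#' @export
measured_fu <- function(m, qc_recovery_min = 75) {
  stop_if(!inherits(m, "binding_measurement"),
          "m must be a binding_measurement")
  raw <- m$c_buffer / m$c_matrix
  structure(
    list(compound_id = m$compound_id, matrix = m$matrix,
         fu = min(raw, 1), clamped = raw > 1, fu_raw = raw,
         source = "measured",
         qc_pass = if (is.na(m$recovery_pct)) NA else
           m$recovery_pct >= qc_recovery_min),
    class = "fu_result"
  )
}

#' Predict the fraction unbound at a diluted matrix concentration
#'
#' The Austin single-site dilution relation maps a fraction unbound measured
#' at protein concentration c1 to the fraction unbound expected at protein
#' concentration c2:
#' \deqn{f_{u2} = \frac{1}{\frac{c_2}{c_1}\,\frac{1 - f_{u1}}{f_{u1}} + 1}}
#' With c1 = 1 (undiluted matrix) and c2 = 0.05 this predicts the unbound
#' fraction after a 20-fold dilution. Dilution can only release drug, so
#' fu2 lies in (fu1, 1] whenever c2 < c1, and fu2 = fu1 at c2 = c1.
#'
#' @param fu1 fraction unbound at matrix concentration `c1`, in (0, 1].
#' @param c2 relative matrix concentration of interest (e.g. 0.05).
#' @param c1 reference relative matrix concentration (default 1).
#' @param dilution alternatively, the fold-dilution D, taken as
#'   `c2 = c1 / D`. Supply either `c2` or `dilution`.
#' @return predicted fraction unbound at `c2` (vectorized over `fu1`).
#' @seealso [invert_fu_dilution()] for the inverse mapping.
#' @export
#' @examples
#' predict_fu_dilution(0.05, dilution = 20) # 0.5128...
predict_fu_dilution <- function(fu1, c2 = NULL, c1 = 1, dilution = NULL) {
  if (is.null(c2)) {
    stop_if(is.null(dilution), "supply either c2 or dilution")
    c2 <- c1 / dilution
  }
  stop_if(any(fu1 <= 0), "fu1 must be > 0 (fu1 = 0 implies infinite binding)")
  stop_if(any(fu1 > 1), "fu1 must be <= 1")
  stop_if(any(c2 <= 0) || any(c2 > c1), "require 0 < c2 <= c1")
  1 / ((c2 / c1) * ((1 - fu1) / fu1) + 1)
}

#' Invert the Austin dilution relation
#'
#' Recovers the fraction unbound at the reference matrix concentration c1
#' from a fraction unbound at concentration c2. Exact algebraic inverse of
#' [predict_fu_dilution()].
#'
#' @param fu2 fraction unbound at `c2`, in (0, 1].
#' @param c2,c1 relative matrix concentrations as in [predict_fu_dilution()].
#' @param dilution alternatively the fold-dilution D (`c2 = c1 / D`).
#' @return fraction unbound at `c1`.
#' @export
invert_fu_dilution <- function(fu2, c2 = NULL, c1 = 1, dilution = NULL) {
  if (is.null(c2)) {
    stop_if(is.null(dilution), "supply either c2 or dilution")
    c2 <- c1 / dilution
  }
  stop_if(any(fu2 <= 0) || any(fu2 > 1), "fu2 must be in (0, 1]")
  r <- c2 / c1
  r / ((1 / fu2 - 1) + r)
}

#' Side-by-side measured vs predicted fraction-unbound table
#'
#' Joins dialysis-measured unbound fractions with dilution-scaled
#' predictions per compound and matrix, reporting the relative difference
#' |predicted - measured| / measured binned as `"<10%"`, `"10-20%"` or
#' `">20%"`. Compounds or matrices present in only one source are reported
#' with the other side absent (`NA`) rather than dropped.
#'
#' @param measured data frame with columns `compound_id`, `matrix`,
#'   `c_buffer_uM`, `c_matrix_uM` and optionally `dilution_factor`,
#'   `recovery_pct` (the `dialysis.csv` schema).
#' @param reference data frame with columns `compound_id`, `matrix`,
#'   `fu_at_c1`, `c2_over_c1` (the `fu_reference.csv` schema) giving the
#'   undiluted-matrix fu from which to predict.
#' @return data frame with one row per compound x matrix: `fu_measured`
#'   (clamped), `fu_measured_clamped` flag, `qc_pass`, `fu_predicted`,
#'   `rel_diff` and `diff_bin`.
#' @export
fu_table <- function(measured, reference) {
  meas <- NULL
  if (!is.null(measured) && nrow(measured)) {
    rows <- lapply(seq_len(nrow(measured)), function(i) {
      r <- measured[i, ]
      fr <- measured_fu(binding_measurement(
        r$compound_id, r$matrix,
        c_buffer = r$c_buffer_uM, c_matrix = r$c_matrix_uM,
        matrix_dilution = if (is.null(r$dilution_factor) ||
                              is.na(r$dilution_factor)) 1 else r$dilution_factor,
        recovery_pct = if (is.null(r$recovery_pct)) NA_real_ else r$recovery_pct))
      data.frame(compound_id = fr$compound_id, matrix = fr$matrix,
                 fu_measured = fr$fu, fu_measured_clamped = fr$clamped,
                 qc_pass = if (is.na(fr$qc_pass)) NA else fr$qc_pass,
                 stringsAsFactors = FALSE)
    })
    meas <- do.call(rbind, rows)
    # replicate-level rows averaged per compound x matrix before comparison
    meas <- stats::aggregate(
      cbind(fu_measured = meas$fu_measured),
      by = list(compound_id = meas$compound_id, matrix = meas$matrix),
      FUN = mean)
    flags <- do.call(rbind, rows)
    key <- paste(meas$compound_id, meas$matrix)
    meas$fu_measured_clamped <- vapply(key, function(k) {
      any(flags$fu_measured_clamped[paste(flags$compound_id, flags$matrix) == k])
    }, logical(1))
    meas$qc_pass <- vapply(key, function(k) {
      q <- flags$qc_pass[paste(flags$compound_id, flags$matrix) == k]
      if (all(is.na(q))) NA else all(q[!is.na(q)])
    }, logical(1))
  }

  pred <- NULL
  if (!is.null(reference) && nrow(reference)) {
    pred <- data.frame(
      compound_id = reference$compound_id, matrix = reference$matrix,
      fu_predicted = predict_fu_dilution(reference$fu_at_c1,
                                         c2 = reference$c2_over_c1),
      stringsAsFactors = FALSE)
  }

  if (is.null(meas) && is.null(pred)) {
    return(data.frame(compound_id = character(), matrix = character(),
                      fu_measured = numeric(), fu_measured_clamped = logical(),
                      qc_pass = logical(), fu_predicted = numeric(),
                      rel_diff = numeric(), diff_bin = character(),
                      stringsAsFactors = FALSE))
  }
  out <- if (is.null(meas)) {
    cbind(pred[, c("compound_id", "matrix")],
          fu_measured = NA_real_, fu_measured_clamped = NA,
          qc_pass = NA, fu_predicted = pred$fu_predicted)
  } else if (is.null(pred)) {
    cbind(meas, fu_predicted = NA_real_)
  } else {
    merge(meas, pred, by = c("compound_id", "matrix"), all = TRUE)
  }
  out$rel_diff <- abs(out$fu_predicted - out$fu_measured) / out$fu_measured
  out$diff_bin <- bin_rel_diff(out$rel_diff)
  out[order(out$compound_id, out$matrix), , drop = FALSE]
}

bin_rel_diff <- function(rel_diff) {
  ifelse(is.na(rel_diff), NA_character_,
         ifelse(rel_diff < 0.10, "<10%",
                ifelse(rel_diff <= 0.20, "10-20%", ">20%")))
}
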