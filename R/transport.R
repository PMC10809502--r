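#' Transwell geometry for a bidirectional transport assay
#'
#' Bundles the chamber volumes, filter area and incubation time of one leg of
#' a bidirectional permeability experiment. The default geometry is the
#' 96-well insert format used for 1-h MDCKII-MDR1 screens: 50 uL apical
#' donor, 250 uL basolateral receiver, 0.0804 cm2 filter.
#'
#' @param donor_volume_ul donor chamber volume (uL), > 0.
#' @param receiver_volume_ul receiver chamber volume (uL), > 0.
#' @param area_cm2 monolayer surface area (cm2), > 0.
#' @param duration_s incubation time (s), > 0.
#' @return An object of class `transport_geometry`.
#' @export
transport_geometry <- function(donor_volume_ul = 50,
                               receiver_volume_ul = 250,
                               area_cm2 = 0.0804,
                               duration_s = 3600) {
  vals <- c(donor_volume_ul, receiver_volume_ul, area_cm2, duration_s)
  stop_if(!all(vapply(vals, is_scalar_number, logical(1))) || any(vals <= 0),
          "all geometry fields must be strictly positive numbers")
  structure(
    list(donor_volume_ul = donor_volume_ul,
         receiver_volume_ul = receiver_volume_ul,
         area_cm2 = area_cm2,
         duration_s = duration_s),
    class = "transport_geometry"
  )
}

#' One leg of a bidirectional transport measurement
#'
#' Concentrations are in uM. A receiver (or donor) concentration below the
#' lower limit of quantification is represented by `NA` together with the
#' `lloq` field; downstream calculations propagate it as an explicit
#' censored state, never as zero.
#'
#' @param compound_id compound identifier.
#' @param direction `"AtoB"` (apical-to-basolateral) or `"BtoA"`.
#' @param c0_donor initial donor concentration (uM), > 0.
#' @param c_donor_final final donor concentration (uM), or `NA` if censored.
#' @param c_receiver_final final receiver concentration (uM), or `NA` if
#'   censored.
#' @param c_cell_lysate optional concentration in the cell lysate (uM).
#' @param lloq lower limit of quantification (uM); values below it are
#'   treated as censored.
#' @param geometry a [transport_geometry()].
#' @return An object of class `transport_measurement`.
#' @export
transport_measurement <- function(compound_id, direction,
                                  c0_donor, c_donor_final, c_receiver_final,
                                  c_cell_lysate = NA_real_,
                                  lloq = 0,
                                  geometry = transport_geometry()) {
  direction <- match.arg(direction, c("AtoB", "BtoA"))
  stop_if(!is_scalar_number(c0_donor) || c0_donor <= 0,
          "c0_donor must be a positive number")
  for (v in list(c_donor_final, c_receiver_final, c_cell_lysate)) {
    stop_if(!is.na(v) && (!is.numeric(v) || v < 0),
            "concentrations must be non-negative or NA (censored)")
  }
  stop_if(!inherits(geometry, "transport_geometry"),
          "geometry must be a transport_geometry object")
  structure(
    list(compound_id = as.character(compound_id), direction = direction,
         c0_donor = c0_donor, c_donor_final = c_donor_final,
         c_receiver_final = c_receiver_final, c_cell_lysate = c_cell_lysate,
         lloq = lloq, geometry = geometry),
    class = "transport_measurement"
  )
}

is_censored <- function(value, lloq) {
  is.na(value) || value < lloq
}

#' Apparent permeability coefficient from a single transport leg
#'
#' Computes Papp = (dCr/dt) * Vr / (A * C0) with the receiver accumulation
#' rate estimated as the end-point receiver concentration over the incubation
#' time (the receiver starts drug-free in a one-interval design). The result
#' is reported in 1e-6 cm/s, the unit permeability screens are tabulated in.
#' A receiver concentration below the LLOQ yields a censored result (papp
#' `NA`, class `"censored"`) rather than zero.
#'
#' @param m a [transport_measurement()].
#' @return An object of class `papp_result`: a list with `compound_id`,
#'   `direction`, `papp` (1e-6 cm/s or `NA`), `censored`,
#'   `recovery_without_cell`, `recovery_with_cell` (percent, `NA` when no
#'   lysate measurement exists) and `permeability_class`.
#' @seealso [classify_permeability()], [compute_efflux_ratio()]
#' @export
#' @examples
#' g <- transport_geometry(50, 250, 0.0804, 3600)
#' m <- transport_measurement("drug", "AtoB", c0_donor = 1,
#'                            c_donor_final = 0.9, c_receiver_final = 0.01,
#'                            geometry = g)
#' compute_papp(m)$papp # ~8.64e-6 cm/s reported as 8.64
compute_papp <- function(m) {
  stop_if(!inherits(m, "transport_measurement"),
          "m must be a transport_measurement")
  g <- m$geometry
  censored <- is_censored(m$c_receiver_final, m$lloq)
  if (censored) {
    papp <- NA_real_
    cls <- "censored"
  } else {
    # (uM/s) * cm3 / (cm2 * uM) = cm/s; scaled to 1e-6 cm/s
    papp <- (m$c_receiver_final / g$duration_s) *
      ul_to_cm3(g$receiver_volume_ul) / (g$area_cm2 * m$c0_donor) * 1e6
    cls <- classify_permeability(papp)
  }
  rec_wo <- if (is.na(m$c_donor_final) || censored) NA_real_ else
    compute_transport_recovery(m, include_cell = FALSE)
  rec_w <- if (!is.na(m$c_cell_lysate) && !is.na(rec_wo))
    compute_transport_recovery(m, include_cell = TRUE) else NA_real_
  structure(
    list(compound_id = m$compound_id, direction = m$direction,
         papp = papp, censored = censored,
         recovery_without_cell = rec_wo, recovery_with_cell = rec_w,
         permeability_class = cls),
    class = "papp_result"
  )
}

#' Construct a permeability result from a pre-tabulated Papp value
#'
#' For summary-level data where apparent permeabilities are already
#' tabulated (e.g. reported mean Papp values per direction) rather than
#' derived from raw concentrations. `NA` marks a below-LLOQ (censored)
#' permeability.
#'
#' @param compound_id compound identifier.
#' @param direction `"AtoB"` or `"BtoA"`.
#' @param papp apparent permeability in 1e-6 cm/s, or `NA` if censored.
#' @return An object of class `papp_result` usable with
#'   [compute_efflux_ratio()].
#' @export
papp_result <- function(compound_id, direction = c("AtoB", "BtoA"), papp) {
  direction <- match.arg(direction)
  censored <- is.na(papp)
  stop_if(!censored && papp < 0, "papp must be non-negative or NA (censored)")
  structure(
    list(compound_id = as.character(compound_id), direction = direction,
         papp = if (censored) NA_real_ else papp, censored = censored,
         recovery_without_cell = NA_real_, recovery_with_cell = NA_real_,
         permeability_class = if (censored) "censored" else
           classify_permeability(papp)),
    class = "papp_result")
}

#' Efflux ratio from a pair of directional permeabilities
#'
#' ER = Papp(BtoA) / Papp(AtoB). An efflux ratio above one indicates net
#' apical-directed (efflux) transport, the P-glycoprotein signature in
#' MDCKII-MDR1 monolayers. When the AtoB leg is censored but the BtoA leg is
#' quantifiable, no ratio can be formed yet apical-directed transport has
#' been demonstrated, so the compound is classed a "possible" substrate;
#' when the BtoA leg (or both) is censored the classification is
#' `"not_available"`.
#'
#' @param ab the AtoB [compute_papp()] result.
#' @param ba the BtoA result for the same compound.
#' @return An object of class `efflux_result`: list with `compound_id`, `er`
#'   (`NA` when not available) and `pgp_class`.
#' @export
compute_efflux_ratio <- function(ab, ba) {
  stop_if(!inherits(ab, "papp_result") || !inherits(ba, "papp_result"),
          "ab and ba must be papp_result objects")
  stop_if(ab$compound_id != ba$compound_id,
          "efflux ratio requires both directions for the same compound, got '",
          ab$compound_id, "' and '", ba$compound_id, "'")
  stop_if(ab$direction != "AtoB" || ba$direction != "BtoA",
          "ab must be the AtoB leg and ba the BtoA leg")
  if (!ab$censored && !ba$censored) {
    er <- ba$papp / ab$papp
    cls <- classify_pgp(er)
  } else if (ab$censored && !ba$censored) {
    er <- NA_real_
    cls <- "possible"
  } else {
    er <- NA_real_
    cls <- "not_available"
  }
  structure(list(compound_id = ab$compound_id, er = er, pgp_class = cls),
            class = "efflux_result")
}

#' Mass-balance recovery of a transport leg
#'
#' Recovery(\%) = 100 * (Vr*Cr + Vd*Cd + Vc*Cc) / (Vd*C0), where the cell
#' term Vc*Cc (insert well volume times lysate concentration) is included
#' only when `include_cell = TRUE`.
#'
#' @param m a [transport_measurement()].
#' @param include_cell include the filter/monolayer-associated amount.
#' @param cell_volume_ul insert well volume used for the lysate term
#'   (uL, default 50).
#' @return recovery in percent.
#' @export
compute_transport_recovery <- function(m, include_cell = FALSE,
                                       cell_volume_ul = 50) {
  stop_if(!inherits(m, "transport_measurement"),
          "m must be a transport_measurement")
  g <- m$geometry
  cd <- if (is.na(m$c_donor_final)) 0 else m$c_donor_final
  cr <- if (is.na(m$c_receiver_final)) 0 else m$c_receiver_final
  recovered <- g$receiver_volume_ul * cr + g$donor_volume_ul * cd
  if (include_cell) {
    stop_if(is.na(m$c_cell_lysate),
            "include_cell requested but no cell lysate concentration present")
    recovered <- recovered + cell_volume_ul * m$c_cell_lysate
  }
  100 * recovered / (g$donor_volume_ul * m$c0_donor)
}

#' Permeability classification
#'
#' Screening categories on Papp in 1e-6 cm/s: low below 1, moderate from 1
#' to 10 (inclusive at both ends), high above 10.
#'
#' @param papp apparent permeability (1e-6 cm/s), non-negative; vectorized.
#' @return character vector: `"low"`, `"moderate"` or `"high"`.
#' @export
classify_permeability <- function(papp) {
  stop_if(any(is.na(papp)) || any(papp < 0),
          "papp must be non-negative and quantified")
  ifelse(papp < 1, "low", ifelse(papp <= 10, "moderate", "high"))
}

#' P-glycoprotein substrate classification from the efflux ratio
#'
#' Unlikely substrate below 1.5, possible from 1.5 to 2 (inclusive),
#' likely above 2.
#'
#' @param er efflux ratio, > 0; vectorized.
#' @return character vector: `"unlikely"`, `"possible"` or `"likely"`.
#' @export
classify_pgp <- function(er) {
  stop_if(any(is.na(er)) || any(er <= 0), "er must be positive and quantified")
  ifelse(er < 1.5, "unlikely", ifelse(er <= 2, "possible", "likely"))
}

#' Per-compound permeability and efflux table from long-format transport data
#'
#' Table-level wrapper: takes a data frame with one row per compound x
#' direction (the `transport.csv` schema, see [read_transport_csv()]),
#' computes Papp, recoveries and classifications per leg and the efflux
#' ratio per compound.
#'
#' @param df data frame with columns `compound_id`, `direction`,
#'   `c0_donor_uM`, `c_donor_final_uM`, `c_receiver_final_uM`,
#'   `c_cell_lysate_uM`, `lloq_uM`, `donor_volume_uL`, `receiver_volume_uL`,
#'   `area_cm2`, `duration_s`.
#' @param include_cell include the cell/filter term in the with-cell
#'   recovery where a lysate concentration is present.
#' @return data frame with one row per compound: Papp for both directions
#'   (1e-6 cm/s), censoring flags, recoveries, permeability classes, `er`
#'   and `pgp_class`.
#' @export
papp_table <- function(df, include_cell = TRUE) {
  needed <- c("compound_id", "direction", "c0_donor_uM", "c_donor_final_uM",
              "c_receiver_final_uM", "lloq_uM", "donor_volume_uL",
              "receiver_volume_uL", "area_cm2", "duration_s")
  stop_if(!all(needed %in% names(df)),
          "missing columns: ", paste(setdiff(needed, names(df)), collapse = ", "))
  if (is.null(df$c_cell_lysate_uM)) df$c_cell_lysate_uM <- NA_real_

  one_leg <- function(row) {
    m <- transport_measurement(
      row$compound_id, row$direction,
      c0_donor = row$c0_donor_uM,
      c_donor_final = row$c_donor_final_uM,
      c_receiver_final = row$c_receiver_final_uM,
      c_cell_lysate = row$c_cell_lysate_uM,
      lloq = if (is.na(row$lloq_uM)) 0 else row$lloq_uM,
      geometry = transport_geometry(row$donor_volume_uL, row$receiver_volume_uL,
                                    row$area_cm2, row$duration_s))
    compute_papp(m)
  }

  out <- lapply(split(df, df$compound_id), function(sub) {
    legs <- lapply(seq_len(nrow(sub)), function(i) one_leg(sub[i, ]))
    names(legs) <- sub$direction
    ab <- legs[["AtoB"]]
    ba <- legs[["BtoA"]]
    er <- if (!is.null(ab) && !is.null(ba)) compute_efflux_ratio(ab, ba) else NULL
    leg_field <- function(leg, field) if (is.null(leg)) NA else leg[[field]]
    data.frame(
      compound_id = sub$compound_id[1],
      papp_AtoB_1e6_cm_s = leg_field(ab, "papp"),
      papp_BtoA_1e6_cm_s = leg_field(ba, "papp"),
      censored_AtoB = isTRUE(leg_field(ab, "censored")),
      censored_BtoA = isTRUE(leg_field(ba, "censored")),
      class_AtoB = as.character(leg_field(ab, "permeability_class")),
      class_BtoA = as.character(leg_field(ba, "permeability_class")),
      recovery_without_cell_AtoB_pct = leg_field(ab, "recovery_without_cell"),
      recovery_with_cell_AtoB_pct = leg_field(ab, "recovery_with_cell"),
      recovery_without_cell_BtoA_pct = leg_field(ba, "recovery_without_cell"),
      recovery_with_cell_BtoA_pct = leg_field(ba, "recovery_with_cell"),
      er = if (is.null(er)) NA_real_ else er$er,
      pgp_class = if (is.null(er)) "not_available" else er$pgp_class,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!include_cell) {
    out$recovery_with_cell_AtoB_pct <- NA_real_
    out$recovery_with_cell_BtoA_pct <- NA_real_
  }
  out
}
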