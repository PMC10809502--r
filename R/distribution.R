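#' Concentration-time series from a two-chamber equilibrium experiment
#'
#' Observed apical ("BSA"/blood side) and basolateral ("brain" side)
#' concentrations over a long-term transwell incubation. The default
#' geometry is the 12-well format: 500 uL apical, 1000 uL basolateral,
#' 40/80 uL aliquots drawn per sampling. Designs: `"UniL"` loads drug into
#' the apical chamber only; `"BiL"` loads both chambers to speed
#' equilibration.
#'
#' @param compound_id compound identifier.
#' @param design `"UniL"` or `"BiL"`.
#' @param times_h strictly increasing sampling times (h).
#' @param apical_conc,basolateral_conc observed concentrations (uM) at
#'   `times_h`; `NA` marks a censored (below-LLOQ) observation.
#' @param c0_apical initial apical concentration (uM).
#' @param c0_basolateral initial basolateral concentration (uM); must be 0
#'   for the Uni-L design.
#' @param apical_volume_ul,basolateral_volume_ul initial chamber volumes (uL).
#' @param apical_draw_ul,basolateral_draw_ul aliquot volume removed from
#'   each chamber at each sampling time (uL).
#' @param replace_volume were drawn aliquots replaced with blank matrix?
#'   Default `FALSE`: chamber volumes deplete as the experiment proceeds.
#' @return An object of class `chamber_timeseries`.
#' @export
chamber_timeseries <- function(compound_id, design = c("UniL", "BiL"),
                               times_h, apical_conc, basolateral_conc,
                               c0_apical, c0_basolateral = 0,
                               apical_volume_ul = 500,
                               basolateral_volume_ul = 1000,
                               apical_draw_ul = 40,
                               basolateral_draw_ul = 80,
                               replace_volume = FALSE) {
  design <- match.arg(design)
  stop_if(length(times_h) < 1 || is.unsorted(times_h, strictly = TRUE),
          "times_h must be strictly increasing")
  stop_if(length(apical_conc) != length(times_h) ||
            length(basolateral_conc) != length(times_h),
          "concentration vectors must match times_h in length")
  stop_if(any(stats::na.omit(c(apical_conc, basolateral_conc)) < 0),
          "concentrations must be non-negative")
  stop_if(design == "UniL" && c0_basolateral != 0,
          "Uni-L design requires c0_basolateral = 0")
  structure(
    list(compound_id = as.character(compound_id), design = design,
         times_h = times_h, apical_conc = apical_conc,
         basolateral_conc = basolateral_conc,
         c0_apical = c0_apical, c0_basolateral = c0_basolateral,
         apical_volume_ul = apical_volume_ul,
         basolateral_volume_ul = basolateral_volume_ul,
         apical_draw_ul = apical_draw_ul,
         basolateral_draw_ul = basolateral_draw_ul,
         replace_volume = replace_volume),
    class = "chamber_timeseries"
  )
}

#' In vitro Kp,brain: total brain-to-BSA concentration ratio at end of
#' incubation
#'
#' Kp,brain = C_total,brain / C_total,BSA evaluated at the final sampled
#' time point, the in vitro analogue of the total brain-to-plasma partition
#' coefficient. Replicates should be averaged before this ratio is taken.
#'
#' @param ts a [chamber_timeseries()].
#' @return the ratio (basolateral / apical) at the final time point.
#' @export
compute_kp_brain <- function(ts) {
  stop_if(!inherits(ts, "chamber_timeseries"),
          "ts must be a chamber_timeseries")
  n <- length(ts$times_h)
  ca <- ts$apical_conc[n]
  cb <- ts$basolateral_conc[n]
  stop_if(is.na(ca) || is.na(cb),
          "final time point must be quantified in both chambers")
  stop_if(ca == 0, "apical final concentration is zero; Kp,brain undefined")
  cb / ca
}

#' In vitro Kp,uu,brain from Kp,brain and the two unbound fractions
#'
#' Kp,uu,brain = Kp,brain * fu,brain / fu,BSA: scaling the total ratio by
#' the matrix unbound fractions converts it to the unbound brain-to-unbound
#' plasma ratio, the measure of the extent of brain penetration (1 for
#' purely passive distribution at equilibrium, < 1 under net efflux).
#'
#' @param kp_brain total concentration ratio from [compute_kp_brain()].
#' @param fu_brain fraction unbound in the brain-side matrix, in (0, 1].
#' @param fu_bsa fraction unbound in the BSA-side matrix, in (0, 1].
#' @return the unbound partition coefficient (vectorized).
#' @export
compute_kp_uu <- function(kp_brain, fu_brain, fu_bsa) {
  stop_if(any(kp_brain <= 0), "kp_brain must be > 0")
  stop_if(any(fu_brain <= 0) || any(fu_brain > 1) ||
            any(fu_bsa <= 0) || any(fu_bsa > 1),
          "unbound fractions must lie in (0, 1]")
  kp_brain * fu_brain / fu_bsa
}

#' Has the two-chamber system reached distribution equilibrium?
#'
#' Operational criterion: the relative concentration change between the two
#' final sampling times is at most `rel_tol` in both chambers. Low
#' permeability compounds typically fail this at 29 h in the Uni-L design.
#'
#' @param ts a [chamber_timeseries()] with at least two time points.
#' @param rel_tol maximum relative change still accepted as equilibrium
#'   (default 0.15).
#' @return `TRUE`/`FALSE`.
#' @export
assess_equilibrium <- function(ts, rel_tol = 0.15) {
  stop_if(!inherits(ts, "chamber_timeseries"),
          "ts must be a chamber_timeseries")
  n <- length(ts$times_h)
  stop_if(n < 2, "equilibrium assessment needs at least two time points")
  rel_change <- function(conc) {
    prev <- conc[n - 1]
    last <- conc[n]
    if (is.na(prev) || is.na(last)) return(NA_real_)
    if (prev == 0 && last == 0) return(0)
    abs(last - prev) / max(abs(prev), .Machine$double.eps)
  }
  da <- rel_change(ts$apical_conc)
  db <- rel_change(ts$basolateral_conc)
  stop_if(is.na(da) || is.na(db),
          "equilibrium assessment needs quantified final two time points")
  da <= rel_tol && db <= rel_tol
}

#' Mass-balance recovery of an equilibrium-distribution experiment
#'
#' Total recovered mass (final chamber amounts at their depleted volumes,
#' plus every interim sampled aliquot) over total loaded mass, in percent.
#' For Uni-L the denominator is the apical load only; for Bi-L both loads
#' contribute. The monolayer/filter-associated amount is not measurable in
#' this assay format, so recoveries run lower than in short transport
#' experiments; results are flagged against a 50\% acceptability floor.
#' Censored interim samples are skipped and the result flagged partial.
#'
#' @param ts a [chamber_timeseries()].
#' @param floor_pct acceptability floor in percent (default 50).
#' @return list with `recovery_pct`, `acceptable` (recovery >= floor) and
#'   `partial` (TRUE when censored interim samples were skipped).
#' @export
compute_distribution_recovery <- function(ts, floor_pct = 50) {
  stop_if(!inherits(ts, "chamber_timeseries"),
          "ts must be a chamber_timeseries")
  n <- length(ts$times_h)
  ca <- ts$apical_conc
  cb <- ts$basolateral_conc
  stop_if(is.na(ca[n]) || is.na(cb[n]),
          "final concentrations must be quantified for recovery")
  draws_before_final <- n - 1
  va_final <- ts$apical_volume_ul -
    if (ts$replace_volume) 0 else draws_before_final * ts$apical_draw_ul
  vb_final <- ts$basolateral_volume_ul -
    if (ts$replace_volume) 0 else draws_before_final * ts$basolateral_draw_ul
  stop_if(va_final <= 0 || vb_final <= 0,
          "sampling draws exceed chamber volume")

  interim_a <- ca[-n]
  interim_b <- cb[-n]
  partial <- any(is.na(interim_a)) || any(is.na(interim_b))
  sampled <- sum(interim_a * ts$apical_draw_ul, na.rm = TRUE) +
    sum(interim_b * ts$basolateral_draw_ul, na.rm = TRUE)
  recovered <- va_final * ca[n] + vb_final * cb[n] + sampled
  loaded <- ts$apical_volume_ul * ts$c0_apical +
    ts$basolateral_volume_ul * ts$c0_basolateral
  stop_if(loaded <= 0, "no drug loaded")
  rec <- 100 * recovered / loaded
  list(recovery_pct = rec, acceptable = rec >= floor_pct, partial = partial)
}

#' Brain-penetration classification from Kp,uu,brain
#'
#' Restricted below 0.3 (efflux-dominated), partially restricted from 0.3
#' to 0.7 (inclusive), unrestricted above 0.7.
#'
#' @param kp_uu unbound partition coefficient(s), > 0; vectorized.
#' @return character vector: `"restricted"`, `"partial"` or `"unrestricted"`.
#' @export
classify_brain_penetration <- function(kp_uu) {
  stop_if(any(is.na(kp_uu)) || any(kp_uu <= 0),
          "kp_uu must be positive and quantified")
  ifelse(kp_uu < 0.3, "restricted",
         ifelse(kp_uu <= 0.7, "partial", "unrestricted"))
}

#' Kp,brain / Kp,uu,brain results table from time-series and fu data
#'
#' Table-level wrapper joining a list of chamber time series (replicates
#' already averaged) with per-compound unbound fractions, emitting Kp,brain,
#' Kp,uu,brain under measured and/or predicted fu, the equilibrium flag,
#' recovery and the penetration class.
#'
#' @param ts_list list of [chamber_timeseries()] objects, one per compound
#'   and design.
#' @param fu data frame with columns `compound_id`, `matrix`
#'   (`"BSA"`/`"brain_homogenate"`), `fu`, `source`
#'   (`"measured"`/`"predicted"`); as produced by reshaping [fu_table()].
#' @param equilibrium_tol relative-change tolerance passed to
#'   [assess_equilibrium()].
#' @return data frame with one row per time series: `kp_brain`,
#'   `kp_uu_measured_fu`, `kp_uu_predicted_fu` (NA where the fu variant is
#'   absent), penetration classes for each variant, `equilibrium_reached`,
#'   `recovery_pct`, `recovery_acceptable` and `qc_pass` (equilibrium and
#'   recovery both acceptable).
#' @export
kp_table <- function(ts_list, fu, equilibrium_tol = 0.15) {
  fu_lookup <- function(id, matrix, source) {
    hit <- fu$fu[fu$compound_id == id & fu$matrix == matrix &
                   fu$source == source]
    if (length(hit)) hit[1] else NA_real_
  }
  rows <- lapply(ts_list, function(ts) {
    # censored (below-LLOQ) final samples make the ratio unavailable; such
    # series are reported with NA results rather than dropped
    kp <- tryCatch(compute_kp_brain(ts), error = function(e) NA_real_)
    eq <- tryCatch(assess_equilibrium(ts, rel_tol = equilibrium_tol),
                   error = function(e) NA)
    rec <- tryCatch(compute_distribution_recovery(ts),
                    error = function(e) list(recovery_pct = NA_real_,
                                             acceptable = NA, partial = TRUE))
    kpuu_for <- function(source) {
      fb <- fu_lookup(ts$compound_id, "brain_homogenate", source)
      fa <- fu_lookup(ts$compound_id, "BSA", source)
      if (is.na(fb) || is.na(fa) || is.na(kp)) NA_real_ else
        compute_kp_uu(kp, fb, fa)
    }
    kpuu_m <- kpuu_for("measured")
    kpuu_p <- kpuu_for("predicted")
    cls <- function(x) if (is.na(x)) NA_character_ else
      classify_brain_penetration(x)
    data.frame(
      compound_id = ts$compound_id, design = ts$design,
      kp_brain = kp,
      kp_uu_measured_fu = kpuu_m, kp_uu_predicted_fu = kpuu_p,
      class_measured_fu = cls(kpuu_m), class_predicted_fu = cls(kpuu_p),
      equilibrium_reached = eq,
      recovery_pct = rec$recovery_pct,
      recovery_acceptable = rec$acceptable,
      qc_pass = isTRUE(eq) && isTRUE(rec$acceptable),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
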