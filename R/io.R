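# CSV schema contracts and the end-to-end pipeline.

read_checked_csv <- function(path, required, na_tokens = c("", "NA")) {
  stop_if(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_tokens)
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          basename(path), ": missing columns: ",
          paste(missing, collapse = ", "))
  df
}

# Collect row-level schema violations; fail with a report naming each
# offending row and field instead of silently dropping rows.
validate_rows <- function(df, path, checks) {
  problems <- character()
  for (field in names(checks)) {
    bad <- which(checks[[field]](df))
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d, %s: invalid value (%s)",
                                      bad, field,
                                      as.character(df[[field]][bad])))
    }
  }
  stop_if(length(problems) > 0,
          basename(path), ": ", length(problems), " invalid row value(s):\n  ",
          paste(problems, collapse = "\n  "))
  invisible(df)
}

#' Read a bidirectional transport CSV
#'
#' Schema: `compound_id, direction, c0_donor_uM, c_donor_final_uM,
#' c_receiver_final_uM, c_cell_lysate_uM, lloq_uM, donor_volume_uL,
#' receiver_volume_uL, area_cm2, duration_s`. Empty cells are missing; the
#' literal token `LLOQ` in a concentration column marks a censored
#' (below-quantification) value and is read as `NA` alongside the `lloq_uM`
#' field. Malformed rows raise an error naming each row and field.
#'
#' @param path CSV file path.
#' @return validated data frame ready for [papp_table()].
#' @export
read_transport_csv <- function(path) {
  df <- read_checked_csv(
    path,
    required = c("compound_id", "direction", "c0_donor_uM", "c_donor_final_uM",
                 "c_receiver_final_uM", "lloq_uM", "donor_volume_uL",
                 "receiver_volume_uL", "area_cm2", "duration_s"),
    na_tokens = c("", "NA", "LLOQ", "<LLOQ"))
  if (is.null(df$c_cell_lysate_uM)) df$c_cell_lysate_uM <- NA_real_
  nonneg <- function(col) function(d) !is.na(d[[col]]) & d[[col]] < 0
  validate_rows(df, path, list(
    direction = function(d) !d$direction %in% c("AtoB", "BtoA"),
    c0_donor_uM = function(d) is.na(d$c0_donor_uM) | d$c0_donor_uM <= 0,
    c_donor_final_uM = nonneg("c_donor_final_uM"),
    c_receiver_final_uM = nonneg("c_receiver_final_uM"),
    donor_volume_uL = function(d) is.na(d$donor_volume_uL) | d$donor_volume_uL <= 0,
    receiver_volume_uL = function(d) is.na(d$receiver_volume_uL) |
      d$receiver_volume_uL <= 0,
    area_cm2 = function(d) is.na(d$area_cm2) | d$area_cm2 <= 0,
    duration_s = function(d) is.na(d$duration_s) | d$duration_s <= 0))
}

#' Read an equilibrium-dialysis CSV
#'
#' Schema: `compound_id, matrix, dilution_factor, c_buffer_uM, c_matrix_uM,
#' recovery_pct`.
#'
#' @param path CSV file path.
#' @return validated data frame ready for [fu_table()].
#' @export
read_dialysis_csv <- function(path) {
  df <- read_checked_csv(path, c("compound_id", "matrix", "dilution_factor",
                                 "c_buffer_uM", "c_matrix_uM"))
  if (is.null(df$recovery_pct)) df$recovery_pct <- NA_real_
  validate_rows(df, path, list(
    matrix = function(d) !d$matrix %in% c("BSA", "brain_homogenate", "plasma"),
    c_buffer_uM = function(d) is.na(d$c_buffer_uM) | d$c_buffer_uM < 0,
    c_matrix_uM = function(d) is.na(d$c_matrix_uM) | d$c_matrix_uM <= 0,
    dilution_factor = function(d) !is.na(d$dilution_factor) &
      d$dilution_factor < 1))
}

#' Read a fraction-unbound reference CSV for dilution prediction
#'
#' Schema: `compound_id, matrix, fu_at_c1, c2_over_c1` -- the unbound
#' fraction measured at the undiluted matrix concentration and the relative
#' concentration to predict at (0.05 for a 20-fold dilution).
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_fu_reference_csv <- function(path) {
  df <- read_checked_csv(path, c("compound_id", "matrix", "fu_at_c1",
                                 "c2_over_c1"))
  validate_rows(df, path, list(
    fu_at_c1 = function(d) is.na(d$fu_at_c1) | d$fu_at_c1 <= 0 | d$fu_at_c1 > 1,
    c2_over_c1 = function(d) is.na(d$c2_over_c1) | d$c2_over_c1 <= 0 |
      d$c2_over_c1 > 1))
}

#' Read an equilibrium-distribution time-series CSV
#'
#' Schema: `compound_id, design, time_h, apical_conc_uM, basolateral_conc_uM,
#' replicate_id`. Replicates are averaged per compound, design and time.
#' Geometry and loading come from an optional JSON sidecar with fields
#' `apical_volume_ul`, `basolateral_volume_ul`, `apical_draw_ul`,
#' `basolateral_draw_ul`, `replace_volume`, `c0_apical`, `c0_basolateral`
#' (defaults: the 12-well 500/1000 uL, 40/80 uL design loaded at 1 uM,
#' basolateral load 0 for Uni-L and equal to apical for Bi-L).
#'
#' @param path CSV file path.
#' @param sidecar optional path to the JSON sidecar.
#' @return list of [chamber_timeseries()] objects, one per compound x design.
#' @export
read_timeseries_csv <- function(path, sidecar = NULL) {
  df <- read_checked_csv(path, c("compound_id", "design", "time_h",
                                 "apical_conc_uM", "basolateral_conc_uM"))
  validate_rows(df, path, list(
    design = function(d) !d$design %in% c("UniL", "BiL"),
    time_h = function(d) is.na(d$time_h) | d$time_h <= 0,
    apical_conc_uM = function(d) !is.na(d$apical_conc_uM) & d$apical_conc_uM < 0,
    basolateral_conc_uM = function(d) !is.na(d$basolateral_conc_uM) &
      d$basolateral_conc_uM < 0))
  meta <- list(apical_volume_ul = 500, basolateral_volume_ul = 1000,
               apical_draw_ul = 40, basolateral_draw_ul = 80,
               replace_volume = FALSE, c0_apical = 1, c0_basolateral = NA)
  if (!is.null(sidecar)) {
    user <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta[names(user)] <- user
  }
  if (nrow(df) == 0) return(list())
  groups <- split(df, list(df$compound_id, df$design), drop = TRUE)
  lapply(unname(groups), function(sub) {
    agg <- stats::aggregate(
      cbind(apical = sub$apical_conc_uM, basolateral = sub$basolateral_conc_uM),
      by = list(time_h = sub$time_h), FUN = mean)
    agg <- agg[order(agg$time_h), ]
    design <- sub$design[1]
    c0_b <- if (is.na(meta$c0_basolateral)) {
      if (design == "BiL") meta$c0_apical else 0
    } else meta$c0_basolateral
    chamber_timeseries(
      compound_id = sub$compound_id[1], design = design,
      times_h = agg$time_h, apical_conc = agg$apical,
      basolateral_conc = agg$basolateral,
      c0_apical = meta$c0_apical, c0_basolateral = c0_b,
      apical_volume_ul = meta$apical_volume_ul,
      basolateral_volume_ul = meta$basolateral_volume_ul,
      apical_draw_ul = meta$apical_draw_ul,
      basolateral_draw_ul = meta$basolateral_draw_ul,
      replace_volume = isTRUE(meta$replace_volume))
  })
}

#' Read an in vitro / in vivo reference CSV
#'
#' Schema: `compound_id, in_vivo_kp, in_vivo_kpuu, uptake_substrate,
#' low_recovery` plus optional pre-computed `in_vitro_kp`,
#' `in_vitro_kpuu` columns (the pipeline fills these from the
#' time-series stage when absent).
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_ivive_csv <- function(path) {
  df <- read_checked_csv(path, c("compound_id", "in_vivo_kp", "in_vivo_kpuu",
                                 "uptake_substrate"))
  if (is.null(df$low_recovery)) df$low_recovery <- FALSE
  validate_rows(df, path, list(
    in_vivo_kp = function(d) !is.na(d$in_vivo_kp) & d$in_vivo_kp <= 0,
    in_vivo_kpuu = function(d) !is.na(d$in_vivo_kpuu) & d$in_vivo_kpuu <= 0))
  df$uptake_substrate <- as.logical(df$uptake_substrate)
  df$low_recovery <- as.logical(df$low_recovery)
  df
}

#' Run the full in vitro brain-distribution pipeline
#'
#' Executes the four analysis stages in order on a directory of input CSVs
#' (the layout written by [generate_cohort()]): bidirectional transport
#' (Papp, efflux ratio, classifications), binding (measured and
#' dilution-predicted unbound fractions), equilibrium distribution
#' (Kp,brain, Kp,uu,brain, equilibrium and recovery QC) and in vitro / in
#' vivo concordance. Per-stage CSVs, a JSON concordance report and a run
#' log (seed, package version, every QC flag raised) are written to
#' `out_dir`.
#'
#' @param input_dir directory containing `transport.csv`, `dialysis.csv`,
#'   `fu_reference.csv`, `timeseries.csv` and (optionally) `ivive.csv` and
#'   `timeseries_meta.json`.
#' @param out_dir output directory (created if needed).
#' @param fu_source which unbound-fraction variant feeds the Kp,uu
#'   concordance: `"measured"`, `"predicted"` or `"both"` (default).
#' @param equilibrium_tol relative-change tolerance for
#'   [assess_equilibrium()].
#' @param exclude_uptake exclude uptake substrates from concordance.
#' @param seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with `papp`, `fu`, `kp`, `concordance` and
#'   `log`.
#' @export
run_pipeline <- function(input_dir, out_dir,
                         fu_source = c("both", "measured", "predicted"),
                         equilibrium_tol = 0.15,
                         exclude_uptake = TRUE,
                         seed = NULL) {
  fu_source <- match.arg(fu_source)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("kpuu pipeline, package version %s",
                         as.character(utils::packageVersion("kpuu"))),
                 sprintf("input_dir: %s", input_dir),
                 sprintf("seed: %s", if (is.null(seed)) "none" else seed),
                 sprintf("fu_source: %s; equilibrium_tol: %g",
                         fu_source, equilibrium_tol))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # stage 1: transport
  transport <- read_transport_csv(file.path(input_dir, "transport.csv"))
  papp <- if (nrow(transport)) papp_table(transport) else NULL
  if (!is.null(papp)) {
    for (i in which(papp$censored_AtoB | papp$censored_BtoA)) {
      note("QC transport: %s has censored (< LLOQ) leg(s)", papp$compound_id[i])
    }
    utils::write.csv(papp, file.path(out_dir, "papp_results.csv"),
                     row.names = FALSE)
  }

  # stage 2: binding
  dialysis <- read_dialysis_csv(file.path(input_dir, "dialysis.csv"))
  fu_ref_path <- file.path(input_dir, "fu_reference.csv")
  fu_ref <- if (file.exists(fu_ref_path)) read_fu_reference_csv(fu_ref_path)
    else NULL
  fu <- fu_table(dialysis, fu_ref)
  for (i in which(!is.na(fu$fu_measured_clamped) & fu$fu_measured_clamped)) {
    note("QC binding: %s/%s measured fu > 1 clamped to 1",
         fu$compound_id[i], fu$matrix[i])
  }
  utils::write.csv(fu, file.path(out_dir, "fu_results.csv"), row.names = FALSE)

  # long fu lookup for the distribution stage
  fu_long <- rbind(
    data.frame(compound_id = fu$compound_id, matrix = fu$matrix,
               fu = fu$fu_measured, source = "measured",
               stringsAsFactors = FALSE),
    data.frame(compound_id = fu$compound_id, matrix = fu$matrix,
               fu = fu$fu_predicted, source = "predicted",
               stringsAsFactors = FALSE))
  fu_long <- fu_long[!is.na(fu_long$fu), ]
  if (fu_source != "both") fu_long <- fu_long[fu_long$source == fu_source, ]

  # stage 3: equilibrium distribution
  sidecar <- file.path(input_dir, "timeseries_meta.json")
  ts_list <- read_timeseries_csv(file.path(input_dir, "timeseries.csv"),
                                 sidecar = if (file.exists(sidecar)) sidecar
                                 else NULL)
  kp <- if (length(ts_list)) kp_table(ts_list, fu_long, equilibrium_tol) else NULL
  if (!is.null(kp)) {
    for (i in which(!kp$equilibrium_reached)) {
      note("QC distribution: %s (%s) did not reach equilibrium",
           kp$compound_id[i], kp$design[i])
    }
    for (i in which(!kp$recovery_acceptable)) {
      note("QC distribution: %s (%s) recovery %.1f%% below floor",
           kp$compound_id[i], kp$design[i], kp$recovery_pct[i])
    }
    utils::write.csv(kp, file.path(out_dir, "kp_results.csv"),
                     row.names = FALSE)
  }

  # stage 4: concordance
  concordance <- NULL
  ivive_path <- file.path(input_dir, "ivive.csv")
  if (file.exists(ivive_path) && !is.null(kp)) {
    iv <- read_ivive_csv(ivive_path)
    uni <- kp[kp$design == "UniL", ]
    iv <- merge(iv, uni[, c("compound_id", "kp_brain", "kp_uu_measured_fu",
                            "kp_uu_predicted_fu", "recovery_acceptable")],
                by = "compound_id")
    iv$low_recovery <- iv$low_recovery | !iv$recovery_acceptable
    mk_pairs <- function(vitro, vivo) {
      data.frame(compound_id = iv$compound_id, in_vitro = vitro,
                 in_vivo = vivo, uptake_substrate = iv$uptake_substrate,
                 low_recovery = iv$low_recovery, stringsAsFactors = FALSE)
    }
    concordance <- list()
    # too few usable pairs (tiny cohorts, heavy exclusion) is a reportable
    # condition, not a pipeline failure
    try_report <- function(name, vitro, vivo) {
      r <- tryCatch(concordance_report(mk_pairs(vitro, vivo),
                                       exclude_uptake = exclude_uptake),
                    error = function(e) {
                      note("concordance %s skipped: %s", name,
                           conditionMessage(e))
                      NULL
                    })
      if (!is.null(r)) concordance[[name]] <<- r
    }
    if (any(!is.na(iv$in_vivo_kp))) {
      try_report("kp", iv$kp_brain, iv$in_vivo_kp)
    }
    if (fu_source %in% c("both", "measured") &&
        any(!is.na(iv$kp_uu_measured_fu))) {
      try_report("kpuu_measured_fu", iv$kp_uu_measured_fu, iv$in_vivo_kpuu)
    }
    if (fu_source %in% c("both", "predicted") &&
        any(!is.na(iv$kp_uu_predicted_fu))) {
      try_report("kpuu_predicted_fu", iv$kp_uu_predicted_fu, iv$in_vivo_kpuu)
    }
    report <- lapply(concordance, function(r) {
      list(n_included = r$n_included,
           regression_primary = r$regression_primary,
           regression_secondary = r$regression_secondary,
           twofold_fraction = r$twofold_fraction,
           twofold_pct = r$twofold_pct,
           category_agreement = r$category_agreement,
           category_agreement_pct = r$category_agreement_pct,
           confusion = as.data.frame(r$confusion),
           per_compound = r$per_compound,
           exclusions = r$exclusions)
    })
    jsonlite::write_json(report, file.path(out_dir, "concordance.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    for (r in concordance) {
      if (nrow(r$exclusions)) {
        note("concordance: excluded %s",
             paste(r$exclusions$compound_id, "(", r$exclusions$reason, ")",
                   collapse = ", "))
      }
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(papp = papp, fu = fu, kp = kp, concordance = concordance,
                 log = log_lines))
}
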