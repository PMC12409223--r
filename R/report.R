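# irradiation time of one field: last beam-on sample minus first (ms)
irradiation_time_ms <- function(log) {
  inc <- monitor_increments(log)
  on <- which(inc > 0)
  if (length(on) == 0) return(0)
  log$samples$t_ms[on[length(on)]] - log$samples$t_ms[max(on[1] - 1L, 1L)]
}

# summary statistics of a dose-rate grid over its valid mask
rate_summary <- function(rg) {
  v <- rg$values[rg$valid_mask]
  list(min_gy_s = min(v), mean_gy_s = mean(v), max_gy_s = max(v),
       n_valid_voxels = sum(rg$valid_mask))
}

#' Assemble a treatment delivery report
#'
#' The report is split into three parts following the trial's blinding
#' design: part 1 (shareable before unblinding) carries patient/field
#' metadata, the 2D-field dose metrics and the QA decision statuses;
#' part 2 (restricted) carries everything dose-rate- and beam-current-
#' related (dose-rate map statistics, irradiation times, measured point
#' dose rates, log-file references, the delivery-arm label); part 3 carries
#' the raw QA results.  With `blinded = TRUE` the restricted parts are
#' omitted by construction — not merely hidden — so the serialized output
#' contains no dose-rate value, no beam-current value and no arm label.
#'
#' 3D DVH metrics (V95, D98, ...) require patient CT data and are reported
#' as "not computed"; the 2D-field min/mean/max within the 90% isodose
#' stand in for them.
#'
#' @param plan A [simple_plan()].
#' @param decisions Named list of `qa_decision` objects (e.g. `psqa`,
#'   `dqa`).
#' @param dose_map Delivered/reconstructed [dose_grid()].
#' @param dose_rate_maps Named list of [dose_rate_grid()]s (e.g. `pbs`,
#'   `dose_averaged`).
#' @param logs List of [delivery_log()]s (or file paths under `log_files`).
#' @param point_dose_rates Numeric vector of measured point dose rates,
#'   Gy/s.
#' @param patient_meta Named list of pass-through metadata strings
#'   (veterinary/anesthesia fields are recorded, never computed).
#' @param blinded Logical; omit the restricted parts.
#' @return Object of class `treatment_report`.
#' @export
build_report <- function(plan, decisions = list(), dose_map = NULL,
                         dose_rate_maps = list(), logs = list(),
                         point_dose_rates = NULL, patient_meta = list(),
                         blinded = FALSE) {
  part1 <- list(
    field_id = plan$field_id,
    patient = patient_meta,
    setup = list(gantry_angle_deg = plan$gantry_angle,
                 couch_angle_deg = plan$couch_angle),
    prescription = list(fractions = plan$fractions,
                        fraction_dose_gy = plan$fraction_dose,
                        total_dose_gy = plan_total_dose(plan)),
    dvh_metrics = "not computed (3D patient data out of scope)",
    qa_status = lapply(decisions, function(d) d$status)
  )
  if (!is.null(dose_map)) {
    mask <- dose_map$values >= 0.9 * max(dose_map$values)
    ctr <- plan_center(plan)
    part1$field_dose <- list(
      min_gy = min(dose_map$values[mask]),
      mean_gy = mean(dose_map$values[mask]),
      max_gy = max(dose_map$values[mask]),
      reference_point_gy = dose_at(dose_map, ctr[1], ctr[2]),
      isodose_level = 0.9
    )
  }
  if (blinded) {
    if (length(part1) == 0) stop("blinded report requested with no shareable content")
    return(structure(list(part1 = part1, blinded = TRUE),
                     class = "treatment_report"))
  }
  part2 <- list(
    arm = plan$arm,
    intensity_mu_s = plan$intensity,
    dose_rate_maps = lapply(dose_rate_maps, rate_summary),
    irradiation_time_ms = lapply(logs, function(l) {
      if (inherits(l, "delivery_log")) irradiation_time_ms(l) else NA_real_
    }),
    point_dose_rates_gy_s = point_dose_rates,
    log_files = vapply(logs, function(l) {
      if (inherits(l, "delivery_log")) l$field_id else as.character(l)
    }, character(1))
  )
  part3 <- lapply(decisions, function(d) {
    list(kind = d$kind, status = d$status,
         central_dose_ratio = d$central_dose$ratio,
         scaling_factor = d$scaling_factor,
         mean_deviation_pct = d$gamma$mean_dev,
         gamma_pass_fraction_pct = d$gamma$pass_fraction,
         five_spot = if (!is.null(d$five_spot)) d$five_spot$spots else NULL,
         notes = d$notes)
  })
  structure(list(part1 = part1, part2 = part2, part3 = part3,
                 blinded = FALSE),
            class = "treatment_report")
}

#' Serialize a treatment report to JSON (and optionally Markdown)
#'
#' @param report A [build_report()] result.
#' @param path Output JSON path.
#' @param md_path Optional Markdown rendering path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, md_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  if (!is.null(md_path)) writeLines(render_report_md(report), md_path)
  invisible(path)
}

render_report_md <- function(report) {
  p1 <- report$part1
  out <- c(sprintf("# Delivery report — field %s", p1$field_id),
           if (report$blinded) "*Blinded: dose-rate and beam-current information withheld until unblinding.*",
           "", "## Part 1 — Dosimetric evaluation (shareable)",
           sprintf("- Gantry %g deg, couch %g deg",
                   p1$setup$gantry_angle_deg, p1$setup$couch_angle_deg),
           sprintf("- Prescription: %d x %g Gy = %g Gy",
                   p1$prescription$fractions, p1$prescription$fraction_dose_gy,
                   p1$prescription$total_dose_gy),
           sprintf("- DVH metrics: %s", p1$dvh_metrics))
  if (!is.null(p1$field_dose)) {
    fd <- p1$field_dose
    out <- c(out, sprintf(
      "- Field dose in 90%% isodose: min %.3f / mean %.3f / max %.3f Gy; reference point %.3f Gy",
      fd$min_gy, fd$mean_gy, fd$max_gy, fd$reference_point_gy))
  }
  for (n in names(p1$qa_status)) {
    out <- c(out, sprintf("- %s status: %s", toupper(n), p1$qa_status[[n]]))
  }
  if (!report$blinded) {
    p2 <- report$part2
    out <- c(out, "", "## Part 2 — Dose rate (restricted)",
             sprintf("- Arm: %s, intensity %g MU/s", p2$arm, p2$intensity_mu_s))
    for (n in names(p2$dose_rate_maps)) {
      rs <- p2$dose_rate_maps[[n]]
      out <- c(out, sprintf("- %s dose rate: min %.2f / mean %.2f / max %.2f Gy/s",
                            n, rs$min_gy_s, rs$mean_gy_s, rs$max_gy_s))
    }
    if (length(p2$irradiation_time_ms)) {
      out <- c(out, sprintf("- Irradiation time per field: %s ms",
                            paste(sprintf("%.1f", unlist(p2$irradiation_time_ms)),
                                  collapse = ", ")))
    }
    if (!is.null(p2$point_dose_rates_gy_s)) {
      out <- c(out, sprintf("- Measured point dose rates: %s Gy/s",
                            paste(sprintf("%.1f", p2$point_dose_rates_gy_s),
                                  collapse = ", ")))
    }
    out <- c(out, "", "## Part 3 — QA results")
    for (n in names(report$part3)) {
      d <- report$part3[[n]]
      out <- c(out, sprintf(
        "- %s: %s (central ratio %.4f, mean dev %.2f%%, gamma pass %.1f%%)",
        d$kind, d$status, d$central_dose_ratio, d$mean_deviation_pct,
        d$gamma_pass_fraction_pct))
    }
  }
  out
}
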