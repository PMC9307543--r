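#' Simulated phantom-study configuration
#'
#' Describes one complete simulated accuracy study: which phantoms, how
#' many participants, which sutures each participant delineates (the
#' sagittal suture is shown only as a mid-line guide and is excluded by
#' default), the noise channels, and the resample step.
#'
#' The study replays the causal chain of a tracked AR navigation
#' experiment: an operator aligns the CT model to the physical phantom by
#' digitizing six anatomical landmarks with the electromagnetically tracked
#' pointer (noise `emts_sigma`); the imperfect alignment displaces the
#' displayed sutures; the participant traces the displayed curve with
#' smooth hand noise; finally an independent optical tracker digitizes the
#' drawn curves and the fiducial markers (noise `ots_sigma`) to map them
#' back into CT space for scoring with the area-over-length distance.
#'
#' @param phantoms list of `phantom_model` objects; defaults to an adult-
#'   like phantom with 10 fiducials (`SK1`) and a child-like phantom with 8
#'   (`SK2`).
#' @param participants number of simulated participants (>= 1); 12 by
#'   default.
#' @param sutures_to_delineate suture labels scored per phantom.
#' @param emts_sigma per-axis digitization noise of the electromagnetic
#'   pointer, mm.
#' @param ots_sigma per-axis digitization noise of the optical evaluation
#'   tracker, mm.
#' @param delineation a [noise_spec()] for the hand-drawing channel.
#' @param step resample step in mm (default 0.25).
#' @param seed master integer seed; all per-participant streams derive from
#'   it.
#' @return A `study_config` list.
#' @export
study_config <- function(phantoms = NULL,
                         participants = 12,
                         sutures_to_delineate = c("coronal", "virtual_1",
                                                  "virtual_2", "virtual_3",
                                                  "lambdoid"),
                         emts_sigma = 0.35,
                         ots_sigma = 0.4,
                         delineation = noise_spec(delineation_sigma = 1.0,
                                                  delineation_correlation_length = 15),
                         step = 0.25,
                         seed = 1L) {
  if (participants < 1L) {
    stop("invalid parameter: participants must be >= 1", call. = FALSE)
  }
  if (step <= 0) {
    stop("invalid parameter: step must be > 0", call. = FALSE)
  }
  if (is.null(phantoms)) {
    phantoms <- list(
      make_phantom(phantom_spec(n_fiducials = 10), seed = derive_seed(seed, "SK1"),
                   id = "SK1"),
      make_phantom(phantom_spec(n_fiducials = 8), seed = derive_seed(seed, "SK2"),
                   id = "SK2"))
  }
  for (ph in phantoms) {
    stopifnot(inherits(ph, "phantom_model"))
    missing_sut <- setdiff(sutures_to_delineate, names(ph$sutures))
    if (length(missing_sut) > 0L) {
      stop("phantom ", ph$id, " lacks suture(s): ",
           paste(missing_sut, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(phantoms = phantoms,
                 participants = as.integer(participants),
                 sutures_to_delineate = sutures_to_delineate,
                 emts_sigma = emts_sigma,
                 ots_sigma = ots_sigma,
                 delineation = delineation,
                 step = step,
                 seed = as.integer(seed)),
            class = "study_config")
}

# True lab geometry for one phantom: a frame graph carrying the phantom
# placement (CT -> PATIENT_SENSOR) and the two tracker poses. Deterministic
# per phantom id so that simulated digitizations are reproducible.
lab_frame_graph <- function(phantom) {
  g <- frame_graph()
  g <- add_frame_edge(g, "CT", "PATIENT_SENSOR", phantom$patient_sensor_pose)
  g <- add_frame_edge(g, "PATIENT_SENSOR", "EMTS",
                      random_rigid_transform(derive_seed(phantom$seed, "emts_pose"),
                                             translation_sd = 200))
  g <- add_frame_edge(g, "PATIENT_SENSOR", "OTS",
                      random_rigid_transform(derive_seed(phantom$seed, "ots_pose"),
                                             translation_sd = 500))
  g
}

#' Run a simulated delineation study
#'
#' Executes the full protocol of [study_config()] and returns a
#' `study_report`: one delineation record per (participant, phantom,
#' delineated suture) plus per-participant registration errors. A suture
#' pair with no usable overlap after noise is recorded as missing (with a
#' warning), not an error.
#'
#' @param config a `study_config`.
#' @param quiet suppress per-stage progress messages.
#' @return A `study_report` list with data frames `records` (columns
#'   `participant`, `phantom`, `suture`, `S_A_mm2`, `D_L_mm`, `d_mm`,
#'   `overlap_fraction`), `registration` (`participant`, `phantom`,
#'   `emts_fre_mm`, `emts_tre_mm`, `ots_fre_mm`), the grouped `summary`
#'   from [summarize_report()], a Table-2-shaped `registration_summary`,
#'   the `config`, and `n_missing`.
#' @export
run_simulated_study <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  records <- list()
  registration <- list()
  n_missing <- 0L
  for (phantom in config$phantoms) {
    graph <- lab_frame_graph(phantom)
    t_ct_emts <- resolve_frame_path(graph, "CT", "EMTS")
    t_ct_ots <- resolve_frame_path(graph, "CT", "OTS")
    surface <- phantom$surface
    lm <- phantom$anatomical_landmarks
    fid <- phantom$fiducials
    lm_emts_true <- labeled_points(lm$label,
                                   transform_points(t_ct_emts, point_matrix(lm)))
    fid_emts_true <- labeled_points(fid$label,
                                    transform_points(t_ct_emts, point_matrix(fid)))
    fid_ots_true <- labeled_points(fid$label,
                                   transform_points(t_ct_ots, point_matrix(fid)))
    if (!quiet) {
      message("phantom ", phantom$id, ": ", config$participants,
              " participants x ", length(config$sutures_to_delineate),
              " sutures")
    }
    for (p in seq_len(config$participants)) {
      sd_ <- function(stage) derive_seed(config$seed, phantom$id, p, stage)

      # (1) experiment registration: landmarks digitized with the EM pointer
      lm_meas <- perturb_points(lm_emts_true, config$emts_sigma,
                                sd_("emts_landmarks"))
      reg_exp <- register_paired_points(lm, lm_meas)
      tre <- target_registration_error(reg_exp$transform, fid, fid_emts_true)

      # (2) misalignment of the AR overlay, expressed in CT space
      misalign <- compose(reg_exp$transform, invert(t_ct_emts))

      # (4) evaluation registration via the optical tracker fiducials
      fid_meas <- perturb_points(fid_ots_true, config$ots_sigma,
                                 sd_("ots_fiducials"))
      reg_eval <- register_paired_points(fid, fid_meas)
      eval_back <- invert(reg_eval$transform)

      registration[[length(registration) + 1L]] <- data.frame(
        participant = p, phantom = phantom$id,
        emts_fre_mm = reg_exp$fre, emts_tre_mm = tre$tre,
        ots_fre_mm = reg_eval$fre)

      for (sut in config$sutures_to_delineate) {
        planned <- phantom$sutures[[sut]]
        displayed <- polyline3(transform_points(misalign,
                                                as_point_matrix(planned)),
                               label = sut)
        # (3) the participant traces the displayed overlay on the skull
        drawn_ct <- simulate_drawn_suture(surface, displayed,
                                          config$delineation,
                                          sd_(paste0("draw_", sut)),
                                          step = config$step)
        # (5) the drawn curve is digitized by the OTS and mapped back to CT
        drawn_ots <- transform_points(t_ct_ots, as_point_matrix(drawn_ct))
        if (config$ots_sigma > 0) {
          noise <- with_seed(sd_(paste0("digitize_", sut)),
                             matrix(stats::rnorm(length(drawn_ots),
                                                 sd = config$ots_sigma),
                                    ncol = 3L))
          drawn_ots <- drawn_ots + noise
        }
        drawn_back <- polyline3(transform_points(eval_back, drawn_ots),
                                label = sut)
        # (6) score against the planned suture
        err <- tryCatch(
          delineation_distance(surface, planned, drawn_back,
                               step = config$step),
          error = function(e) e)
        if (inherits(err, "error")) {
          warning("participant ", p, ", phantom ", phantom$id, ", suture ",
                  sut, ": ", conditionMessage(err), call. = FALSE)
          n_missing <- n_missing + 1L
          next
        }
        records[[length(records) + 1L]] <- data.frame(
          participant = p, phantom = phantom$id, suture = sut,
          S_A_mm2 = err$spanned_area, D_L_mm = err$overlap_length,
          d_mm = err$distance, overlap_fraction = err$overlap_fraction)
      }
    }
  }
  records <- do.call(rbind, records)
  registration <- do.call(rbind, registration)
  structure(list(records = records,
                 registration = registration,
                 summary = summarize_report(records),
                 registration_summary = summarize_registration(registration),
                 config = config,
                 n_missing = n_missing),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", nrow(x$records), "delineation records (",
      x$n_missing, "missing ),", length(x$config$phantoms), "phantoms,",
      x$config$participants, "participants\n\n")
  print(x$summary, digits = 3)
  invisible(x)
}

suture_class <- function(suture) {
  ifelse(startsWith(suture, "virtual"), "Virtual",
         paste0(toupper(substring(suture, 1, 1)), substring(suture, 2)))
}

#' Summarize delineation records by phantom and suture class
#'
#' Groups the per-record distances by phantom and suture class — Coronal,
#' Virtual (the three virtual sutures pooled), Lambdoid — plus an `All`
#' row per phantom, reporting the mean and sample standard deviation
#' (n - 1 denominator) of `d`. A single-record group gets `sd = 0` and
#' `sd_defined = FALSE`.
#'
#' @param records the `records` data frame of a `study_report`.
#' @return A data frame with columns `phantom`, `class`, `n`, `mean_d_mm`,
#'   `sd_d_mm`, `sd_defined`.
#' @export
summarize_report <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("degenerate input: no delineation records", call. = FALSE)
  }
  records$class <- suture_class(records$suture)
  groups <- rbind(
    unique(records[, c("phantom", "class")]),
    data.frame(phantom = unique(records$phantom), class = "All"))
  out <- lapply(seq_len(nrow(groups)), function(i) {
    ph <- groups$phantom[i]; cl <- groups$class[i]
    d <- records$d_mm[records$phantom == ph &
                        (cl == "All" | records$class == cl)]
    data.frame(phantom = ph, class = cl, n = length(d),
               mean_d_mm = mean(d),
               sd_d_mm = if (length(d) > 1L) stats::sd(d) else 0,
               sd_defined = length(d) > 1L)
  })
  out <- do.call(rbind, out)
  class_order <- c("Coronal", "Virtual", "Lambdoid", "All")
  out <- out[order(out$phantom,
                   match(out$class, class_order, nomatch = 99L)), ]
  rownames(out) <- NULL
  out
}

# Per-phantom mean +/- sd of the registration errors across participants.
summarize_registration <- function(registration) {
  out <- lapply(split(registration, registration$phantom), function(df) {
    data.frame(phantom = df$phantom[1],
               emts_fre_mean = mean(df$emts_fre_mm),
               emts_fre_sd = stats::sd(df$emts_fre_mm),
               emts_tre_mean = mean(df$emts_tre_mm),
               emts_tre_sd = stats::sd(df$emts_tre_mm),
               ots_fre_mean = mean(df$ots_fre_mm),
               ots_fre_sd = stats::sd(df$ots_fre_mm))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a study report to disk
#'
#' Writes `records.csv`, `registration.csv`, `summary.csv`,
#' `registration_summary.csv` and a plain-text `run_manifest.txt` (config,
#' master seed, record/missing counts, package version). The CSV files
#' round-trip through [read_study_records()].
#'
#' @param report a `study_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$records, file.path(dir, "records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$registration, file.path(dir, "registration.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$registration_summary,
                   file.path(dir, "registration_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- report$config
  manifest <- file.path(dir, "run_manifest.txt")
  writeLines(c(
    paste("package_version:",
          as.character(utils::packageVersion("suturenav"))),
    paste("master_seed:", cfg$seed),
    paste("participants:", cfg$participants),
    paste("phantoms:", paste(vapply(cfg$phantoms, `[[`, "", "id"),
                             collapse = " ")),
    paste("sutures_to_delineate:",
          paste(cfg$sutures_to_delineate, collapse = " ")),
    paste("emts_sigma_mm:", cfg$emts_sigma),
    paste("ots_sigma_mm:", cfg$ots_sigma),
    paste("delineation_sigma_mm:", cfg$delineation$delineation_sigma),
    paste("delineation_correlation_mm:",
          cfg$delineation$delineation_correlation_length),
    paste("systematic_offset_mm:", cfg$delineation$systematic_offset),
    paste("step_mm:", cfg$step),
    paste("records:", nrow(report$records)),
    paste("missing:", report$n_missing)),
    manifest)
  invisible(manifest)
}

#' @rdname write_study_report
#' @param path path to a `records.csv` written by [write_study_report()].
#' @export
read_study_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Score externally supplied drawn curves
#'
#' The evaluation-only entry point: given a skull mesh and matched lists of
#' planned and drawn curves (e.g. read from files), scores every pair with
#' [delineation_distance()].
#'
#' @param surface a `tri_surface`.
#' @param planned,drawn equally long lists of `polyline3` curves; pairs are
#'   matched by position (and labels are reported when present).
#' @param step resample step in mm.
#' @return A data frame with one row per pair (same columns as the
#'   `records` of a study, minus participant/phantom).
#' @export
evaluate_delineations <- function(surface, planned, drawn, step = 0.25) {
  if (length(planned) != length(drawn)) {
    stop("planned and drawn curve lists must have equal length",
         call. = FALSE)
  }
  out <- lapply(seq_along(planned), function(i) {
    e <- delineation_distance(surface, planned[[i]], drawn[[i]], step = step)
    data.frame(reference_label = e$reference_label %||% as.character(i),
               drawn_label = e$drawn_label %||% as.character(i),
               S_A_mm2 = e$spanned_area, D_L_mm = e$overlap_length,
               d_mm = e$distance, overlap_fraction = e$overlap_fraction)
  })
  do.call(rbind, out)
}
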