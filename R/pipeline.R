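# Protocol orchestration: generate (or load) the phantom stacks for each
# named condition, run every configured measurement, and emit report tables
# plus curve exports. Conditions are opaque labels -- the runner never claims
# to emulate any particular reconstruction algorithm.

#' Define a protocol condition
#'
#' A named scan condition binding the three phantom modules. By default the
#' three module stacks are synthesized from the Catphan-style presets with
#' the given noise and blur; alternatively `stacks` may name raw + YAML
#' stack paths (see [write_stack()]) per module.
#'
#' @param name unique condition label.
#' @param sigma_hu noise SD in HU.
#' @param blur_sigma_mm Gaussian edge blur in mm.
#' @param texture noise texture (see [noise_model()]).
#' @param correlation_length_mm for `"gaussian_lowpass"`.
#' @param target_curve for `"target_nps"`.
#' @param n_slices slices per stack.
#' @param grid a [grid_spec()].
#' @param body_diameter_mm phantom body diameter (mm).
#' @param insert_circle_radius_mm sensitometry insert circle radius (mm).
#' @param low_contrast_radius_mm low-contrast circle radius (mm).
#' @param stacks optional named list (`uniformity`, `sensitometry`,
#'   `low_contrast`) of stack path prefixes to load instead of simulating.
#' @return a `protocol_condition`.
#' @export
protocol_condition <- function(name, sigma_hu = 15.4, blur_sigma_mm = 0.3,
                               texture = "white",
                               correlation_length_mm = NULL,
                               target_curve = NULL,
                               n_slices = 50L, grid = grid_spec(),
                               body_diameter_mm = 200,
                               insert_circle_radius_mm = 58.5,
                               low_contrast_radius_mm = 50,
                               stacks = NULL) {
  structure(
    list(name = as.character(name), sigma_hu = sigma_hu,
         blur_sigma_mm = blur_sigma_mm, texture = texture,
         correlation_length_mm = correlation_length_mm,
         target_curve = target_curve, n_slices = as.integer(n_slices),
         grid = grid, body_diameter_mm = body_diameter_mm,
         insert_circle_radius_mm = insert_circle_radius_mm,
         low_contrast_radius_mm = low_contrast_radius_mm,
         stacks = stacks),
    class = "protocol_condition"
  )
}

#' Define a protocol configuration
#'
#' @param conditions list of [protocol_condition()] objects with unique
#'   names.
#' @param output_dir directory for the report tables and curve exports.
#' @param seed master seed; per-condition, per-module seeds are derived from
#'   it deterministically.
#' @param reference name of the reference condition for the noise ratio
#'   table (default: the first condition).
#' @param analyses toggles: `ct_number`, `apc`, `noise`, `nps`, `mtf`,
#'   `detectability` (all TRUE by default).
#' @param mtf_replicates replicate stacks per condition for the MTF SE
#'   (default 10).
#' @param noise_roi_size ROI side in pixels for the noise / NPS
#'   measurements; `NULL` (default) uses 256 capped to the square inscribed
#'   in the phantom body so the ROI never touches the body edge.
#' @param nps_detrend detrend mode for [compute_nps()].
#' @param detect_threshold decision SNR of the detectability surrogate.
#' @param ratings_csv optional CSV of two-reader ratings; when given, the
#'   report includes the Cohen's kappa of the readers.
#' @return a `protocol_config`.
#' @export
protocol_config <- function(conditions, output_dir, seed = 1L,
                            reference = NULL,
                            analyses = list(),
                            mtf_replicates = 10L,
                            noise_roi_size = NULL,
                            nps_detrend = "mean",
                            detect_threshold = 5.0,
                            ratings_csv = NULL) {
  if (inherits(conditions, "protocol_condition")) {
    conditions <- list(conditions)
  }
  nm <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("condition names must be unique", call. = FALSE)
  }
  toggles <- utils::modifyList(
    list(ct_number = TRUE, apc = TRUE, noise = TRUE, nps = TRUE,
         mtf = TRUE, detectability = TRUE),
    analyses)
  structure(
    list(conditions = stats::setNames(conditions, nm),
         output_dir = output_dir, seed = as.integer(seed),
         reference = reference %||% nm[1],
         analyses = toggles,
         mtf_replicates = as.integer(mtf_replicates),
         noise_roi_size = noise_roi_size,
         nps_detrend = nps_detrend,
         detect_threshold = detect_threshold,
         ratings_csv = ratings_csv),
    class = "protocol_config"
  )
}

#' Read a protocol configuration from YAML
#'
#' Top-level fields mirror [protocol_config()]; each entry under
#' `conditions:` mirrors [protocol_condition()], with `grid:` given as
#' `matrix_size` / `field_of_view` / `slice_thickness`.
#'
#' @param path YAML file.
#' @return a `protocol_config`.
#' @export
read_protocol_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$conditions) || !length(x$conditions)) {
    stop(sprintf("'%s' defines no conditions", path), call. = FALSE)
  }
  conds <- lapply(x$conditions, function(cc) {
    g <- cc$grid %||% list()
    protocol_condition(
      name = cc$name,
      sigma_hu = cc$sigma_hu %||% 15.4,
      blur_sigma_mm = cc$blur_sigma_mm %||% 0.3,
      texture = cc$texture %||% "white",
      correlation_length_mm = cc$correlation_length_mm,
      target_curve = if (!is.null(cc$target_curve)) {
        as.data.frame(cc$target_curve)
      },
      n_slices = cc$n_slices %||% 50L,
      grid = grid_spec(g$matrix_size %||% 1024L,
                       g$field_of_view %||% 400,
                       g$slice_thickness %||% 0.5),
      body_diameter_mm = cc$body_diameter_mm %||% 200,
      insert_circle_radius_mm = cc$insert_circle_radius_mm %||% 58.5,
      low_contrast_radius_mm = cc$low_contrast_radius_mm %||% 50,
      stacks = cc$stacks
    )
  })
  protocol_config(conds,
                  output_dir = x$output_dir %||% ".",
                  seed = x$seed %||% 1L,
                  reference = x$reference,
                  analyses = x$analyses %||% list(),
                  mtf_replicates = x$mtf_replicates %||% 10L,
                  noise_roi_size = x$noise_roi_size,
                  nps_detrend = x$nps_detrend %||% "mean",
                  detect_threshold = x$detect_threshold %||% 5.0,
                  ratings_csv = x$ratings_csv)
}

# deterministic sub-seed; kept well below 2^31
.sub_seed <- function(seed, i, j) {
  (seed * 1009L + i * 131L + j * 17L) %% 2000000011L
}

# build the phantom spec for one module of one condition
.condition_spec <- function(cond, module, seed) {
  nm <- noise_model(cond$sigma_hu, cond$texture,
                    correlation_length_mm = cond$correlation_length_mm,
                    target_curve = cond$target_curve, seed = seed)
  catphan_presets(module, grid = cond$grid, noise = nm,
                  blur_sigma_mm = cond$blur_sigma_mm,
                  n_slices = cond$n_slices,
                  insert_circle_radius_mm = cond$insert_circle_radius_mm,
                  low_contrast_radius_mm = cond$low_contrast_radius_mm,
                  body_diameter_mm = cond$body_diameter_mm)
}

.condition_stack <- function(cond, module, seed) {
  if (!is.null(cond$stacks) && !is.null(cond$stacks[[module]])) {
    return(load_stack(cond$stacks[[module]]))
  }
  generate_stack(.condition_spec(cond, module, seed))
}

.write_csv <- function(d, dir, file) {
  path <- file.path(dir, file)
  utils::write.csv(d, path, row.names = FALSE)
  path
}

#' Run a full measurement protocol
#'
#' For every condition, generates (or loads) the uniformity, sensitometry
#' and low-contrast module stacks and runs the configured measurements:
#' noise magnitude and NPS (with its unit-area normalization) on the
#' uniformity module; insert CT numbers, attenuation profile curves and the
#' circular-edge MTF on the sensitometry module; the model-observer
#' detectability surrogate on the low-contrast geometry. Results are written
#' as CSV tables plus a human-readable summary whose provenance block lists
#' every analysis default actually used. A failing stage is recorded per
#' condition without aborting the others; every configured analysis produces
#' either a result or an explicit skip record.
#'
#' @param config a [protocol_config()].
#' @return a `study_report` (tables as data frames, file paths, skip
#'   records), invisibly writable via its `files` element.
#' @export
run_protocol <- function(config) {
  if (!inherits(config, "protocol_config")) {
    stop("`config` must be a protocol_config", call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analyses
  ct_rows <- list(); noise_rows <- list(); mtf_rows <- list()
  detect_rows <- list(); skip <- list(); files <- character()
  noise_by_cond <- numeric()

  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[[i]]
    step <- function(label, expr) {
      tryCatch(expr, error = function(e) {
        skip[[length(skip) + 1L]] <<- data.frame(
          condition = cond$name, analysis = label,
          reason = conditionMessage(e))
        NULL
      })
    }

    # ROI capped to the square inscribed in the body, with a 3-mm margin
    # per side keeping the (possibly blurred) body edge out of the ROI
    roi_px <- config$noise_roi_size %||%
      min(256L, as.integer((cond$body_diameter_mm / sqrt(2) - 6) /
                             cond$grid$pixel_spacing))
    uni <- if (an$noise || an$nps) {
      step("uniformity stack",
           .condition_stack(cond, "uniformity", .sub_seed(config$seed, i, 1L)))
    }
    if (an$noise) {
      nr <- step("noise", noise_magnitude(uni, roi_size = roi_px))
      if (!is.null(nr)) {
        noise_by_cond[cond$name] <- nr$mean_sd_hu
        noise_rows[[cond$name]] <- data.frame(
          condition = cond$name, mean_sd_hu = nr$mean_sd_hu,
          se_hu = nr$se_hu, n_slices = nr$n_slices)
      }
    }
    if (an$nps) {
      sp <- step("nps", compute_nps(uni, roi_size = roi_px,
                                    detrend = config$nps_detrend))
      if (!is.null(sp)) {
        files <- c(files, .write_csv(as.data.frame(sp), config$output_dir,
                                     sprintf("nps_%s.csv", cond$name)))
      }
    } else {
      sp <- NULL
    }
    rm(uni)

    if (an$ct_number || an$apc || an$mtf) {
      sens_spec <- .condition_spec(cond, "sensitometry",
                                   .sub_seed(config$seed, i, 2L))
      sens <- if (an$ct_number || an$apc) {
        step("sensitometry stack", generate_stack(sens_spec))
      }
      ins <- sens_spec$inserts
      names(ins) <- vapply(ins, `[[`, character(1), "label")
      if (!is.null(sens)) {
        for (lbl in c("high", "moderate", "low")) {
          if (an$ct_number) {
            r <- step(paste("ct_number", lbl),
                      measure_ct_number(sens, ins[[lbl]]$center,
                                        insert_label = lbl))
            if (!is.null(r)) {
              ct_rows[[length(ct_rows) + 1L]] <- data.frame(
                condition = cond$name, insert = lbl,
                nominal_hu = ins[[lbl]]$contrast_hu,
                mean_hu = r$mean_hu, sd_hu = r$sd_hu)
            }
          }
          if (an$apc) {
            a <- step(paste("apc", lbl),
                      measure_apc(sens, ins[[lbl]]$center,
                                  insert_label = lbl))
            if (!is.null(a)) {
              files <- c(files, .write_csv(
                as.data.frame(a), config$output_dir,
                sprintf("apc_%s_%s.csv", cond$name, lbl)))
            }
          }
        }
      }
      rm(sens)
      if (an$mtf) {
        m <- step("mtf", {
          reps <- lapply(seq_len(config$mtf_replicates), function(r) {
            generate_stack(.condition_spec(cond, "sensitometry",
                                           .sub_seed(config$seed, i,
                                                     10L + r)))
          })
          mtf_with_replicates(reps, radius = ins[["mtf"]]$diameter / 2,
                              center = ins[["mtf"]]$center)
        })
        if (!is.null(m)) {
          mtf_rows[[cond$name]] <- data.frame(
            condition = cond$name, f50 = m$f50, f50_se = m$f50_se,
            f10 = m$f10, f10_se = m$f10_se,
            n_replicates = config$mtf_replicates)
          files <- c(files, .write_csv(as.data.frame(m), config$output_dir,
                                       sprintf("mtf_%s.csv", cond$name)))
        }
      }
    }

    if (an$detectability) {
      d <- step("detectability", {
        lc <- .condition_spec(cond, "low_contrast",
                              .sub_seed(config$seed, i, 3L))
        contrast <- lc$inserts[[1]]$contrast_hu
        sd_use <- noise_by_cond[cond$name]
        if (!length(sd_use) || is.na(sd_use)) sd_use <- cond$sigma_hu
        min_detectable_diameter(
          contrast_hu = contrast, noise_sd_hu = sd_use,
          pixel_spacing = cond$grid$pixel_spacing,
          threshold = config$detect_threshold, nps = sp)
      })
      if (!is.null(d)) {
        detect_rows[[cond$name]] <- data.frame(
          condition = cond$name,
          min_detectable_diameter_mm = d$min_detectable_diameter,
          threshold = d$threshold)
      }
    }
  }

  bindr <- function(rows) {
    if (length(rows)) do.call(rbind, unname(rows)) else NULL
  }
  ct_tab <- bindr(ct_rows)
  noise_tab <- bindr(noise_rows)
  mtf_tab <- bindr(mtf_rows)
  detect_tab <- bindr(detect_rows)
  skip_tab <- bindr(skip)

  ratio_tab <- NULL
  if (!is.null(noise_tab) && config$reference %in% noise_tab$condition &&
      noise_tab$mean_sd_hu[noise_tab$condition == config$reference] > 0) {
    ref <- noise_tab$mean_sd_hu[noise_tab$condition == config$reference]
    ratio_tab <- do.call(rbind, lapply(seq_len(nrow(noise_tab)), function(k) {
      dr <- dose_ratio_percent(noise_tab$mean_sd_hu[k], ref)
      data.frame(condition = noise_tab$condition[k],
                 percent_vs_reference = dr$percent,
                 reference = config$reference)
    }))
  } else if (!is.null(noise_tab)) {
    skip_tab <- rbind(skip_tab, data.frame(
      condition = "(all)", analysis = "noise ratio",
      reason = "reference condition missing or has zero noise"))
  }

  kappa_res <- NULL
  if (!is.null(config$ratings_csv)) {
    kappa_res <- tryCatch(
      cohens_kappa(read_rating_table(config$ratings_csv)),
      error = function(e) {
        skip_tab <<- rbind(skip_tab, data.frame(
          condition = "(all)", analysis = "kappa",
          reason = conditionMessage(e)))
        NULL
      })
  }

  for (nm_tab in c("ct_number_table", "noise_table", "mtf_table",
                   "ratio_table", "detectability_table", "skipped")) {
    tab <- switch(nm_tab, ct_number_table = ct_tab,
                  noise_table = noise_tab, mtf_table = mtf_tab,
                  ratio_table = ratio_tab, detectability_table = detect_tab,
                  skipped = skip_tab)
    if (!is.null(tab)) {
      files <- c(files, .write_csv(tab, config$output_dir,
                                   paste0(nm_tab, ".csv")))
    }
  }

  report <- structure(
    list(ct_number_table = ct_tab, noise_table = noise_tab,
         mtf_table = mtf_tab, ratio_table = ratio_tab,
         detectability_table = detect_tab, kappa = kappa_res,
         skipped = skip_tab, files = files,
         provenance = .provenance(config)),
    class = "study_report"
  )
  writeLines(format_study_report(report), file.path(config$output_dir,
                                                    "summary.md"))
  report$files <- c(report$files, file.path(config$output_dir, "summary.md"))
  report
}

# every analysis default actually used, for the provenance block
.provenance <- function(config) {
  c(sprintf("seed: %d", config$seed),
    sprintf("reference condition: %s", config$reference),
    sprintf("nps detrend: %s (per-ROI surface subtraction)",
            config$nps_detrend),
    sprintf("noise/nps roi: %s px, centred, inside the phantom body",
            config$noise_roi_size %||% "auto (<=256)"),
    "nps radial bin width: DFT spacing 1/(roi_size * pixel_spacing)",
    "ct-number SD convention: grand SD pooling all line-ROI samples",
    paste("line ROI: 27 px (CT number) / 51 px (APC), 360 angles at",
          "1 degree, bilinear interpolation"),
    "low-contrast convention: 1.0% contrast = 10 HU above local background",
    "esf: 0.1-px radial bins, +-5 mm annulus, empty bins interpolated",
    paste("mtf: Tukey(0.5) taper, tail baseline subtraction,",
          "central-difference and pixel-aperture transfer corrections,",
          "first downward crossing readout"),
    paste("mtf radius refinement: one pass at the provisional",
          "half-amplitude crossing"),
    sprintf("mtf replicates: %d independent stacks", config$mtf_replicates),
    sprintf(paste("detectability surrogate: non-prewhitening matched",
                  "filter, SNR threshold %g (model observer, not a",
                  "human-reader reproduction)"),
            config$detect_threshold),
    "noise applied post-blur (reconstruction-domain noise model)")
}

#' Format a study report as markdown
#' @param report a `study_report`.
#' @return character vector of lines.
#' @export
format_study_report <- function(report) {
  out <- c("# Phantom image-quality study report", "")
  tab_md <- function(d) {
    if (is.null(d)) return("(not run)")
    hdr <- paste(names(d), collapse = " | ")
    sep <- paste(rep("---", ncol(d)), collapse = " | ")
    rows <- apply(d, 1, function(r) paste(trimws(format(r)), collapse = " | "))
    c(paste("|", hdr, "|"), paste("|", sep, "|"), paste("|", rows, "|"))
  }
  sect <- function(title, d) c(paste("##", title), "", tab_md(d), "")
  out <- c(out,
           sect("CT number (mean +- SD, HU)", report$ct_number_table),
           sect("Image noise (HU, SE)", report$noise_table),
           sect("Noise ratio vs reference (%)", report$ratio_table),
           sect("MTF f50 / f10 (cycles/mm, SE)", report$mtf_table),
           sect("Model-observer detectability surrogate",
                report$detectability_table))
  if (!is.null(report$kappa)) {
    out <- c(out, "## Inter-rater agreement", "",
             sprintf("kappa = %.3f (%s)", report$kappa$kappa,
                     report$kappa$band), "")
  }
  if (!is.null(report$skipped)) {
    out <- c(out, sect("Skipped analyses", report$skipped))
  }
  c(out, "## Provenance", "", paste("-", report$provenance))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in c("ct_number_table", "noise_table", "ratio_table", "mtf_table",
               "detectability_table")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: %d row(s)\n", nm, nrow(x[[nm]])))
    }
  }
  if (!is.null(x$skipped)) cat(sprintf("  skipped: %d\n", nrow(x$skipped)))
  invisible(x)
}
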