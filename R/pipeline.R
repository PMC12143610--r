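# End-to-end orchestration: simulate -> segment/count -> dose-response ->
# survival -> expression, with a serializable config and a reproducible
# demo experiment.

#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis-mode defaults:
#' focus `min_area` 5 px, survival level 0.10, DE cutoffs 1.5 (fold change),
#' 0.05 (p) and 0.5 (mean FPKM). One global integer seed is expanded into
#' per-stage substreams.
#'
#' The demo experiment encoded by the defaults is a two-quality comparison:
#' an X-ray-like quality with focus-induction slope 0.1 foci/cell/Gy and
#' LQ parameters (alpha 0.3/Gy, beta 0.03/Gy^2) against a carbon-like
#' quality with slope 0.3 foci/cell/Gy and (alpha 0.75/Gy, beta 0.04/Gy^2),
#' i.e. an iso-survival dose ratio near 2 at 10% survival.
#'
#' @param seed Global integer seed.
#' @param stages Named logical vector toggling `imaging`, `dose_response`,
#'   `survival`, `expression`.
#' @param qualities Radiation-quality tags (first = reference for RBE).
#' @param focus_slopes Foci/cell/Gy per quality.
#' @param focus_background 0 Gy background foci/cell.
#' @param lq_params Named list per quality with `alpha`, `beta`.
#' @param imaging_doses Doses (Gy) for the imaging stage; must include 0.
#' @param fields_per_dose,cells_per_field Imaging stage size.
#' @param min_area Focus size cutoff in pixels.
#' @param survival_level Iso-survival level for RBE.
#' @param survival_doses Doses for the clonogenic stage; must include 0.
#' @param n_seeded,plating_efficiency,survival_replicates Clonogenic stage
#'   parameters.
#' @param fc_cutoff,p_cutoff,fpkm_floor DE-filter cutoffs.
#' @param cq_fold_changes Tibble (`gene`, `condition`, `fold_change`) of true
#'   qPCR fold changes for the demo Cq table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c(imaging = TRUE, dose_response = TRUE,
                                       survival = TRUE, expression = TRUE),
                            qualities = c("xray", "carbon"),
                            focus_slopes = c(xray = 0.1, carbon = 0.3),
                            focus_background = 1,
                            lq_params = list(
                              xray = list(alpha = 0.3, beta = 0.03),
                              carbon = list(alpha = 0.75, beta = 0.04)
                            ),
                            imaging_doses = c(0, 2, 4, 8, 12, 16),
                            fields_per_dose = 2L,
                            cells_per_field = 5L,
                            min_area = 5,
                            survival_level = 0.10,
                            survival_doses = c(0, 1, 2, 4, 6, 8),
                            n_seeded = 500L,
                            plating_efficiency = 0.5,
                            survival_replicates = 3L,
                            fc_cutoff = 1.5,
                            p_cutoff = 0.05,
                            fpkm_floor = 0.5,
                            cq_fold_changes = tibble::tibble(
                              gene = c("Ifnb1", "Trex1"),
                              condition = "irradiated",
                              fold_change = c(6, 3)
                            )) {
  stages_full <- c(imaging = TRUE, dose_response = TRUE, survival = TRUE,
                   expression = TRUE)
  stages_full[names(stages)] <- stages
  cfg <- list(
    seed = as.integer(seed), stages = as.list(stages_full),
    qualities = qualities,
    focus_slopes = as.list(focus_slopes),
    focus_background = focus_background,
    lq_params = lq_params,
    imaging_doses = imaging_doses,
    fields_per_dose = as.integer(fields_per_dose),
    cells_per_field = as.integer(cells_per_field),
    min_area = min_area,
    survival_level = survival_level,
    survival_doses = survival_doses,
    n_seeded = as.integer(n_seeded),
    plating_efficiency = plating_efficiency,
    survival_replicates = as.integer(survival_replicates),
    fc_cutoff = fc_cutoff, p_cutoff = p_cutoff, fpkm_floor = fpkm_floor,
    cq_fold_changes = tibble::as_tibble(cq_fold_changes)
  )
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip at full numeric precision, so a written config restores
#' losslessly.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  raw$fields_per_dose <- as.integer(raw$fields_per_dose)
  raw$cells_per_field <- as.integer(raw$cells_per_field)
  raw$n_seeded <- as.integer(raw$n_seeded)
  raw$survival_replicates <- as.integer(raw$survival_replicates)
  raw$cq_fold_changes <- tibble::as_tibble(raw$cq_fold_changes)
  structure(raw, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  st <- config$stages
  if (isTRUE(st$dose_response) && !isTRUE(st$imaging)) {
    abort(paste("invalid config: dose_response requires foci input from the",
                "imaging stage; enable imaging or disable dose_response"))
  }
  if (isTRUE(st$imaging) && !any(config$imaging_doses == 0)) {
    abort("invalid config: imaging_doses must include the 0 Gy background")
  }
  if (!all(config$qualities %in% names(config$focus_slopes)) &&
      isTRUE(st$imaging)) {
    abort("invalid config: every quality needs a focus slope")
  }
  if (isTRUE(st$survival) &&
      !all(config$qualities %in% names(config$lq_params))) {
    abort("invalid config: every quality needs LQ parameters")
  }
  invisible(config)
}

#' Run the full analysis pipeline on simulated data
#'
#' Runs the enabled stages in dependency order on synthetic data generated
#' under the config's ground-truth parameters, writes all result tables to
#' `out_dir` as CSV, and returns a `run_report` that echoes the config and
#' summarizes every stage. Identical config and seed give identical reports
#' and byte-identical output files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for result tables (created if missing);
#'   `NULL` skips writing.
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  report <- list(config = config, warnings = character(), files = character())
  notes <- character()
  wh <- function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (isTRUE(config$stages$imaging)) {
    foci_rows <- list()
    fi <- 0L
    for (qi in seq_along(config$qualities)) {
      q <- config$qualities[qi]
      pars <- imaging_truth_params(
        n_cells = config$cells_per_field,
        focus_rate_intercept = config$focus_background,
        focus_rate_slope = config$focus_slopes[[q]],
        seed = mix_seed(config$seed, 100L + qi)
      )
      for (d in config$imaging_doses) {
        for (f in seq_len(config$fields_per_dose)) {
          fi <- fi + 1L
          sim <- simulate_field(pars, dose = d, quality = q,
                                index = fi)
          foci_rows[[fi]] <- count_field_foci(sim$field,
                                              min_area = config$min_area)
        }
      }
    }
    foci_table <- dplyr::bind_rows(foci_rows)
    corrected <- background_correct(foci_table)
    report$foci_table <- foci_table
    report$foci_groups <- corrected
  }

  if (isTRUE(config$stages$dose_response)) {
    fits <- purrr::map(setNames(config$qualities, config$qualities),
                       function(q) {
      series <- report$foci_groups |>
        dplyr::filter(.data$quality == q) |>
        dplyr::transmute(dose = .data$dose, response = .data$corrected_mean,
                         se = .data$se_foci, n = .data$n_cells, quality = q)
      fit_linear(series)
    })
    report$slope_fits <- fits
    if (length(fits) >= 2) {
      cmp <- compare_slopes(fits[[2]], fits[[1]])
      report$slope_comparison <- dplyr::mutate(
        cmp,
        quality_a = config$qualities[2], quality_b = config$qualities[1],
        significant = .data$p_value <= 0.05
      )
    }
  }

  if (isTRUE(config$stages$survival)) {
    sv <- purrr::imap(config$lq_params[config$qualities], function(p, q) {
      dat <- simulate_survival_data(
        survival_truth_params(
          alpha = p$alpha, beta = p$beta,
          plating_efficiency = config$plating_efficiency,
          n_seeded = config$n_seeded, doses = config$survival_doses,
          replicates = config$survival_replicates,
          seed = mix_seed(config$seed, 200L + match(q, config$qualities))
        ),
        quality = q
      )
      sfs <- surviving_fractions(dat)
      fit <- withCallingHandlers(fit_lq(sfs$summary), warning = wh)
      list(data = dat, sf = sfs$summary, fit = fit,
           dose_at_level = dose_at_survival(fit, config$survival_level))
    })
    report$survival <- sv
    if (length(sv) >= 2) {
      report$rbe <- tibble::tibble(
        reference = config$qualities[1], test = config$qualities[2],
        level = config$survival_level,
        rbe = rbe(sv[[1]]$fit, sv[[2]]$fit, config$survival_level)
      )
    }
  }

  if (isTRUE(config$stages$expression)) {
    cq <- simulate_cq_table(
      config$cq_fold_changes,
      conditions = c("control", unique(config$cq_fold_changes$condition)),
      control_condition = "control",
      seed = mix_seed(config$seed, 300L)
    )
    fc <- purrr::pmap(
      dplyr::distinct(config$cq_fold_changes, .data$gene, .data$condition),
      function(gene, condition) {
        delta_delta_ct(cq, gene, condition, "control")
      }
    ) |> dplyr::bind_rows()
    stability <- reference_stability(cq)
    em <- simulate_expression_matrix(
      expression_truth_params(seed = mix_seed(config$seed, 301L))
    )
    de <- de_filter(em$fpkm, em$groups,
                    group_a = unique(em$groups)[1],
                    group_b = unique(em$groups)[2],
                    fc_cutoff = config$fc_cutoff,
                    p_cutoff = config$p_cutoff,
                    fpkm_floor = config$fpkm_floor)
    grp_means <- vapply(unique(em$groups), function(g) {
      rowMeans(em$fpkm[, names(em$groups)[em$groups == g], drop = FALSE])
    }, numeric(nrow(em$fpkm)))
    zs <- zscore_matrix(grp_means)
    report$expression <- list(
      cq = cq, fold_changes = fc, reference_stability = stability,
      de = de, de_truth = em$truth, zscores = zs
    )
  }

  report$warnings <- notes
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) {
      p <- file.path(out_dir, name)
      readr::write_csv(x, p)
      report$files <<- c(report$files, p)
    }
    if (!is.null(report$foci_table)) {
      wr(report$foci_table, "foci_per_cell.csv")
      wr(report$foci_groups, "foci_group_summary.csv")
    }
    if (!is.null(report$slope_comparison)) {
      wr(report$slope_comparison, "slope_comparison.csv")
    }
    if (!is.null(report$survival)) {
      wr(dplyr::bind_rows(purrr::map(report$survival, "sf")),
         "surviving_fractions.csv")
      lq <- purrr::imap(report$survival, function(s, q) {
        tibble::tibble(quality = q, alpha = s$fit$alpha, beta = s$fit$beta,
                       dose_at_level = s$dose_at_level)
      }) |> dplyr::bind_rows()
      if (!is.null(report$rbe)) {
        wr(report$rbe, "rbe.csv")
      }
      wr(lq, "lq_fits.csv")
    }
    if (!is.null(report$expression)) {
      wr(report$expression$fold_changes, "qpcr_fold_changes.csv")
      wr(report$expression$de, "de_filter.csv")
      wr(tibble::as_tibble(report$expression$zscores$z, rownames = "gene"),
         "zscores.csv")
    }
  }
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$config$seed, "\n")
  if (!is.null(x$foci_groups)) {
    cat("  imaging:", nrow(x$foci_table), "cells across",
        dplyr::n_distinct(x$foci_table$field_id), "fields\n")
  }
  if (!is.null(x$slope_comparison)) {
    cat(sprintf("  slopes: %s - %s = %.3g foci/cell/Gy (p = %.3g%s)\n",
                x$slope_comparison$quality_a, x$slope_comparison$quality_b,
                x$slope_comparison$estimate, x$slope_comparison$p_value,
                if (x$slope_comparison$significant) ", significant" else ""))
  }
  if (!is.null(x$rbe)) {
    cat(sprintf("  RBE(%s/%s) at %.0f%% survival: %.2f\n",
                x$rbe$reference, x$rbe$test, 100 * x$rbe$level, x$rbe$rbe))
  }
  if (!is.null(x$expression)) {
    cat("  expression:", sum(x$expression$de$de), "DE genes;",
        nrow(x$expression$fold_changes), "qPCR fold changes\n")
  }
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Compare two fractionation schemes endpoint by endpoint
#'
#' For each endpoint measured under both schemes (e.g. foci per cell, gene
#' fold change, cytokine release), runs an unpaired two-tailed Welch t-test
#' between the schemes' replicate values, mirroring the single-high-dose vs
#' hypofractionation comparison design.
#'
#' @param scheme_a,scheme_b Tibbles with columns `endpoint` and `value`
#'   (replicate measurements), one per scheme.
#' @param labels Length-2 character, names of the schemes.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A tibble with one row per endpoint: group means, `estimate`, `t`,
#'   `df`, `p_value`, `significant`.
#' @export
fractionation_compare <- function(scheme_a, scheme_b,
                                  labels = c("A", "B"), alpha = 0.05) {
  stopifnot(all(c("endpoint", "value") %in% names(scheme_a)),
            all(c("endpoint", "value") %in% names(scheme_b)))
  ea <- sort(unique(scheme_a$endpoint))
  eb <- sort(unique(scheme_b$endpoint))
  if (!identical(ea, eb)) {
    abort("schemes measure different endpoints; cannot compare")
  }
  counts <- c(table(scheme_a$endpoint), table(scheme_b$endpoint))
  if (any(counts < 2)) {
    abort("every endpoint needs at least 2 replicates per scheme")
  }
  purrr::map(ea, function(e) {
    xa <- scheme_a$value[scheme_a$endpoint == e]
    xb <- scheme_b$value[scheme_b$endpoint == e]
    res <- compare_groups(xa, xb)
    tibble::tibble(
      endpoint = e,
      mean_a = mean(xa), mean_b = mean(xb),
      estimate = res$estimate, t = res$t, df = res$df,
      p_value = res$p_value, significant = res$p_value <= alpha
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::rename(!!paste0("mean_", labels[1]) := "mean_a",
                  !!paste0("mean_", labels[2]) := "mean_b")
}
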