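#' Parameters for the clonogenic-survival generator
#'
#' The generator draws colony counts under the linear-quadratic (LQ) cell
#' survival law `S(D) = exp(-alpha * D - beta * D^2)`: each flask seeded with
#' `n_seeded` cells yields `Binomial(n_seeded, plating_efficiency * S(D))`
#' colonies.
#'
#' @param alpha Linear kill coefficient, 1/Gy (>= 0).
#' @param beta Quadratic kill coefficient, 1/Gy^2 (>= 0).
#' @param plating_efficiency Fraction of unirradiated cells forming a colony,
#'   in (0, 1].
#' @param n_seeded Cells seeded per flask (single value or one per dose).
#' @param doses Dose levels in Gy; must include 0 Gy (needed downstream to
#'   estimate the plating efficiency).
#' @param replicates Flasks per dose.
#' @param seed Integer seed.
#' @return A list of class `survival_truth_params`.
#' @export
survival_truth_params <- function(alpha = 0.3, beta = 0.03,
                                  plating_efficiency = 0.5,
                                  n_seeded = 500,
                                  doses = c(0, 1, 2, 4, 6, 8),
                                  replicates = 3,
                                  seed = 1L) {
  stopifnot(alpha >= 0, beta >= 0,
            plating_efficiency > 0, plating_efficiency <= 1,
            all(doses >= 0), replicates >= 1,
            length(n_seeded) %in% c(1L, length(doses)), all(n_seeded >= 1))
  if (!any(doses == 0)) {
    abort("doses must include 0 Gy (plating-efficiency reference)")
  }
  structure(
    list(alpha = alpha, beta = beta,
         plating_efficiency = plating_efficiency,
         n_seeded = as.integer(n_seeded), doses = as.numeric(doses),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "survival_truth_params"
  )
}

#' Simulate a colony-forming assay dataset
#'
#' @param params A [survival_truth_params()] object.
#' @param quality Radiation-quality tag attached to every row.
#' @return A tibble with one row per flask: `dose`, `quality`, `replicate`,
#'   `cells_seeded`, `colonies_counted`. Colonies follow
#'   `Binomial(cells_seeded, plating_efficiency * exp(-alpha*D - beta*D^2))`.
#' @export
simulate_survival_data <- function(params, quality = "xray") {
  stopifnot(inherits(params, "survival_truth_params"))
  seeded <- if (length(params$n_seeded) == 1L) {
    rep(params$n_seeded, length(params$doses))
  } else {
    params$n_seeded
  }
  with_seed(params$seed, {
    tidyr::expand_grid(
      dose = params$doses,
      replicate = seq_len(params$replicates)
    ) |>
      dplyr::mutate(
        quality = quality,
        cells_seeded = seeded[match(.data$dose, params$doses)],
        p = params$plating_efficiency *
          exp(-params$alpha * .data$dose - params$beta * .data$dose^2),
        colonies_counted = rbinom(dplyr::n(), .data$cells_seeded, .data$p)
      ) |>
      dplyr::select("dose", "quality", "replicate", "cells_seeded",
                    "colonies_counted")
  })
}

#' Simulate a qPCR Cq table with known fold changes
#'
#' Generates technical-replicate Cq values for target and reference genes
#' under known true relative expression: for a gene with true fold change
#' `f` in a condition (relative to the control condition),
#' `Cq = baseline_cq - log2(f) + N(0, cq_noise_sd)`. Reference genes are
#' perfectly stable unless given an explicit fold change.
#'
#' @param fold_changes A tibble with columns `gene`, `condition`,
#'   `fold_change` giving the true relative expression of each target gene in
#'   each non-control condition (control is implicitly 1).
#' @param conditions Character vector of all conditions, control first unless
#'   `control_condition` names it.
#' @param control_condition Name of the control condition.
#' @param reference_genes At least two reference-gene names (the downstream
#'   ddCt normalization uses the geometric mean of two references).
#' @param baseline_cq Named numeric of per-gene control-condition mean Cq;
#'   genes not named get `default_cq`.
#' @param default_cq Fallback baseline Cq.
#' @param replicates Technical replicates per (sample, gene).
#' @param cq_noise_sd Gaussian replicate noise SD in cycles (0 for exact
#'   round-trip fixtures).
#' @param seed Integer seed.
#' @return A tibble `sample_id, condition, gene, replicate, cq` of class
#'   suitable for [delta_delta_ct()].
#' @export
simulate_cq_table <- function(fold_changes,
                              conditions,
                              control_condition = conditions[1],
                              reference_genes = c("Gapdh", "Rpl13a"),
                              baseline_cq = c(Gapdh = 18, Rpl13a = 22),
                              default_cq = 26,
                              replicates = 3,
                              cq_noise_sd = 0.2,
                              seed = 1L) {
  if (length(reference_genes) < 2L) {
    abort("at least 2 reference genes are required")
  }
  stopifnot(control_condition %in% conditions, replicates >= 1,
            cq_noise_sd >= 0)
  fold_changes <- tibble::as_tibble(fold_changes)
  stopifnot(all(c("gene", "condition", "fold_change") %in% names(fold_changes)))
  genes <- union(unique(fold_changes$gene), reference_genes)
  with_seed(seed, {
    tidyr::expand_grid(
      condition = conditions, gene = genes,
      replicate = seq_len(replicates)
    ) |>
      dplyr::left_join(fold_changes, by = c("gene", "condition")) |>
      dplyr::mutate(
        fold_change = dplyr::if_else(
          is.na(.data$fold_change) | .data$condition == control_condition,
          1, .data$fold_change
        ),
        base = unname(
          ifelse(.data$gene %in% names(baseline_cq),
                 baseline_cq[.data$gene], default_cq)
        ),
        cq = .data$base - log2(.data$fold_change) +
          rnorm(dplyr::n(), 0, cq_noise_sd),
        sample_id = paste0(.data$condition, "_s1")
      ) |>
      dplyr::select("sample_id", "condition", "gene", "replicate", "cq")
  })
}

#' Parameters for the FPKM expression-matrix generator
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector of per-group replicate counts (>= 2
#'   each for any group entering a test), e.g. `c(control = 3, irr = 3)`.
#' @param de_fraction Fraction of genes planted as differentially expressed
#'   in the second group, in `[0, 1]`.
#' @param log2fc Effect size: planted DE genes get `+log2fc` (up) or
#'   `-log2fc` (down, half of them) in the second group.
#' @param meanlog,sdlog Log-normal parameters of the baseline per-gene FPKM
#'   level; `sdlog` must be positive.
#' @param noise_sdlog Per-sample log-normal noise SD (0 for near-exact
#'   fixtures).
#' @param seed Integer seed.
#' @return A list of class `expression_truth_params`.
#' @export
expression_truth_params <- function(n_genes = 50,
                                    groups = c(control = 3L, irradiated = 3L),
                                    de_fraction = 0.2,
                                    log2fc = 2,
                                    meanlog = 1.5, sdlog = 1.2,
                                    noise_sdlog = 0.25,
                                    seed = 1L) {
  stopifnot(n_genes >= 1, length(groups) >= 2, all(groups >= 1),
            de_fraction >= 0, de_fraction <= 1, log2fc >= 0,
            noise_sdlog >= 0)
  if (sdlog <= 0) abort("sdlog (log-normal scale) must be positive")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  structure(
    list(n_genes = as.integer(n_genes), groups = as.integer(groups) |>
           setNames(names(groups)),
         de_fraction = de_fraction, log2fc = log2fc,
         meanlog = meanlog, sdlog = sdlog, noise_sdlog = noise_sdlog,
         seed = as.integer(seed)),
    class = "expression_truth_params"
  )
}

#' Simulate an FPKM matrix with planted differential expression
#'
#' Baseline per-gene FPKM levels are log-normal; a `de_fraction` of genes
#' receives a `+/- log2fc` shift in the second group (half up, half down).
#' Per-sample multiplicative noise is log-normal with SD `noise_sdlog`.
#'
#' @param params An [expression_truth_params()] object.
#' @return A list with `fpkm` (genes x samples numeric matrix), `groups`
#'   (named character vector mapping sample to group) and `truth` (tibble
#'   `gene`, `is_de`, `log2fc`, `direction`).
#' @export
simulate_expression_matrix <- function(params) {
  stopifnot(inherits(params, "expression_truth_params"))
  with_seed(params$seed, {
    g <- params$groups
    samples <- unlist(purrr::imap(g, function(n, nm) paste0(nm, "_", seq_len(n))))
    group_of <- unlist(purrr::imap(g, function(n, nm) rep(nm, n)))
    names(group_of) <- samples

    genes <- paste0("gene", sprintf("%04d", seq_len(params$n_genes)))
    base_log <- rnorm(params$n_genes, params$meanlog, params$sdlog)

    n_de <- round(params$de_fraction * params$n_genes)
    de_idx <- if (n_de > 0) sample.int(params$n_genes, n_de) else integer()
    dirs <- rep(0, params$n_genes)
    if (n_de > 0) {
      up <- de_idx[seq_len(ceiling(n_de / 2))]
      down <- setdiff(de_idx, up)
      dirs[up] <- 1
      dirs[down] <- -1
    }

    second_group <- names(g)[2]
    fpkm <- matrix(0, params$n_genes, length(samples),
                   dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      shift <- if (group_of[j] == second_group) {
        dirs * params$log2fc * log(2)
      } else {
        0
      }
      fpkm[, j] <- exp(base_log + shift +
                         rnorm(params$n_genes, 0, params$noise_sdlog))
    }
    truth <- tibble::tibble(
      gene = genes,
      is_de = dirs != 0,
      log2fc = dirs * params$log2fc,
      direction = dplyr::case_when(dirs > 0 ~ "up", dirs < 0 ~ "down",
                                   .default = NA_character_)
    )
    list(fpkm = fpkm, groups = group_of, truth = truth)
  })
}
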