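# Relative qPCR quantification, reference-gene stability, FPKM
# differential-expression filtering and Z-score summaries.

#' Relative quantification by the 2^(-ddCt) method
#'
#' Technical replicates are first averaged to one Cq per (condition, gene).
#' Within each condition, `dCt = mean Cq(target) - geometric mean of the two
#' reference genes' mean Cq values`; then
#' `ddCt = dCt(condition) - dCt(control)` and the fold change is
#' `2^(-ddCt)`. Normalizing to the geometric mean of the reference-gene Cq
#' values follows the convention stated with the assay; the alternative of
#' averaging the references on the expression scale (arithmetic mean of Cq)
#' is available via `reference_mean = "arithmetic"`.
#'
#' @param table Cq tibble with columns `condition`, `gene`, `cq` (and
#'   optionally `replicate`), e.g. from [simulate_cq_table()].
#' @param gene Target gene name.
#' @param condition Condition to quantify.
#' @param control_condition Reference condition (fold change 1 by
#'   definition when compared with itself).
#' @param reference_genes Exactly two reference genes (default Gapdh and
#'   Rpl13a, the usual murine pair).
#' @param reference_mean `"geometric"` (default) or `"arithmetic"` mean of
#'   the two reference-gene mean Cqs.
#' @return A one-row tibble: `gene`, `condition`, `control_condition`,
#'   `dct`, `dct_control`, `ddct`, `fold_change`.
#' @export
delta_delta_ct <- function(table, gene, condition, control_condition,
                           reference_genes = c("Gapdh", "Rpl13a"),
                           reference_mean = c("geometric", "arithmetic")) {
  reference_mean <- match.arg(reference_mean)
  stopifnot(all(c("condition", "gene", "cq") %in% names(table)))
  if (length(reference_genes) != 2L) {
    abort("exactly 2 reference genes are required")
  }
  need <- tidyr::expand_grid(condition = c(condition, control_condition),
                             gene = c(gene, reference_genes))
  have <- dplyr::distinct(table, .data$condition, .data$gene)
  miss <- dplyr::anti_join(need, have, by = c("condition", "gene"))
  if (nrow(miss)) {
    abort(paste0("missing Cq measurements: ",
                 paste(miss$gene, "in", miss$condition, collapse = "; ")))
  }
  mean_cq <- function(cond, g) {
    mean(table$cq[table$condition == cond & table$gene == g])
  }
  dct_of <- function(cond) {
    refs <- vapply(reference_genes, mean_cq, numeric(1), cond = cond)
    ref <- if (reference_mean == "geometric") {
      if (any(refs <= 0)) {
        abort("non-positive reference Cq cannot enter a geometric mean")
      }
      sqrt(prod(refs))
    } else {
      mean(refs)
    }
    mean_cq(cond, gene) - ref
  }
  dct <- dct_of(condition)
  dct_ctrl <- dct_of(control_condition)
  ddct <- dct - dct_ctrl
  tibble::tibble(
    gene = gene, condition = condition,
    control_condition = control_condition,
    dct = dct, dct_control = dct_ctrl, ddct = ddct,
    fold_change = 2^(-ddct)
  )
}

#' Reference-gene stability across conditions
#'
#' A descriptive stability report: per reference gene, the SD of the mean Cq
#' across conditions and the maximum pairwise difference between condition
#' means. A gene is flagged unstable when its SD exceeds `max_sd` cycles.
#'
#' @param table Cq tibble with `condition`, `gene`, `cq`.
#' @param reference_genes Genes to report on.
#' @param max_sd Flagging bound on the across-condition SD in cycles
#'   (default 0.5).
#' @return Tibble `gene, n_conditions, sd_cq, max_pairwise_diff, flagged`.
#' @export
reference_stability <- function(table,
                                reference_genes = c("Gapdh", "Rpl13a"),
                                max_sd = 0.5) {
  stopifnot(all(c("condition", "gene", "cq") %in% names(table)))
  d <- table |>
    dplyr::filter(.data$gene %in% reference_genes) |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop_last")
  if (any(dplyr::summarise(d, n = dplyr::n())$n < 2)) {
    abort("at least 2 conditions are required to assess stability")
  }
  d |>
    dplyr::summarise(
      n_conditions = dplyr::n(),
      sd_cq = sd(.data$cq),
      max_pairwise_diff = max(.data$cq) - min(.data$cq),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$sd_cq > max_sd)
}

#' Filter differentially expressed genes from an FPKM matrix
#'
#' Applies three criteria per gene, all cutoffs inclusive:
#' fold change at least 1.5 in either direction
#' (`FC >= 1.5` or `FC <= 1/1.5`), unpaired two-tailed t-test p-value
#' `<= 0.05` on `log2(FPKM + pseudocount)`, and mean FPKM `>= 0.5` in at
#' least one group. A gene is differentially expressed iff all three flags
#' hold. No multiple-testing correction enters the flag (the rule set is
#' defined on raw p-values); a Benjamini-Hochberg FDR column is reported
#' alongside for transparency.
#'
#' @param fpkm Genes x samples numeric matrix (rownames = genes).
#' @param groups Named character vector mapping sample (column) names to
#'   group labels.
#' @param group_a,group_b The two groups to compare (fold change is
#'   `mean_b / mean_a`, i.e. B relative to A).
#' @param fc_cutoff Fold-change cutoff (default 1.5).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @param fpkm_floor Minimum group-mean FPKM in at least one group
#'   (default 0.5).
#' @param pseudocount Added inside the log2 transform for the t-test
#'   (default 0.1). The fold change itself is computed on raw group means.
#' @return A tibble with one row per gene: `gene`, `mean_a`, `mean_b`,
#'   `fold_change`, `p_value`, `fdr`, `passes_fc`, `passes_p`,
#'   `passes_fpkm`, `de`, `direction`.
#' @export
de_filter <- function(fpkm, groups, group_a, group_b,
                      fc_cutoff = 1.5, p_cutoff = 0.05, fpkm_floor = 0.5,
                      pseudocount = 0.1) {
  stopifnot(is.matrix(fpkm), !is.null(colnames(fpkm)))
  a_cols <- names(groups)[groups == group_a]
  b_cols <- names(groups)[groups == group_b]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    abort("each group needs at least 2 samples")
  }
  a <- fpkm[, a_cols, drop = FALSE]
  b <- fpkm[, b_cols, drop = FALSE]
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  fc <- mean_b / mean_a
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  p <- vapply(seq_len(nrow(fpkm)), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    if (sd(xa) == 0 && sd(xb) == 0) {
      if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      t.test(xa, xb, var.equal = FALSE)$p.value
    }
  }, numeric(1))
  passes_fc <- fc >= fc_cutoff | fc <= 1 / fc_cutoff
  passes_p <- p <= p_cutoff
  passes_fpkm <- mean_a >= fpkm_floor | mean_b >= fpkm_floor
  de <- passes_fc & passes_p & passes_fpkm
  tibble::tibble(
    gene = rownames(fpkm) %||% as.character(seq_len(nrow(fpkm))),
    mean_a = mean_a, mean_b = mean_b, fold_change = fc,
    p_value = p, fdr = stats::p.adjust(p, "BH"),
    passes_fc = passes_fc, passes_p = passes_p, passes_fpkm = passes_fpkm,
    de = de,
    direction = dplyr::case_when(
      de & fc > 1 ~ "up", de & fc < 1 ~ "down", .default = NA_character_
    )
  )
}

#' Row-wise Z-scores of a summary expression matrix
#'
#' Standardizes each gene (row) across conditions:
#' `z = (x - row mean) / row SD`. Constant rows, whose SD is 0, are returned
#' as all-zero and flagged.
#'
#' @param values Genes x conditions numeric matrix with at least 2 columns.
#' @return A list with `z` (matrix of the same shape) and `constant`
#'   (logical vector flagging constant rows).
#' @export
zscore_matrix <- function(values) {
  stopifnot(is.matrix(values))
  if (ncol(values) < 2) abort("at least 2 conditions are required")
  mu <- rowMeans(values)
  sdv <- apply(values, 1, sd)
  constant <- sdv == 0
  z <- (values - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  list(z = z, constant = constant)
}
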