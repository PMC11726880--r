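#' CASh configuration
#'
#' Tuning parameters of the Shapley-difference pipeline. Defaults follow
#' the published protocol: gene preselection at raw p below 0.05 (0.01 for
#' the stricter variant), 1000 bootstrap iterations, |FC| > 2 fold-change
#' filter, BH FDR at 0.05.
#'
#' @param preselect_alpha Raw p-value cutoff used both to preselect genes
#'   and as the raw-significance stringency (0.01 or 0.05 in the protocol;
#'   any value in (0, 1] is accepted).
#' @param n_boot Number of bootstrap iterations (B).
#' @param fc_threshold Fold-change cutoff; a gene passes iff |FC| is
#'   strictly greater than this (> 1).
#' @param fdr_alpha BH FDR level applied over the preselected family.
#' @param seed Integer seed driving the bootstrap resamples.
#' @param preselect_method Source of the preselection raw p: `"welch"`
#'   (default) or `"ebayes"`.
#' @return A list of class `cash_config`.
#' @export
cash_config <- function(preselect_alpha = 0.05, n_boot = 1000,
                        fc_threshold = 2, fdr_alpha = 0.05, seed = 1L,
                        preselect_method = c("welch", "ebayes")) {
  preselect_method <- match.arg(preselect_method)
  if (preselect_alpha <= 0 || preselect_alpha > 1) {
    validation_error("preselect_alpha must be in (0, 1]")
  }
  if (n_boot < 1) validation_error("n_boot must be >= 1")
  if (fc_threshold <= 1) validation_error("fc_threshold must be > 1")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    validation_error("fdr_alpha must be in (0, 1)")
  }
  structure(list(preselect_alpha = preselect_alpha,
                 n_boot = as.integer(n_boot), fc_threshold = fc_threshold,
                 fdr_alpha = fdr_alpha, seed = as.integer(seed),
                 preselect_method = preselect_method),
            class = "cash_config")
}

#' Preselect genes by raw p-value
#'
#' Restricts the game to genes showing at least nominal evidence of
#' differential expression: those with raw p strictly below `alpha` from
#' the chosen classical test. The subset may be empty.
#'
#' @param ds An [expression_dataset()] with groups.
#' @param alpha Raw p-value cutoff.
#' @param method `"welch"` or `"ebayes"`.
#' @return Character vector of gene ids (dataset order).
#' @export
preselect_genes <- function(ds, alpha, method = c("welch", "ebayes")) {
  method <- match.arg(method)
  p <- if (method == "welch") welch_t(ds)$p else ebayes_moderated_t(ds)$p
  rownames(ds$values)[p < alpha]
}

# Per-gene, per-sample Shapley weights b_gj / k_j (0 where k_j = 0).
# A group's Shapley vector is the row mean over that group's columns,
# because k_j depends only on the column itself.
shapley_weights <- function(mat) {
  k <- colSums(mat)
  w <- sweep(mat, 2, pmax(k, 1), "/")
  w[, k == 0] <- 0
  w
}

#' Bootstrap p-values for the Shapley difference in one direction
#'
#' Observed statistic: `d_g = phi_case_g - phi_ctrl_g`, the difference of
#' the per-group Shapley values for one Boolean direction. Significance is
#' assessed with a centered within-group bootstrap: in each of B
#' iterations, `m_case` pseudo-case columns are drawn with replacement
#' from the case matrix and `m_ctrl` pseudo-control columns from the
#' control matrix, the difference `d*` is recomputed, and the centered
#' residual `d* - d` estimates the sampling noise of `d` around its
#' estimand. Two-sided p with add-one correction:
#' `p_g = (1 + #\{b : |d*_g - d_g| >= |d_g|\}) / (B + 1)`, so p lives on
#' the grid `\{1/(B+1), ..., 1\}` and is never zero. Resampling per group
#' (rather than from the pooled columns) is essential for calibration
#' here: the coding thresholds adapt to the control samples, so control
#' columns have systematically smaller flag-count variance than case
#' columns and the two groups are not exchangeable even under the null.
#' Resampled column sets are shared across genes, preserving gene-gene
#' dependence.
#'
#' @param b_case,b_ctrl `boolean_expression_matrix` pair for one direction,
#'   same gene list, each with >= 2 samples.
#' @param n_boot Number of iterations B.
#' @param seed Integer seed; fixes the resamples.
#' @return A list with `d` (observed difference), `p`, `phi_case`,
#'   `phi_ctrl` (named per-gene vectors) and `n_boot`.
#' @export
bootstrap_pvalues <- function(b_case, b_ctrl, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(b_case, "boolean_expression_matrix"),
            inherits(b_ctrl, "boolean_expression_matrix"))
  if (!identical(rownames(b_case$values), rownames(b_ctrl$values))) {
    validation_error("case and control matrices must share the gene list")
  }
  m1 <- ncol(b_case$values)
  m2 <- ncol(b_ctrl$values)
  if (m1 < 2 || m2 < 2) validation_error("each group needs >= 2 samples")
  genes <- rownames(b_case$values)
  pooled <- cbind(b_case$values, b_ctrl$values)
  m <- m1 + m2
  w <- shapley_weights(pooled)
  phi_case <- rowMeans(w[, seq_len(m1), drop = FALSE])
  phi_ctrl <- rowMeans(w[, m1 + seq_len(m2), drop = FALSE])
  d_obs <- phi_case - phi_ctrl

  # coefficient matrix: column b holds +1/m1 per drawn pseudo-case
  # (case columns only), -1/m2 per drawn pseudo-control (control columns
  # only), so all B differences come from one matrix product W %*% coef
  coef <- with_seed(seed, {
    idx_case <- matrix(sample.int(m1, m1 * n_boot, replace = TRUE), m1)
    idx_ctrl <- matrix(sample.int(m2, m2 * n_boot, replace = TRUE), m2)
    vapply(seq_len(n_boot), function(b) {
      c(tabulate(idx_case[, b], m1) / m1, -tabulate(idx_ctrl[, b], m2) / m2)
    }, numeric(m))
  })
  resid <- abs(w %*% coef - d_obs)
  exceed <- rowSums(resid >= abs(d_obs) - 1e-12)
  p <- (1 + exceed) / (n_boot + 1)
  list(d = stats::setNames(d_obs, genes), p = stats::setNames(p, genes),
       phi_case = stats::setNames(phi_case, genes),
       phi_ctrl = stats::setNames(phi_ctrl, genes), n_boot = n_boot)
}

#' Combine over- and under-expression p-values per gene
#'
#' The two directions are tested as separate games; a gene-level p is
#' obtained by Bonferroni over the pair, `p_gene = min(1, 2 * min(p_over,
#' p_under))`, with direction taken from the minimizing (firing) side:
#' `up` when the over side fires, `down` when the under side does. When
#' the observed Shapley differences are supplied, a firing side whose
#' difference is negative flips the label — excess over-flags among
#' *controls* means the gene is relatively down in cases, and vice versa
#' (the two-sided test can fire on either sign). Exact p ties are broken
#' by the sign of the log2 mean difference `delta`, then `up`.
#'
#' @param p_over,p_under Per-gene p-value vectors on the same genes.
#' @param d_over,d_under Optional observed Shapley differences
#'   (case - control) per direction; when omitted the firing side is
#'   assumed case-elevated.
#' @param delta Per-gene log2 mean difference (case - control), used only
#'   as tie-break.
#' @return A list with `p` (combined) and `direction` (`"up"`/`"down"`).
#' @export
combine_directions <- function(p_over, p_under, d_over = NULL,
                               d_under = NULL, delta = 0) {
  if (length(p_over) != length(p_under)) {
    validation_error("p_over and p_under must cover the same genes")
  }
  n <- length(p_over)
  delta <- rep_len(delta, n)
  if (is.null(d_over)) d_over <- rep_len(0, n)
  if (is.null(d_under)) d_under <- rep_len(0, n)
  p <- pmin(1, 2 * pmin(p_over, p_under))
  direction <- ifelse(p_over < p_under,
                      ifelse(d_over < 0, "down", "up"),
                      ifelse(p_under < p_over,
                             ifelse(d_under < 0, "up", "down"),
                             ifelse(delta < 0, "down", "up")))
  list(p = p, direction = direction)
}

#' Per-gene fold change on log2 data
#'
#' `delta = mean(case) - mean(control)` on the log2 scale; the signed fold
#' change is `2^delta` for `delta >= 0` and `-2^(-delta)` otherwise, so
#' |FC| > threshold is equivalent to |delta| > log2(threshold) (strict).
#'
#' @param ds An [expression_dataset()] with groups.
#' @return Data frame with columns `gene`, `delta`, `fold_change`.
#' @export
fold_change <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  delta <- rowMeans(group_matrix(ds, "case")) -
    rowMeans(group_matrix(ds, "control"))
  fc <- ifelse(delta >= 0, 2^delta, -2^(-delta))
  data.frame(gene = rownames(ds$values), delta = unname(delta),
             fold_change = unname(fc), stringsAsFactors = FALSE)
}

#' Run the full CASh pipeline
#'
#' Preselection (raw p < alpha) -> discretization in both directions
#' relative to the control reference -> per-group microarray games ->
#' Shapley values -> bootstrap p per direction -> Bonferroni combination
#' across directions -> BH FDR over the preselected family -> significance
#' and fold-change flags. Deterministic given the config seed. Genes not
#' preselected carry no result rows; an empty preselection yields an empty
#' (valid) result.
#'
#' @param ds An [expression_dataset()] with groups attached.
#' @param cfg A [cash_config()].
#' @return A data frame of class `cash_result`, one row per preselected
#'   gene: Shapley values per group and direction, observed differences,
#'   per-direction and combined p, BH q, `delta`, signed `fold_change`,
#'   `direction`, and flags `sig_raw`, `sig_fdr` (q_gene < fdr_alpha),
#'   `passes_fc` (|FC| strictly above the threshold). `sig_raw` follows
#'   the protocol's per-direction calling: the over- and under-expression
#'   games are separate analyses, so a gene is raw-significant when
#'   either direction's bootstrap p falls below the stringency
#'   (`min(p_over, p_under) < preselect_alpha`), with `direction` naming
#'   the firing side; the Bonferroni-combined `p_gene` is what enters the
#'   BH correction for `sig_fdr`.
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 200, seed = 3))
#' res <- run_cash(sim$dataset, cash_config(n_boot = 100, seed = 3))
#' head(res)
#' @export
run_cash <- function(ds, cfg = cash_config()) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(cfg, "cash_config"))
  if (is.null(ds$groups)) validation_error("dataset has no group labels attached")
  keep <- preselect_genes(ds, cfg$preselect_alpha, cfg$preselect_method)
  if (length(keep) == 0) return(empty_cash_result())
  sub <- subset_genes(ds, keep)
  ref <- control_reference(sub)
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max - 1L, 2))
  boot <- lapply(c(over = "over", under = "under"), function(dir) {
    parts <- split_by_group(discretize(sub, ref, dir), sub$groups)
    bootstrap_pvalues(parts$case, parts$control, cfg$n_boot,
                      seed = seeds[[if (dir == "over") 1L else 2L]])
  })
  fc <- fold_change(sub)
  comb <- combine_directions(boot$over$p, boot$under$p,
                             boot$over$d, boot$under$d, delta = fc$delta)
  q <- bh_fdr(comb$p)
  res <- data.frame(
    gene = keep,
    phi_case_over = unname(boot$over$phi_case),
    phi_ctrl_over = unname(boot$over$phi_ctrl),
    phi_case_under = unname(boot$under$phi_case),
    phi_ctrl_under = unname(boot$under$phi_ctrl),
    d_over = unname(boot$over$d),
    d_under = unname(boot$under$d),
    p_over = unname(boot$over$p),
    p_under = unname(boot$under$p),
    p_gene = unname(comb$p),
    q_gene = unname(q),
    delta = fc$delta,
    fold_change = fc$fold_change,
    direction = comb$direction,
    stringsAsFactors = FALSE)
  res$sig_raw <- pmin(res$p_over, res$p_under) < cfg$preselect_alpha
  res$sig_fdr <- res$q_gene < cfg$fdr_alpha
  res$passes_fc <- abs(res$delta) > log2(cfg$fc_threshold)
  class(res) <- c("cash_result", "data.frame")
  res
}

empty_cash_result <- function() {
  res <- data.frame(gene = character(), phi_case_over = numeric(),
                    phi_ctrl_over = numeric(), phi_case_under = numeric(),
                    phi_ctrl_under = numeric(), d_over = numeric(),
                    d_under = numeric(), p_over = numeric(),
                    p_under = numeric(), p_gene = numeric(),
                    q_gene = numeric(), delta = numeric(),
                    fold_change = numeric(), direction = character(),
                    sig_raw = logical(), sig_fdr = logical(),
                    passes_fc = logical(), stringsAsFactors = FALSE)
  class(res) <- c("cash_result", "data.frame")
  res
}

#' Convert results to a DEG table
#'
#' @param x A `cash_result` or `classical_result`.
#' @param ... Passed to methods.
#' @return A [deg_table()].
#' @export
as_deg_table <- function(x, ...) UseMethod("as_deg_table")

#' @rdname as_deg_table
#' @param method Method label to record in the table.
#' @export
as_deg_table.cash_result <- function(x, method = "CASh", ...) {
  flags <- list(sig01 = x$p_gene < 0.01, sig05 = x$p_gene < 0.05,
                fdr05 = x$q_gene < 0.05)
  any_flag <- flags$sig01 | flags$sig05 | flags$fdr05
  deg_table(x$gene, rep(method, nrow(x)), x$p_gene, x$q_gene,
            x$fold_change, ifelse(any_flag, x$direction, ""),
            flags$sig01, flags$sig05, flags$fdr05)
}
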