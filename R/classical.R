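#' Per-gene Welch unequal-variance t-test
#'
#' Vectorized over genes: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the t
#' distribution. Degenerate cases: zero variance in both groups with zero
#' mean difference gives t = 0, p = 1; zero variance with a non-zero
#' difference gives an infinite t and p floored at the smallest positive
#' double (p-values are never exactly zero, keeping BH well defined).
#'
#' @param ds An [expression_dataset()] with groups attached (>= 2 samples
#'   per group).
#' @return Data frame with columns `gene`, `mean_case`, `mean_ctrl`, `t`,
#'   `df`, `p`.
#' @export
welch_t <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  x1 <- group_matrix(ds, "case")
  x2 <- group_matrix(ds, "control")
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) validation_error("each group needs >= 2 samples")
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero_var <- se2 == 0
  t[zero_var & diff == 0] <- 0
  t[zero_var & diff > 0] <- Inf
  t[zero_var & diff < 0] <- -Inf
  df[zero_var] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p <- pmax(p, .Machine$double.xmin)
  data.frame(gene = rownames(ds$values), mean_case = unname(m1),
             mean_ctrl = unname(m2), t = unname(t), df = unname(df),
             p = unname(p), stringsAsFactors = FALSE)
}

# Newton inversion of the trigamma function (for the moderated-t prior);
# converges in a handful of iterations for any y > 0.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 50L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

# Method-of-moments fit of the scaled inverse-chi-square prior for
# residual variances: match mean and variance of log s^2 via
# digamma/trigamma. Returns df.prior (possibly Inf) and var.prior.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) validation_error("need >= 2 genes with positive variance to fit the prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
  }
  list(df = df_prior, var = var_prior)
}

#' Empirical-Bayes moderated t-statistic
#'
#' Two-group moderated t: per-gene pooled residual variance `s_g^2` on
#' `d_g = n1 + n2 - 2` degrees of freedom is shrunk toward a prior
#' variance `s0^2` with prior degrees of freedom `d0` estimated across all
#' genes by matching moments of `log s_g^2` (digamma/trigamma, with
#' trigamma inverted by Newton iteration to 1e-8). The posterior variance
#' is `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the moderated t is referred
#' to a t distribution on `d0 + d_g` degrees of freedom. Borrowing
#' strength across genes stabilizes small-sample variance estimates, the
#' chronic weakness of the per-gene t-test in microarray studies.
#'
#' Limit behaviour: forcing `prior_df = 0` recovers the ordinary
#' pooled-variance t exactly; `prior_df = Inf` uses the common prior
#' variance for every gene (normal reference distribution).
#'
#' @param ds An [expression_dataset()] with groups (>= 2 per group, >= 2
#'   genes unless the prior is supplied).
#' @param prior_df,prior_var Optional override of the estimated prior
#'   (both must be given together, except `prior_df = 0` which needs no
#'   prior variance).
#' @return Data frame with columns `gene`, `t`, `df_total`, `p`,
#'   `s2_post`, plus attributes `df_prior` and `var_prior`.
#' @export
ebayes_moderated_t <- function(ds, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  x1 <- group_matrix(ds, "case")
  x2 <- group_matrix(ds, "control")
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) validation_error("each group needs >= 2 samples")
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  dg <- n1 + n2 - 2
  s2 <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / dg
  if (is.null(prior_df)) {
    if (nrow(ds$values) < 2) {
      validation_error("need >= 2 genes to estimate the variance prior")
    }
    prior <- fit_variance_prior(s2, dg)
  } else {
    if (prior_df < 0) validation_error("prior_df must be >= 0")
    if (prior_df > 0 && is.null(prior_var)) {
      validation_error("prior_var must accompany a positive prior_df")
    }
    prior <- list(df = prior_df, var = if (prior_df == 0) NA_real_ else prior_var)
  }
  s2_post <- if (is.infinite(prior$df)) {
    rep(prior$var, length(s2))
  } else if (prior$df == 0) {
    s2
  } else {
    (prior$df * prior$var + dg * s2) / (prior$df + dg)
  }
  t <- (m1 - m2) / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- prior$df + dg
  p <- 2 * stats::pt(-abs(t), df_total)
  p <- pmax(p, .Machine$double.xmin)
  out <- data.frame(gene = rownames(ds$values), t = unname(t),
                    df_total = df_total, p = unname(p),
                    s2_post = unname(s2_post), stringsAsFactors = FALSE)
  attr(out, "df_prior") <- prior$df
  attr(out, "var_prior") <- prior$var
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validating wrapper around the classical step-up procedure
#' (`stats::p.adjust(method = "BH")`): sorted ascending,
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1, original order
#' restored. Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    validation_error("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Classical differential-expression baselines
#'
#' Runs both conventional tests (Welch and moderated t) and applies BH
#' correction to each, returning one row per gene.
#'
#' @param ds An [expression_dataset()] with groups attached.
#' @return Data frame of class `classical_result` with columns `gene`,
#'   `mean_case`, `mean_ctrl`, `t_welch`, `df_welch`, `p_welch`,
#'   `q_welch`, `t_ebayes`, `df_ebayes`, `p_ebayes`, `q_ebayes`, `delta`,
#'   `fold_change`.
#' @export
classical_de <- function(ds) {
  w <- welch_t(ds)
  e <- ebayes_moderated_t(ds)
  fc <- fold_change(ds)
  res <- data.frame(gene = w$gene, mean_case = w$mean_case,
                    mean_ctrl = w$mean_ctrl,
                    t_welch = w$t, df_welch = w$df, p_welch = w$p,
                    q_welch = bh_fdr(w$p),
                    t_ebayes = e$t, df_ebayes = e$df_total, p_ebayes = e$p,
                    q_ebayes = bh_fdr(e$p),
                    delta = fc$delta, fold_change = fc$fold_change,
                    stringsAsFactors = FALSE)
  class(res) <- c("classical_result", "data.frame")
  res
}

#' @rdname as_deg_table
#' @param test Which baseline to tabulate: `"welch"` or `"ebayes"`.
#' @export
as_deg_table.classical_result <- function(x, test = c("welch", "ebayes"),
                                          ...) {
  test <- match.arg(test)
  p <- x[[paste0("p_", test)]]
  q <- x[[paste0("q_", test)]]
  flags <- list(sig01 = p < 0.01, sig05 = p < 0.05, fdr05 = q < 0.05)
  any_flag <- flags$sig01 | flags$sig05 | flags$fdr05
  direction <- ifelse(any_flag, ifelse(x$delta >= 0, "up", "down"), "")
  deg_table(x$gene, rep(if (test == "welch") "Welch" else "EBayes", nrow(x)),
            p, q, x$fold_change, direction,
            flags$sig01, flags$sig05, flags$fdr05)
}
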