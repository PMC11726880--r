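#' Control-group reference statistics
#'
#' Per-gene arithmetic mean and sample standard deviation (n - 1
#' denominator) of expression across the control samples only. These
#' define the discretization thresholds mean + sd (over-expression) and
#' mean - sd (under-expression).
#'
#' @param ds An [expression_dataset()] with groups attached and at least
#'   two control samples.
#' @return A list of class `control_reference` with elements `gene`,
#'   `mean`, `sd`.
#' @export
control_reference <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  ctrl <- group_matrix(ds, "control")
  if (ncol(ctrl) < 2) {
    validation_error("control reference needs >= 2 control samples")
  }
  mu <- rowMeans(ctrl)
  sd <- sqrt(rowSums((ctrl - mu)^2) / (ncol(ctrl) - 1))
  structure(list(gene = rownames(ds$values), mean = unname(mu),
                 sd = unname(sd)),
            class = "control_reference")
}

#' Discretize expression relative to the control reference
#'
#' Builds the Boolean abnormal-expression matrix for one direction, applied
#' to all samples (cases and controls alike):
#' * `over`:  1 iff the value meets or exceeds `mean + sd` (inclusive);
#' * `under`: 1 iff the value is strictly below `mean - sd`.
#'
#' Genes whose control standard deviation is zero are non-informative
#' (mean +/- 0 would flag samples vacuously) and get all-zero rows in both
#' directions.
#'
#' @param ds An [expression_dataset()].
#' @param ref A [control_reference()] built from the same gene list.
#' @param direction `"over"` or `"under"`.
#' @return An object of class `boolean_expression_matrix`: a list with the
#'   0/1 integer matrix `values` (genes x samples) and `direction`.
#' @export
discretize <- function(ds, ref, direction = c("over", "under")) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(ref, "control_reference"))
  direction <- match.arg(direction)
  if (!identical(rownames(ds$values), ref$gene)) {
    validation_error("control reference gene list does not match dataset")
  }
  # genes x samples: per-gene threshold recycles down each column
  b <- if (direction == "over") {
    ds$values >= ref$mean + ref$sd
  } else {
    ds$values < ref$mean - ref$sd
  }
  b[ref$sd == 0, ] <- FALSE
  structure(list(values = array(as.integer(b), dim = dim(b),
                                dimnames = dimnames(ds$values)),
                 direction = direction),
            class = "boolean_expression_matrix")
}

#' Split a Boolean matrix by sample group
#'
#' Column-partitions the matrix into the case and control submatrices,
#' preserving column order; concatenating the two outputs column-wise
#' reconstructs the input.
#'
#' @param b A `boolean_expression_matrix` from [discretize()].
#' @param groups Named character vector mapping each sample (column) to
#'   `"case"` or `"control"`, e.g. `ds$groups`.
#' @return A list with elements `case` and `control`, each a
#'   `boolean_expression_matrix`.
#' @export
split_by_group <- function(b, groups) {
  stopifnot(inherits(b, "boolean_expression_matrix"))
  samples <- colnames(b$values)
  if (!setequal(names(groups), samples)) {
    validation_error("group labels do not cover the matrix columns")
  }
  groups <- groups[samples]
  pick <- function(g) {
    structure(list(values = b$values[, groups == g, drop = FALSE],
                   direction = b$direction),
              class = "boolean_expression_matrix")
  }
  list(case = pick("case"), control = pick("control"))
}

#' Build a microarray game from a Boolean matrix
#'
#' Each sample j contributes its support sp(j), the set of genes flagged
#' abnormal in that sample, with k_j = |sp(j)|. The characteristic
#' function of the game over gene coalitions S is
#' v(S) = (1/m) * #\{j : sp(j) nonempty and sp(j) subset of S\},
#' i.e. the fraction of samples whose abnormality is fully explained by S.
#' Samples with empty support still count in m (they dilute all values).
#'
#' @param b A `boolean_expression_matrix`, or a plain 0/1 matrix with
#'   gene rownames.
#' @return A list of class `microarray_game`: `genes`, `n_genes`, `m`,
#'   `supports` (list of integer gene indices per sample), `k`.
#' @export
build_game <- function(b) {
  mat <- if (inherits(b, "boolean_expression_matrix")) b$values else b
  if (!is.matrix(mat) || ncol(mat) < 1 || nrow(mat) < 1) {
    validation_error("Boolean matrix must have >= 1 gene and >= 1 sample")
  }
  if (!all(mat %in% c(0L, 1L))) validation_error("matrix entries must be 0/1")
  supports <- lapply(seq_len(ncol(mat)), function(j) {
    unname(which(mat[, j] == 1L))
  })
  structure(list(genes = rownames(mat), n_genes = nrow(mat), m = ncol(mat),
                 supports = supports, k = lengths(supports)),
            class = "microarray_game")
}

# Characteristic function v(S) with S an integer index vector.
game_value <- function(game, coalition) {
  inside <- vapply(game$supports, function(sp) {
    length(sp) > 0 && all(sp %in% coalition)
  }, logical(1))
  sum(inside) / game$m
}

#' Shapley values of a microarray game (closed form)
#'
#' For microarray games the Shapley value has the exact closed form
#' `phi_g = (1/m) * sum over samples j with k_j > 0 of b_gj / k_j`:
#' each sample splits one unit of worth equally among the genes it flags.
#' The vector satisfies efficiency (`sum(phi)` equals the fraction of
#' samples with non-empty support), the dummy axiom (all-zero gene rows
#' get 0), and symmetry (identical rows get identical values).
#'
#' @param game A [build_game()] result.
#' @return Named numeric vector of per-gene Shapley values.
#' @export
shapley <- function(game) {
  stopifnot(inherits(game, "microarray_game"))
  phi <- numeric(game$n_genes)
  for (j in seq_len(game$m)) {
    kj <- game$k[j]
    if (kj > 0) phi[game$supports[[j]]] <- phi[game$supports[[j]]] + 1 / kj
  }
  stats::setNames(phi / game$m, game$genes)
}

#' Shapley values by exhaustive coalition enumeration (oracle)
#'
#' Independent of the closed form: evaluates the textbook definition
#' `phi_g = sum over coalitions S not containing g of
#' |S|! (n - |S| - 1)! / n! * (v(S + g) - v(S))` with v evaluated directly
#' from the supports, enumerating all 2^n coalitions as bitmasks. Guarded
#' to n <= 10 genes.
#'
#' @param game A [build_game()] result with at most 10 genes.
#' @return Named numeric vector of per-gene Shapley values.
#' @export
shapley_bruteforce <- function(game) {
  stopifnot(inherits(game, "microarray_game"))
  n <- game$n_genes
  if (n > 10) {
    validation_error("brute-force Shapley is limited to 10 genes (2^n coalitions)")
  }
  support_masks <- vapply(game$supports, function(sp) {
    sum(bitwShiftL(1L, sp - 1L))
  }, numeric(1))
  nonempty <- support_masks > 0
  n_coal <- bitwShiftL(1L, n)
  # v for every coalition mask: sp(j) subset of S  <=>  sp_mask & ~S == 0
  all_mask <- n_coal - 1L
  v <- vapply(seq_len(n_coal) - 1L, function(S) {
    sum(nonempty & bitwAnd(support_masks, bitwXor(all_mask, S)) == 0) / game$m
  }, numeric(1))
  fact <- factorial(0:n)
  phi <- numeric(n)
  for (g in seq_len(n)) {
    gbit <- bitwShiftL(1L, g - 1L)
    for (S in seq_len(n_coal) - 1L) {
      if (bitwAnd(S, gbit) != 0) next
      s <- sum(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) != 0)
      w <- fact[s + 1] * fact[n - s] / fact[n + 1]
      phi[g] <- phi[g] + w * (v[S + gbit + 1L] - v[S + 1L])
    }
  }
  stats::setNames(phi, game$genes)
}
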