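#' Simulation configuration
#'
#' Parameters of the synthetic case/control expression generator. The
#' defaults emulate a peripheral-blood style microarray comparison of 12
#' cases against 14 controls at 2000 genes: per-gene baselines are drawn
#' from Normal(baseline_mean, baseline_sd^2) on the log2 scale, every
#' measurement adds Normal(0, noise_sd^2) noise, and each differentially
#' expressed (DE) gene receives an additive shift of
#' `effect_size * noise_sd` in a fixed-size random subset of case samples
#' (`round(penetrance * n_case)` of them). Partial penetrance models
#' heterogeneous molecular profiles: an effect present in only some
#' patients, the regime where per-gene mean tests lose power.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group (each >= 2).
#' @param frac_de Fraction of genes that are DE; `round(n_genes * frac_de)`
#'   genes are planted.
#' @param effect_size Shift of affected samples, in units of `noise_sd`.
#' @param penetrance Fraction of case samples carrying the effect, in
#'   (0, 1].
#' @param direction_mix Fraction of DE genes shifted up (the rest down).
#' @param baseline_mean,baseline_sd Log2-scale distribution of per-gene
#'   baseline expression across genes.
#' @param noise_sd Within-gene measurement SD (log2 units).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_case = 12, n_control = 14,
                              frac_de = 0.025, effect_size = 2,
                              penetrance = 0.4, direction_mix = 0.5,
                              baseline_mean = 7, baseline_sd = 1.5,
                              noise_sd = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_case = as.integer(n_case),
              n_control = as.integer(n_control), frac_de = frac_de,
              effect_size = effect_size, penetrance = penetrance,
              direction_mix = direction_mix, baseline_mean = baseline_mean,
              baseline_sd = baseline_sd, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1) validation_error("n_genes must be positive")
  if (cfg$n_case < 2 || cfg$n_control < 2) {
    validation_error("n_case and n_control must each be >= 2")
  }
  if (frac_de < 0 || frac_de > 1) validation_error("frac_de must be in [0, 1]")
  if (penetrance <= 0 || penetrance > 1) {
    validation_error("penetrance must be in (0, 1]")
  }
  if (direction_mix < 0 || direction_mix > 1) {
    validation_error("direction_mix must be in [0, 1]")
  }
  if (baseline_sd < 0 || noise_sd < 0) {
    validation_error("baseline_sd and noise_sd must be >= 0")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic case/control dataset with known truth
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `dataset` (an [expression_dataset()] with
#'   groups attached) and `truth` (a `synthetic_truth` data frame with
#'   per-gene columns `gene`, `is_de`, `direction`, `effect_size`, and an
#'   `affected` list-column of case sample ids carrying the effect).
#' @examples
#' sim <- generate_dataset(simulation_config(n_genes = 100, seed = 7))
#' sum(sim$truth$is_de)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_de <- round(cfg$n_genes * cfg$frac_de)
  n_aff <- round(cfg$penetrance * cfg$n_case)
  if (n_de > 0 && n_aff < 1) {
    validation_error("penetrance * n_case < 1: no case sample would carry the effect")
  }
  genes <- sprintf("gene_%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
  samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
               sprintf("ctrl_%02d", seq_len(cfg$n_control)))
  n_samples <- cfg$n_case + cfg$n_control

  with_seed(cfg$seed, {
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
    # column-major fill: per-gene mean recycles correctly down each column
    values <- matrix(stats::rnorm(cfg$n_genes * n_samples, mean = mu,
                                  sd = cfg$noise_sd),
                     nrow = cfg$n_genes, ncol = n_samples,
                     dimnames = list(genes, samples))
    de_idx <- sort(sample.int(cfg$n_genes, n_de))
    n_up <- round(cfg$direction_mix * n_de)
    up_idx <- if (n_de > 0) sort(sample(de_idx, n_up)) else integer()
    direction <- rep("none", cfg$n_genes)
    direction[de_idx] <- "down"
    direction[up_idx] <- "up"
    affected <- vector("list", cfg$n_genes)
    for (g in seq_len(cfg$n_genes)) affected[[g]] <- character()
    shift <- cfg$effect_size * cfg$noise_sd
    for (g in de_idx) {
      aff <- sort(sample.int(cfg$n_case, n_aff))
      values[g, aff] <- values[g, aff] +
        if (direction[g] == "up") shift else -shift
      affected[[g]] <- samples[aff]
    }
  })

  groups <- stats::setNames(rep(c("case", "control"),
                                c(cfg$n_case, cfg$n_control)), samples)
  truth <- data.frame(gene = genes, is_de = direction != "none",
                      direction = direction,
                      effect_size = ifelse(direction == "none", 0,
                                           cfg$effect_size),
                      stringsAsFactors = FALSE)
  truth$affected <- affected
  class(truth) <- c("synthetic_truth", "data.frame")
  list(dataset = expression_dataset(values, groups), truth = truth)
}

#' Permute group labels to create an exact null dataset
#'
#' Randomly reassigns the case/control labels across samples (group sizes
#' preserved), severing any gene-group association while keeping the
#' expression values untouched. Useful for type-I-error calibration of the
#' bootstrap.
#'
#' @param ds An [expression_dataset()] with groups attached.
#' @param seed Integer seed for the permutation.
#' @return The dataset with permuted labels.
#' @export
null_permutation_dataset <- function(ds, seed) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(ds$groups)) validation_error("dataset has no group labels attached")
  perm <- with_seed(seed, sample(unname(ds$groups)))
  expression_dataset(ds$values, stats::setNames(perm, names(ds$groups)))
}

#' Write a simulated dataset (matrix, sheet, truth) to disk
#'
#' @param sim Result of [generate_dataset()].
#' @param prefix Output path prefix; writes `<prefix>_expression.tsv`,
#'   `<prefix>_samples.tsv` and `<prefix>_truth.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_simulation <- function(sim, prefix) {
  paths <- c(expression = paste0(prefix, "_expression.tsv"),
             samples = paste0(prefix, "_samples.tsv"),
             truth = paste0(prefix, "_truth.tsv"))
  write_expression_matrix(sim$dataset, paths[["expression"]])
  write_sample_sheet(sim$dataset, paths[["samples"]])
  truth <- sim$truth
  out <- cbind(gene = truth$gene,
               is_de = ifelse(truth$is_de, "TRUE", "FALSE"),
               direction = truth$direction,
               effect_size = formatC(truth$effect_size, format = "g",
                                     digits = 6),
               affected = vapply(truth$affected, paste, "", collapse = ","))
  write_tsv_safely(out, paths[["truth"]])
  invisible(paths)
}
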