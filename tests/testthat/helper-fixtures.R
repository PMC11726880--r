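# Shared fixture builders; everything is generated in code.

toy_dataset <- function(values, n_case, n_control, genes = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  samples <- c(sprintf("case_%d", seq_len(n_case)),
               sprintf("ctrl_%d", seq_len(n_control)))
  dimnames(values) <- list(genes, samples)
  groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                            samples)
  expression_dataset(values, groups)
}

random_boolean_matrix <- function(n_genes, n_samples, prob = 0.4) {
  matrix(rbinom(n_genes * n_samples, 1, prob), n_genes, n_samples,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

as_boolean <- function(mat, direction = "over") {
  structure(list(values = mat, direction = direction),
            class = "boolean_expression_matrix")
}

sort_by_gene <- function(df) df[order(df$gene), , drop = FALSE]

# independent characteristic-function evaluation for oracle checks
game_value_oracle <- function(game, coalition) {
  mean(vapply(game$supports, function(sp) {
    length(sp) > 0 && all(sp %in% coalition)
  }, logical(1)))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "cashr", mustWork = TRUE)
}

load_fixture_dataset <- function() {
  ds <- read_expression_matrix(fixture_path("synthetic_example_expression.tsv"))
  attach_groups(ds, read_sample_sheet(fixture_path("synthetic_example_samples.tsv")))
}
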