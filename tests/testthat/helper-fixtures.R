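# small deterministic fixtures shared across test files

tiny_labelled <- function() {
  seq_dataset(
    id = c("p1", "p2", "p3", "n1", "n2", "n3"),
    sequence = c("GGGCCTTTTTTT", "CCGGATTTTTTT", "GCGCGTTTTTTT",
                 "ACACACACACAC", "AGAGAGAGAGAG", "ATATATATATAT"),
    label = rep(c("positive", "negative"), each = 3)
  )
}

random_seqs <- function(n, len, seed) {
  with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)))
}

# a small, clearly separable feature task for the model zoo
separable_task <- function(n = 30, seed = 4) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(signal = ifelse(y, 1, 0) + rnorm(n, sd = 0.1),
             noise1 = rnorm(n), noise2 = rnorm(n))
  list(X = X, y = y)
}
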