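# Shared fixtures, all built in code.

toy_ref <- function() reference_sequence("GGCAUCCGAUGC", name = "toy12")

qt_ref <- function(seed = 1) make_reference(seed)

# fitness table straight from a known true landscape (no sampling noise)
truth_table <- function(land) {
  ft <- tibble::tibble(
    genotype = land$genotype, class = land$class,
    f_rep1 = land$f_true, f_mean = land$f_true
  )
  class(ft) <- c("fitness_table", class(ft))
  attr(ft, "log_base") <- 2
  ft
}

# minimal hand-built fitness table from named fitness values
mini_table <- function(f, ref) {
  ft <- tibble::tibble(
    genotype = names(f),
    class = qtsuite:::label_class(names(f)),
    f_rep1 = unname(f), f_mean = unname(f)
  )
  class(ft) <- c("fitness_table", class(ft))
  attr(ft, "log_base") <- 2
  ft
}

# counts tibble from named pre/post vectors (single replicate)
counts_from_vectors <- function(pre, post) {
  tibble::tibble(
    replicate = 1L,
    round = rep(c("pre", "post"), c(length(pre), length(post))),
    genotype = c(names(pre), names(post)),
    count = c(unname(pre), unname(post))
  )
}
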