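# Pipeline orchestration: validated run configuration, subcommand dispatch,
# logging, and atomic artifact writes. The shell entry point at
# inst/scripts/qtsuite.R is a thin wrapper over qts_run().

default_config <- function() {
  list(
    seed = 1,
    out_dir = "qtsuite_out",
    reference = NULL, # path to FASTA; NULL = synthesize from seed
    simulate = list(
      read_depth = 1e6, replicates = 3, n_products = 2000,
      triplet_error_rate = 0.074, wobble_bias = 0.7, stall_prob = 0.2,
      timecourse_A = 0.8, timecourse_k = 0.0376, timecourse_noise_sd = 0.005
    ),
    fitness = list(
      counts = NULL, pseudocount = 0.5, log_base = 2, min_count = 10
    ),
    epistasis = list(fitness = NULL, include_wobble = TRUE, threshold = 0),
    fidelity = list(
      products = NULL, expected = NULL, primer_len = 10, tail = NULL,
      method = "geometric"
    ),
    quasispecies = list(
      fitness = NULL, q_grid = c(0.9, 0.926, 0.941, 0.96, 0.974, 0.99),
      activity_threshold = -1, other_fitness = NULL, max_genotypes = 800
    ),
    kinetics = list(timecourse = NULL),
    abundance = list(fitness = NULL, cutoff = -1, pool_length = NULL)
  )
}

# recursive merge of user config over defaults; unknown keys rejected
merge_config <- function(user, defaults, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(
      "unknown config key", if (length(unknown) > 1) "s" else "", ": ",
      paste0(path, unknown, collapse = ", ")
    )
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Build a validated run configuration
#'
#' Merges a user configuration (a nested list, or a path to a JSON file with
#' the same shape) over the package defaults. Unknown keys are rejected with
#' a schema message.
#'
#' @param config Nested list or JSON path; NULL for pure defaults.
#' @param seed Optional seed override.
#' @param out_dir Optional output-directory override.
#' @return Validated configuration list.
#' @export
run_config <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(config, default_config())
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  cfg
}

run_log <- function(out_dir, subcommand, cfg) {
  lines <- c(
    sprintf("qtsuite %s", as.character(utils::packageVersion("qtsuite"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("seed: %s", cfg$seed),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "config:",
    strsplit(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE, null = "null"), "\n")[[1]]
  )
  writeLines(lines, file.path(out_dir, "run.log"))
}

load_ref <- function(cfg) {
  if (!is.null(cfg$reference)) {
    if (!file.exists(cfg$reference)) {
      stop("reference file not found: ", cfg$reference)
    }
    read_reference_fasta(cfg$reference)
  } else {
    make_reference(cfg$seed)
  }
}

artifact <- function(cfg, name) file.path(cfg$out_dir, name)

need_file <- function(path, what) {
  if (is.null(path)) stop("no ", what, " configured and default artifact absent")
  if (!file.exists(path)) stop(what, " not found: ", path)
  path
}

# prefer an explicitly configured path, else the artifact a previous
# subcommand would have written into out_dir
resolve_input <- function(cfg, configured, default_name, what) {
  p <- configured
  if (is.null(p)) p <- artifact(cfg, default_name)
  need_file(p, what)
}

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (generate every synthetic input), `fitness`,
#' `epistasis`, `fidelity`, `quasispecies`, `kinetics`, `abundance`, and
#' `all` (simulate, then fitness, epistasis, quasispecies, and fidelity on
#' the simulated products, plus kinetics and abundance). Each writes its
#' TSV/JSON artifacts into the output directory through a
#' write-then-rename so failed runs leave no partial artifact, plus a
#' `run.log` with version, seed and the full parameter echo.
#'
#' @param subcommand One of the names above.
#' @param config Nested list or JSON path (see [run_config()]).
#' @param seed,out_dir Optional overrides.
#' @return Invisibly, a character vector of written artifact paths.
#' @export
qts_run <- function(subcommand, config = NULL, seed = NULL, out_dir = NULL) {
  subcommands <- c(
    "simulate", "fitness", "epistasis", "fidelity",
    "quasispecies", "kinetics", "abundance", "all"
  )
  if (!subcommand %in% subcommands) {
    stop(
      "unknown subcommand '", subcommand, "'; expected one of: ",
      paste(subcommands, collapse = ", ")
    )
  }
  cfg <- run_config(config, seed = seed, out_dir = out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_log(cfg$out_dir, subcommand, cfg)
  steps <- if (subcommand == "all") {
    c("simulate", "fitness", "epistasis", "quasispecies", "fidelity", "kinetics", "abundance")
  } else {
    subcommand
  }
  written <- character(0)
  for (s in steps) {
    written <- c(written, switch(s,
      simulate = step_simulate(cfg),
      fitness = step_fitness(cfg),
      epistasis = step_epistasis(cfg),
      fidelity = step_fidelity(cfg),
      quasispecies = step_quasispecies(cfg),
      kinetics = step_kinetics(cfg),
      abundance = step_abundance(cfg)
    ))
  }
  invisible(c(written, file.path(cfg$out_dir, "run.log")))
}

step_simulate <- function(cfg) {
  p <- cfg$simulate
  ref <- load_ref(cfg)
  land <- simulate_true_landscape(ref, seed = cfg$seed)
  # library: wild type prominent, singles/deletions at intermediate
  # abundance, the double-mutant bulk sharing the rest uniformly
  singles <- land$genotype[land$class %in% c("single_sub", "single_del")]
  doubles <- land$genotype[land$class == "double_sub"]
  freqs <- c(
    setNames(0.05, "wt"),
    setNames(rep(0.35 / length(singles), length(singles)), singles),
    setNames(rep(0.60 / length(doubles), length(doubles)), doubles)
  )
  freqs <- freqs / sum(freqs)
  spec <- landscape_sim_spec(
    ref, land, freqs,
    read_depth = p$read_depth, replicates = p$replicates, seed = cfg$seed,
    log_base = cfg$fitness$log_base
  )
  counts <- simulate_selection_round(spec)

  # 9-nt primer prefix + 36-nt (12-triplet) synthesized region
  pspec <- product_sim_spec(
    template = ref$seq, primer_len = 9,
    triplet_error_rate = p$triplet_error_rate, wobble_bias = p$wobble_bias,
    stall_prob = p$stall_prob, n_reads = p$n_products,
    seed = cfg$seed
  )
  products <- simulate_products(pspec)

  tc <- simulate_timecourse(
    p$timecourse_A, p$timecourse_k, seq(0, 240, by = 10),
    noise_sd = p$timecourse_noise_sd, replicates = 3, seed = cfg$seed
  )

  paths <- c(
    ref = artifact(cfg, "reference.fasta"),
    land = artifact(cfg, "landscape_true.tsv"),
    counts = artifact(cfg, "counts.tsv"),
    products = artifact(cfg, "products.fastq"),
    tc = artifact(cfg, "timecourse.tsv")
  )
  write_reference_fasta(ref, paths["ref"])
  write_tsv_atomic(land, paths["land"])
  write_tsv_atomic(counts, paths["counts"])
  write_fastq(products, paths["products"])
  write_tsv_atomic(tc, paths["tc"])
  unname(paths)
}

step_fitness <- function(cfg) {
  ref <- load_ref(cfg)
  counts_path <- resolve_input(cfg, cfg$fitness$counts, "counts.tsv", "count table")
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  ft <- compute_fitness(
    counts, ref,
    pseudocount = cfg$fitness$pseudocount,
    log_base = cfg$fitness$log_base, min_count = cfg$fitness$min_count
  )
  paths <- c(artifact(cfg, "fitness.tsv"), artifact(cfg, "fitness_heatmap.tsv"))
  write_tsv_atomic(tibble::as_tibble(ft), paths[1])
  write_tsv_atomic(fitness_heatmap_data(ft), paths[2])
  paths
}

read_fitness_artifact <- function(cfg) {
  path <- resolve_input(cfg, NULL, "fitness.tsv", "fitness table")
  ft <- readr::read_tsv(path, show_col_types = FALSE)
  class(ft) <- c("fitness_table", class(ft))
  attr(ft, "log_base") <- cfg$fitness$log_base
  ft
}

step_epistasis <- function(cfg) {
  ref <- load_ref(cfg)
  ft <- if (is.null(cfg$epistasis$fitness)) {
    read_fitness_artifact(cfg)
  } else {
    ftab <- readr::read_tsv(need_file(cfg$epistasis$fitness, "fitness table"),
      show_col_types = FALSE
    )
    class(ftab) <- c("fitness_table", class(ftab))
    ftab
  }
  eps <- compute_epistasis(ft)
  ev <- pair_evidence(eps, include_wobble = cfg$epistasis$include_wobble)
  pp <- propose_pairs(ev, threshold = cfg$epistasis$threshold)
  paths <- c(
    artifact(cfg, "epistasis.tsv"), artifact(cfg, "pair_evidence.tsv"),
    artifact(cfg, "proposed_pairs.tsv"), artifact(cfg, "structure.dbn")
  )
  write_tsv_atomic(eps, paths[1])
  write_tsv_atomic(ev, paths[2])
  write_tsv_atomic(pp, paths[3])
  writeLines(c(ref$seq, dot_bracket(pp, ref$length)), paths[4])
  paths
}

step_fidelity <- function(cfg) {
  ref <- load_ref(cfg)
  products <- resolve_input(cfg, cfg$fidelity$products, "products.fastq", "product reads")
  expected <- if (is.null(cfg$fidelity$expected)) {
    ref$seq
  } else {
    read_reference_fasta(need_file(cfg$fidelity$expected, "expected product"))$seq
  }
  primer_len <- if (is.null(cfg$fidelity$expected)) 9 else cfg$fidelity$primer_len
  aln <- align_products(products, expected, primer_len, tail = cfg$fidelity$tail)
  prof <- fidelity_profile(aln, nchar(expected), primer_len,
    method = cfg$fidelity$method
  )
  spec <- error_spectrum(aln, expected, primer_len)
  stall <- stalling_profile(aln, nchar(expected), primer_len)
  paths <- c(
    artifact(cfg, "positional_fidelity.tsv"),
    artifact(cfg, "error_spectrum.tsv"),
    artifact(cfg, "stalling.tsv"),
    artifact(cfg, "fidelity_summary.json")
  )
  write_tsv_atomic(tidy(prof), paths[1])
  write_tsv_atomic(tidy(spec), paths[2])
  write_tsv_atomic(stall$rates, paths[3])
  write_json_atomic(
    c(
      as.list(glance(prof)),
      list(
        wobble_fraction = spec$wobble_fraction,
        n_substitutions = spec$n_substitutions,
        n_intermediate = stall$n_intermediate
      )
    ),
    paths[4]
  )
  paths
}

step_quasispecies <- function(cfg) {
  ref <- load_ref(cfg)
  ft <- read_fitness_artifact(cfg)
  # cap the tracked set: wild type and singles always, then the fittest
  # doubles (the active-variant mass sits near the peak; deep-valley doubles
  # are indistinguishable from the lumped compartment)
  cap <- cfg$quasispecies$max_genotypes
  core <- ft[ft$class %in% c("wt", "single_sub"), ]
  dbl <- ft[ft$class == "double_sub", ]
  if (nrow(core) + nrow(dbl) > cap) {
    dbl <- dbl[order(-dbl$f_mean), ]
    dbl <- dbl[seq_len(max(cap - nrow(core), 0)), ]
  }
  ft_capped <- dplyr::bind_rows(core, dbl)
  class(ft_capped) <- c("fitness_table", class(ft_capped))
  attr(ft_capped, "log_base") <- fitness_log_base(ft)
  sweep <- qs_sweep(
    ft_capped, ref, cfg$quasispecies$q_grid,
    log_base = cfg$fitness$log_base,
    other_fitness = cfg$quasispecies$other_fitness,
    activity_threshold = cfg$quasispecies$activity_threshold
  )
  path <- artifact(cfg, "quasispecies_sweep.tsv")
  write_tsv_atomic(sweep, path)
  path
}

step_kinetics <- function(cfg) {
  tc_path <- resolve_input(cfg, cfg$kinetics$timecourse, "timecourse.tsv", "time course")
  tc <- readr::read_tsv(tc_path, show_col_types = FALSE)
  fit <- fit_exponential(tc)
  path <- artifact(cfg, "kinetics_fit.json")
  write_json_atomic(
    list(
      A = fit$A, se_A = fit$se_A, k = fit$k, se_k = fit$se_k,
      initial_rate = fit$initial_rate, se_initial_rate = fit$se_initial_rate,
      r_squared = fit$r_squared, n = fit$n
    ),
    path
  )
  path
}

step_abundance <- function(cfg) {
  ref <- load_ref(cfg)
  ft <- read_fitness_artifact(cfg)
  prof <- tolerance_profile(ft, ref, cutoff = cfg$abundance$cutoff)
  ab <- motif_abundance(prof, pool_length = cfg$abundance$pool_length)
  paths <- c(artifact(cfg, "tolerance_profile.tsv"), artifact(cfg, "abundance.json"))
  write_tsv_atomic(tibble::as_tibble(prof), paths[1])
  write_json_atomic(as.list(ab), paths[2])
  paths
}
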