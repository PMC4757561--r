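#' Read a run configuration from YAML or JSON
#'
#' A configuration holds one command block (`simulate`, `pcurve`,
#' `vibration`, `phack` or `synth`) plus global keys `seed`, `out_dir` and
#' `alpha`. See [run_command()] for the block contents.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Run one analysis command from a configuration
#'
#' Dispatches on the single command block present in `config` and writes all
#' artifacts to `out_dir`, alongside a plain-text manifest (`manifest.txt`)
#' recording the configuration, seed, package and R versions, and row
#' counts. Re-running with the same configuration reproduces identical
#' result files.
#'
#' Command blocks:
#' \describe{
#'   \item{`simulate`}{keys of [dgp_spec()] plus `iterations`; writes
#'     per-iteration results (`simulation.csv`) and a JSON summary of the
#'     significant share and p-curve bin shares.}
#'   \item{`pcurve`}{`input` (one-column p-value CSV), `n_bins`; writes the
#'     binned curve and a JSON summary including the skew classification.}
#'   \item{`vibration`}{`input` growth CSV, column mapping (`outcome`,
#'     `interest`, `adjusters`, optional `id_col`), `n_samples`,
#'     `size_range`, `k`, optional `null_outcome` (default `TRUE`); writes
#'     per-fit results and the share/quantile summary.}
#'   \item{`phack`}{as `vibration` plus [hacking_config()] keys
#'     (`n_hacked`, `target_sign`, `full_sample`, ...); writes the harvested
#'     estimates, their p-curve, and a JSON summary.}
#'   \item{`synth`}{keys of [synthetic_growth_spec()] (or a `flavor`);
#'     writes the generated table as a growth CSV.}
#' }
#'
#' @param config a configuration list (see [read_run_config()]).
#' @param out_dir output directory; created if absent. Defaults to
#'   `config$out_dir`.
#' @return invisibly, a character vector of the files written.
#' @export
run_command <- function(config, out_dir = config$out_dir) {
  commands <- c("simulate", "pcurve", "vibration", "phack", "synth")
  present <- intersect(commands, names(config))
  if (length(present) != 1) {
    stop("usage error: exactly one command block required, found: ",
         if (length(present)) paste(present, collapse = ", ") else "none")
  }
  if (is.null(out_dir)) stop("usage error: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cmd <- present
  block <- config[[cmd]]
  seed <- config$seed
  alpha <- if (!is.null(config$alpha)) config$alpha else 0.05
  files <- switch(cmd,
    simulate = cmd_simulate(block, seed, alpha, out_dir),
    pcurve = cmd_pcurve(block, alpha, out_dir),
    vibration = cmd_vibration(block, seed, alpha, out_dir),
    phack = cmd_phack(block, seed, alpha, out_dir),
    synth = cmd_synth(block, seed, out_dir)
  )
  manifest <- file.path(out_dir, "manifest.txt")
  writeLines(c(
    paste0("command: ", cmd),
    paste0("seed: ", if (is.null(seed)) "none" else seed),
    paste0("alpha: ", alpha),
    paste0("package: phackcurve ",
           as.character(utils::packageVersion("phackcurve"))),
    paste0("r_version: ", R.version.string),
    "config:",
    paste0("  ", strsplit(yaml::as.yaml(config), "\n")[[1]]),
    "outputs:",
    paste0("  ", basename(files))
  ), manifest)
  invisible(c(files, manifest))
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

cmd_simulate <- function(block, seed, alpha, out_dir) {
  spec_args <- block[intersect(names(block), names(formals(dgp_spec)))]
  spec <- do.call(dgp_spec, spec_args)
  iterations <- if (!is.null(block$iterations)) block$iterations else 20000
  sim <- run_ovb_simulation(spec, iterations = iterations, seed = seed,
                            alpha = alpha)
  csv <- file.path(out_dir, "simulation.csv")
  utils::write.csv(as.data.frame(sim), csv, row.names = FALSE)
  pc <- pcurve(sim$p_value, alpha = alpha)
  js <- write_json_summary(list(
    iterations = nrow(sim),
    share_significant = pc$share_significant,
    bin_shares = pc$bin_shares
  ), file.path(out_dir, "simulation_summary.json"))
  c(csv, js)
}

cmd_pcurve <- function(block, alpha, out_dir) {
  p <- read_pvalues_csv(block$input)
  n_bins <- if (!is.null(block$n_bins)) block$n_bins else 5
  pc <- pcurve(p, alpha = alpha, n_bins = n_bins)
  csv <- write_pcurve_csv(pc, file.path(out_dir, "pcurve.csv"))
  js <- write_json_summary(list(
    n_total = pc$n_total, n_significant = pc$n_significant,
    share_significant = pc$share_significant,
    bin_shares = pc$bin_shares,
    skew = if (pc$n_significant > 0) skew_summary(pc) else NULL
  ), file.path(out_dir, "pcurve_summary.json"))
  c(csv, js)
}

load_mapped_table <- function(block) {
  tab <- read_growth_csv(block$input, outcome = block$outcome,
                         interest = block$interest,
                         adjusters = unlist(block$adjusters),
                         id_col = block$id_col,
                         n_min = if (!is.null(block$n_min)) block$n_min else 50)
  if (is.null(block$null_outcome) || isTRUE(block$null_outcome)) {
    construct_null_outcome(tab)$table
  } else {
    tab
  }
}

cmd_vibration <- function(block, seed, alpha, out_dir) {
  tab <- load_mapped_table(block)
  vib <- vibration_analysis(
    tab,
    n_samples = if (!is.null(block$n_samples)) block$n_samples else 100,
    size_range = if (!is.null(block$size_range)) unlist(block$size_range)
                 else c(50, nrow(tab)),
    k = if (!is.null(block$k)) block$k else 6,
    alpha = alpha, seed = seed)
  csv <- file.path(out_dir, "vibration.csv")
  utils::write.csv(as.data.frame(vib), csv, row.names = FALSE)
  js <- write_json_summary(list(
    n_samples = attr(vib, "n_samples"), n_models = attr(vib, "n_models"),
    n_fits = attr(vib, "n_attempted"), n_skipped = nrow(attr(vib, "skipped")),
    shares = as.list(attr(vib, "shares")),
    quantiles = attr(vib, "quantiles")
  ), file.path(out_dir, "vibration_summary.json"))
  c(csv, js)
}

cmd_phack <- function(block, seed, alpha, out_dir) {
  tab <- load_mapped_table(block)
  cfg <- hacking_config(
    alpha = alpha,
    target_sign = if (!is.null(block$target_sign)) block$target_sign else -1,
    n_hacked = if (!is.null(block$n_hacked)) block$n_hacked else 1000,
    sample_size_range = if (!is.null(block$sample_size_range))
      unlist(block$sample_size_range) else c(50, nrow(tab)),
    k = if (!is.null(block$k)) block$k else 6,
    full_sample = isTRUE(block$full_sample),
    max_attempts = if (!is.null(block$max_attempts)) block$max_attempts
                   else 100 * (if (!is.null(block$n_hacked)) block$n_hacked else 1000),
    seed = seed)
  hacked <- phack_search(tab, cfg)
  csv <- file.path(out_dir, "hacked_estimates.csv")
  utils::write.csv(as.data.frame(hacked), csv, row.names = FALSE)
  pc <- pcurve(hacked$p_value, alpha = alpha)
  pcsv <- write_pcurve_csv(pc, file.path(out_dir, "hacked_pcurve.csv"))
  js <- write_json_summary(list(
    n_hacked = nrow(hacked), attempts = attr(hacked, "attempts"),
    bin_shares = pc$bin_shares, skew = skew_summary(pc)
  ), file.path(out_dir, "phack_summary.json"))
  c(csv, pcsv, js)
}

cmd_synth <- function(block, seed, out_dir) {
  spec <- if (!is.null(block$flavor)) {
    default_growth_spec(block$flavor)
  } else {
    spec_from_config(block)
  }
  tab <- generate_growth_table(spec, seed = seed)
  csv <- write_growth_csv(tab, file.path(out_dir, "synthetic_growth.csv"))
  csv
}
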