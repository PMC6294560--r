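# End-to-end orchestration of the two analysis tracks, producing the
# file outputs a command-line run would leave behind, plus a
# machine-readable provenance record.  Outputs are byte-identical across
# repeat runs with the same inputs and seed.

write_provenance <- function(out_dir, subcommand, inputs, parameters, seed) {
  record <- list(
    tool = "topokaryo",
    version = as.character(utils::packageVersion("topokaryo")),
    subcommand = subcommand,
    inputs = inputs,
    parameters = parameters,
    seed = seed
  )
  path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(record, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    rlang::abort(paste0("cannot create output directory ", out_dir))
  }
  out_dir
}

#' Run the banding-pattern analysis track
#'
#' Reads a per-spread annotation table, aggregates banding-pattern counts
#' per condition/replicate, computes per-domain marginals, tests the
#' pooled counts against the independence expectation, fits the three
#' association models, and writes all results (plus a provenance record)
#' to `out_dir`.
#'
#' @param spreads Path to a spread TSV (see [read_spread_table()]) or a
#'   spread tibble.
#' @param out_dir Output directory (created if needed).
#' @param condition Optional condition filter; an empty selection is an
#'   error.
#' @param alpha Significance level for per-pattern flags.
#' @param seed Recorded in the provenance (the analysis itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `marginals`, `gof`, `fits`) and the written `files`.
#' @export
run_patterns <- function(spreads, out_dir, condition = NULL, alpha = 0.05,
                         seed = NULL) {
  input_path <- if (is.character(spreads)) spreads else NA_character_
  if (is.character(spreads)) {
    if (!file.exists(spreads)) {
      rlang::abort(paste0("spread table not found: ", spreads))
    }
    spreads <- read_spread_table(spreads)
  }
  ensure_out_dir(out_dir)
  if (!is.null(condition)) {
    spreads_sel <- dplyr::filter(spreads, .data$condition %in% !!condition)
    if (nrow(spreads_sel) == 0) {
      rlang::abort("no spreads match the requested condition")
    }
  } else {
    spreads_sel <- spreads
  }

  counts <- aggregate_patterns(spreads_sel)
  marg <- condition_marginals(spreads_sel)
  gof <- pattern_gof_test(counts, alpha = alpha)
  fits <- fit_association_models(counts)

  files <- c(
    pattern_counts = file.path(out_dir, "pattern_counts.tsv"),
    marginals = file.path(out_dir, "marginals.tsv"),
    gof = file.path(out_dir, "observed_vs_expected.tsv"),
    gof_global = file.path(out_dir, "observed_vs_expected_global.tsv"),
    model_fits = file.path(out_dir, "model_fits.tsv")
  )
  write_pattern_counts(counts, files[["pattern_counts"]])
  readr::write_tsv(dplyr::select(marg, -"replicate_freqs"), files[["marginals"]],
                   progress = FALSE)
  readr::write_tsv(tidy(gof), files[["gof"]], progress = FALSE)
  readr::write_tsv(glance(gof), files[["gof_global"]], progress = FALSE)
  readr::write_tsv(glance(fits), files[["model_fits"]], progress = FALSE)
  files <- c(files, provenance = write_provenance(
    out_dir, "patterns",
    inputs = list(spreads = input_path),
    parameters = list(condition = condition, alpha = alpha,
                      n_spreads = nrow(spreads_sel)),
    seed = seed
  ))
  invisible(list(counts = counts, marginals = marg, gof = gof, fits = fits,
                 files = files))
}

#' Run the genomic enrichment track
#'
#' Reads IP and input fragment BED files and a LAD BED, bins fragments by
#' midpoint, computes the depth-normalized smoothed log2 IP/input track,
#' aggregates it into windows, and tests LAD-overlapping windows against
#' the genome by Monte Carlo.  Writes the log2 track (bedGraph), the
#' window table, the test summary, the per-LAD fraction-positive summary
#' and a provenance record to `out_dir`.
#'
#' @param ip,input Paths to fragment BED files (or interval tibbles).
#' @param lads Path to a LAD BED file (or an interval tibble).
#' @param genome Path to a headerless chrom-sizes TSV (or a tibble with
#'   `chrom`, `length`).
#' @param out_dir Output directory (created if needed).
#' @param bin_width,window_width Bin and window widths in bp (study:
#'   10 kb bins, 100 kb windows).
#' @param smooth_bins Adjacent bins for the moving average (study: 5).
#' @param pseudocount Pseudocount for the log2 ratio.
#' @param iterations Monte Carlo draws (study: 10 000).
#' @param seed Integer seed for the Monte Carlo test.
#' @return Invisibly, a list with `track`, `windows`, `mc`,
#'   `fraction_positive` and the written `files`.
#' @export
run_enrich <- function(ip, input, lads, genome, out_dir,
                       bin_width = 10000, window_width = 100000,
                       smooth_bins = 5, pseudocount = 0.5,
                       iterations = 10000, seed = 1) {
  paths <- list(ip = ip, input = input, lads = lads, genome = genome)
  load_file <- function(x, reader, what) {
    if (is.character(x)) {
      if (!file.exists(x)) rlang::abort(paste0(what, " file not found: ", x))
      reader(x)
    } else x
  }
  genome <- load_file(genome, read_genome, "genome")
  ip <- load_file(ip, function(p) read_bed(p, genome), "IP fragment")
  input <- load_file(input, function(p) read_bed(p, genome), "input fragment")
  lads <- load_file(lads, function(p) read_bed(p, genome), "LAD")
  ensure_out_dir(out_dir)

  ip_track <- bin_fragments(ip, genome, bin_width)
  input_track <- bin_fragments(input, genome, bin_width)
  track <- log2_ratio_track(ip_track, input_track, pseudocount = pseudocount,
                            smooth_bins = smooth_bins)
  windows <- window_means(track, window_width) |>
    region_overlap_mask(lads)
  mc <- monte_carlo_enrichment(windows, iterations = iterations, seed = seed)
  fp <- fraction_positive(track, lads)

  files <- c(
    log2_track = file.path(out_dir, "log2_ratio.bedGraph"),
    windows = file.path(out_dir, "window_means.tsv"),
    mc = file.path(out_dir, "monte_carlo.tsv"),
    fraction_positive = file.path(out_dir, "fraction_positive.tsv")
  )
  write_bedgraph(track, files[["log2_track"]])
  readr::write_tsv(windows, files[["windows"]], progress = FALSE)
  readr::write_tsv(glance(mc), files[["mc"]], progress = FALSE)
  readr::write_tsv(fp, files[["fraction_positive"]], progress = FALSE)
  files <- c(files, provenance = write_provenance(
    out_dir, "enrich",
    inputs = purrr::map(paths, function(x) if (is.character(x)) x else NA_character_),
    parameters = list(bin_width = bin_width, window_width = window_width,
                      smooth_bins = smooth_bins, pseudocount = pseudocount,
                      iterations = iterations),
    seed = seed
  ))
  invisible(list(track = track, windows = windows, mc = mc,
                 fraction_positive = fp, files = files))
}
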