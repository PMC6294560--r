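# Per-mitotic-spread annotation tables: one row per scored spread with the
# binary labeling state of each emerin-associated domain.  Constant
# domains are declared by column name (EAD_C, EAD_C2, ...), variable
# domains as EAD_V1..EAD_VK; the variable columns define the banding
# pattern.

spread_meta_cols <- c("spread_id", "condition", "replicate")

#' Identify domain columns of a spread table
#'
#' @param spreads A spread annotation data frame.
#' @return A list with character vectors `constant` and `variable`
#'   (variable columns sorted by domain index).
#' @export
domain_columns <- function(spreads) {
  nm <- names(spreads)
  dom <- nm[startsWith(nm, "EAD_")]
  variable <- dom[grepl("^EAD_V[0-9]+$", dom)]
  variable <- variable[order(as.integer(sub("^EAD_V", "", variable)))]
  list(constant = setdiff(dom, variable), variable = variable)
}

validate_spreads <- function(spreads, file = NULL) {
  where <- function(rows) {
    # +1 for the header line when reporting file positions
    if (is.null(file)) sprintf("row %d", rows[1])
    else sprintf("%s, line %d", file, rows[1] + 1L)
  }
  missing <- setdiff(spread_meta_cols, names(spreads))
  if (length(missing) > 0) {
    rlang::abort(paste0("spread table is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  doms <- domain_columns(spreads)
  if (length(doms$variable) == 0) {
    rlang::abort("spread table has no variable domain columns (EAD_V1, EAD_V2, ...)")
  }
  rep_ok <- !is.na(spreads$replicate) & spreads$replicate == floor(spreads$replicate) &
    spreads$replicate >= 1
  if (!all(rep_ok)) {
    rlang::abort(paste0("replicate must be a positive integer (", where(which(!rep_ok)), ")"))
  }
  for (col in c(doms$constant, doms$variable)) {
    v <- spreads[[col]]
    bad <- is.na(v) | !(v %in% c(0, 1))
    if (any(bad)) {
      rlang::abort(sprintf("domain state in column %s must be 0 or 1 (%s)",
                           col, where(which(bad))))
    }
  }
  dplyr::mutate(
    as_tibble(spreads),
    replicate = as.integer(.data$replicate),
    dplyr::across(dplyr::all_of(c(doms$constant, doms$variable)), as.integer)
  )
}

#' Read a per-spread annotation table
#'
#' Expects a TSV with header columns `spread_id`, `condition`,
#' `replicate`, followed by one 0/1 column per domain (`EAD_C`,
#' `EAD_V1`, ..., `EAD_VK`).  Malformed rows (non-binary states,
#' non-integer replicates) raise an error naming the offending line.
#'
#' @param path Path to the TSV file.
#' @return A validated tibble, one row per spread.
#' @export
read_spread_table <- function(path) {
  spreads <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_spreads(spreads, file = path)
}

#' Write a per-spread annotation table
#'
#' @param spreads Spread annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spread_table <- function(spreads, path) {
  readr::write_tsv(validate_spreads(spreads), path, progress = FALSE)
  invisible(path)
}

#' Aggregate spreads into banding-pattern counts
#'
#' Collapses per-spread annotations into counts over the `2^K` banding
#' patterns of the variable domains, per `(condition, replicate)`.  The
#' sum of counts equals the number of selected spreads.  Constant domains
#' do not enter the pattern; their observed frequencies are attached as
#' the `"constant_domains"` attribute (and are reported by
#' [condition_marginals()]).
#'
#' @param spreads Spread annotation tibble.
#' @param condition Optional condition label(s) to filter on; an empty
#'   selection is an error.
#' @return A tibble with columns `condition`, `replicate`, `pattern_id`,
#'   `bp_label`, `count` (all `2^K` ids present per group, zeros allowed).
#' @examples
#' spreads <- simulate_spreads(independence_model(c(0.36, 0.235, 0.14)),
#'                             n_spreads = 50, n_replicates = 2, seed = 1)
#' aggregate_patterns(spreads)
#' @export
aggregate_patterns <- function(spreads, condition = NULL) {
  spreads <- validate_spreads(spreads)
  if (!is.null(condition)) {
    spreads <- dplyr::filter(spreads, .data$condition %in% !!condition)
  }
  if (nrow(spreads) == 0) {
    rlang::abort("no spreads match the requested condition")
  }
  doms <- domain_columns(spreads)
  K <- length(doms$variable)
  spreads$pattern_id <- pattern_ids(spreads[doms$variable])
  pats <- enumerate_patterns(K)
  counted <- dplyr::count(spreads, .data$condition, .data$replicate,
                          .data$pattern_id, name = "count")
  grid <- tidyr::crossing(
    dplyr::distinct(spreads, .data$condition, .data$replicate),
    pattern_id = pats$pattern_id
  )
  counts <- grid |>
    dplyr::left_join(counted, by = c("condition", "replicate", "pattern_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::left_join(dplyr::select(pats, "pattern_id", "bp_label"), by = "pattern_id") |>
    dplyr::select("condition", "replicate", "pattern_id", "bp_label", "count") |>
    dplyr::arrange(.data$condition, .data$replicate, .data$pattern_id)
  if (length(doms$constant) > 0) {
    attr(counts, "constant_domains") <- spreads |>
      tidyr::pivot_longer(dplyr::all_of(doms$constant),
                          names_to = "domain", values_to = "state") |>
      dplyr::group_by(.data$condition, .data$replicate, .data$domain) |>
      dplyr::summarise(frequency = mean(.data$state), n = dplyr::n(),
                       .groups = "drop")
  }
  counts
}

#' Per-condition domain association summaries
#'
#' For every condition and domain (constant and variable), computes the
#' per-replicate association frequencies, their mean and standard error
#' across replicates (SEM = sd / sqrt(r); `NA` for a single replicate),
#' and the pooled frequency over all spreads.
#'
#' @param spreads Spread annotation tibble.
#' @return A tibble with one row per `(condition, domain)`: `mean_freq`,
#'   `sem`, `pooled_freq`, `n_replicates`, `n_spreads`, `is_constant`
#'   (declared by column naming), plus a `replicate_freqs` list-column.
#' @export
condition_marginals <- function(spreads) {
  spreads <- validate_spreads(spreads)
  doms <- domain_columns(spreads)
  per_rep <- spreads |>
    tidyr::pivot_longer(dplyr::all_of(c(doms$constant, doms$variable)),
                        names_to = "domain", values_to = "state") |>
    dplyr::group_by(.data$condition, .data$domain, .data$replicate) |>
    dplyr::summarise(freq = mean(.data$state), n = dplyr::n(), .groups = "drop")
  per_rep |>
    dplyr::group_by(.data$condition, .data$domain) |>
    dplyr::summarise(
      mean_freq = mean(.data$freq),
      sem = if (dplyr::n() > 1) sd(.data$freq) / sqrt(dplyr::n()) else NA_real_,
      pooled_freq = sum(.data$freq * .data$n) / sum(.data$n),
      n_replicates = dplyr::n(),
      n_spreads = sum(.data$n),
      replicate_freqs = list(.data$freq),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_constant = .data$domain %in% doms$constant) |>
    dplyr::arrange(.data$condition, .data$domain)
}

#' Flag domains observed associated in every spread
#'
#' Helper for schema checking: returns the domain columns whose observed
#' association frequency is exactly 1 across all selected spreads (the
#' behaviour expected of a constant domain, EAD_C).
#'
#' @param spreads Spread annotation tibble.
#' @return Character vector of domain column names.
#' @export
infer_constant_domains <- function(spreads) {
  spreads <- validate_spreads(spreads)
  doms <- domain_columns(spreads)
  all_doms <- c(doms$constant, doms$variable)
  freqs <- vapply(all_doms, function(d) mean(spreads[[d]]), numeric(1))
  all_doms[freqs == 1]
}

#' Read/write banding-pattern count tables
#'
#' Pattern distributions are exchanged as TSV with columns `condition`,
#' `replicate`, `pattern_id`, `count` (and optionally `bp_label`).
#'
#' @param path TSV path.
#' @return `read_pattern_counts()` returns a tibble;
#'   `write_pattern_counts()` returns `path` invisibly.
#' @export
read_pattern_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("condition", "replicate", "pattern_id", "count")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("pattern count table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname read_pattern_counts
#' @param counts Pattern count tibble.
#' @export
write_pattern_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}
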