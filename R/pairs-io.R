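# Cause-effect-pairs benchmark plumbing: plain-text two-column pair files
# (one observation per line, X then Y), a per-directory metadata table with
# ground truth and weights, the standard multivariate exclusions, and
# weighted / unweighted accuracy.

#' Read a two-column pair file
#'
#' The cause-effect-pairs dialect: whitespace-separated numeric columns, one
#' observation per line, column 1 the putative cause X and column 2 the
#' effect Y. Scientific notation is accepted. Files with more than two
#' columns describe multivariate problems and are rejected.
#'
#' @param path Path to a text file.
#' @return A tibble with columns `x` and `y`.
#' @export
read_pair_file <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("pair file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop_format(sprintf("pair file is empty: %s", path))
  tokens <- strsplit(trimws(lines[keep]), "[ \t]+")
  widths <- lengths(tokens)
  if (any(widths > 2L)) {
    stop_multivariate(sprintf(
      "%s: line %d has %d columns; only bivariate (two-column) pairs are supported.",
      path, keep[which(widths > 2L)[1L]], widths[widths > 2L][1L]))
  }
  if (any(widths < 2L)) {
    stop_format(sprintf("%s: line %d has fewer than two columns.",
                        path, keep[which(widths < 2L)[1L]]))
  }
  flat <- unlist(tokens)
  vals <- suppressWarnings(as.numeric(flat))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop_format(sprintf("%s: non-numeric token '%s' on line %d.",
                        path, flat[bad], keep[ceiling(bad / 2)]))
  }
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  tibble::tibble(x = m[, 1L], y = m[, 2L])
}

#' Write a bivariate sample as a pair file
#'
#' Values are printed with 17 significant digits, so reading the file back
#' reproduces them bit-exactly.
#'
#' @param data Data frame whose first two numeric columns are X and Y.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_file <- function(data, path) {
  x <- data[[1L]]; y <- data[[2L]]
  writeLines(sprintf("%.17g %.17g", x, y), path)
  invisible(path)
}

#' Default multivariate exclusions for the 100-pair benchmark
#'
#' Pairs 52-55, 70-71 and 81-83 of the benchmark are multivariate problems
#' and are excluded from bivariate analysis.
#'
#' @return Integer vector of pair numbers.
#' @export
default_exclusions <- function() c(52:55, 70:71, 81:83)

normalize_pair_num <- function(id) {
  num <- suppressWarnings(as.integer(gsub("\\D", "", as.character(id))))
  num
}

pair_id_of <- function(num) sprintf("pair%04d", num)

#' Load a cause-effect-pairs benchmark directory
#'
#' Reads the metadata table (one row per pair: id, ground-truth direction,
#' weight), drops the excluded ids, and loads each remaining pair file. The
#' metadata dialect varies across benchmark versions, so the column names
#' are mappable via `col_map`. Truths are accepted as `"x->y"` / `"y->x"`
#' (also `"1"` / `"2"` for first-column-causes / second-column-causes).
#' Pair files with more than two columns are auto-excluded with a warning
#' even when not on the exclusion list.
#'
#' @param dir_path Directory containing files `<id>.txt`.
#' @param meta_path Path to the delimited metadata table (header row;
#'   whitespace- or comma-separated).
#' @param exclusions Pair numbers (or ids) to drop; defaults to
#'   [default_exclusions()].
#' @param col_map Named list mapping the roles `id`, `truth`, `weight` to
#'   metadata column names.
#' @return A tibble with one row per included pair: `pair_id`, `truth`,
#'   `weight`, `n`, and a `data` list-column of samples; excluded ids are
#'   attached as attribute `"excluded_ids"`.
#' @export
load_benchmark <- function(dir_path, meta_path,
                           exclusions = default_exclusions(),
                           col_map = list(id = "id", truth = "truth",
                                          weight = "weight")) {
  if (!file.exists(meta_path)) {
    stop_missing_meta(sprintf("metadata table not found: %s", meta_path))
  }
  meta <- utils::read.table(meta_path, header = TRUE,
                            sep = if (grepl(",", readLines(meta_path, n = 1L))) "," else "",
                            stringsAsFactors = FALSE)
  for (role in c("id", "truth", "weight")) {
    if (!col_map[[role]] %in% names(meta)) {
      stop_missing_meta(sprintf("metadata lacks the '%s' column (mapped to '%s').",
                                role, col_map[[role]]))
    }
  }
  ids <- meta[[col_map$id]]
  nums <- normalize_pair_num(ids)
  truth_raw <- tolower(trimws(as.character(meta[[col_map$truth]])))
  truth <- dplyr::case_when(
    truth_raw %in% c("x->y", "1") ~ "x->y",
    truth_raw %in% c("y->x", "2") ~ "y->x",
    TRUE ~ NA_character_
  )
  if (anyNA(truth)) {
    stop_missing_meta(sprintf("unrecognized ground-truth value '%s'.",
                              truth_raw[is.na(truth)][1L]))
  }
  weight <- as.numeric(meta[[col_map$weight]])
  if (anyNA(weight) || any(weight <= 0)) {
    stop_missing_meta("pair weights must be positive numbers.")
  }
  excl_nums <- normalize_pair_num(exclusions)
  excluded <- pair_id_of(nums[nums %in% excl_nums])
  keep <- !(nums %in% excl_nums)
  # Map (not purrr) so loader errors keep their condition classes unwrapped
  records <- Map(
    function(pair_id, truth, weight) {
      path <- file.path(dir_path, paste0(pair_id, ".txt"))
      if (!file.exists(path)) {
        stop_missing_meta(sprintf("pair '%s' is listed in the metadata but %s does not exist.",
                                  pair_id, path))
      }
      sample <- tryCatch(read_pair_file(path),
                         liv_error_multivariate = function(e) NULL)
      tibble::tibble(pair_id = pair_id, truth = truth, weight = weight,
                     n = if (is.null(sample)) NA_integer_ else nrow(sample),
                     data = list(sample))
    },
    pair_id_of(nums[keep]), truth[keep], weight[keep])
  out <- dplyr::bind_rows(records)
  multi <- out$pair_id[vapply(out$data, is.null, logical(1L))]
  if (length(multi) > 0L) {
    warn(sprintf("auto-excluding multivariate pair file(s): %s",
                 paste(multi, collapse = ", ")),
         class = "liv_warn_auto_excluded")
    excluded <- c(excluded, multi)
    out <- out[!out$pair_id %in% multi, , drop = FALSE]
  }
  attr(out, "excluded_ids") <- sort(unique(excluded))
  out
}

#' Run the pipeline over a loaded benchmark and score it
#'
#' Applies [liv_discover()] to every pair and computes the unweighted and
#' weighted accuracy against the ground truth. A common-cause verdict
#' counts as incorrect against a directional truth unless the forced-choice
#' rule is used (which never produces one).
#'
#' @param records Tibble from [load_benchmark()] (or of the same shape).
#' @param k_clusters,alpha,folds,test,forced,seed Pipeline settings passed
#'   to [liv_discover()].
#' @return A `liv_benchmark`: per-pair tibble plus accuracy summaries.
#' @export
evaluate_benchmark <- function(records, k_clusters = 15L, alpha = 0.05,
                               folds = 10L, test = "auto", forced = FALSE,
                               seed = 1L) {
  if (nrow(records) == 0L) stop_format("no pair records to evaluate.")
  per_pair <- Map(
    function(pair_id, truth, weight, data, i) {
      fit <- liv_discover(data, k_clusters = k_clusters, alpha = alpha,
                          folds = folds, test = test, forced = forced,
                          seed = derive_seed(seed, "pair", i))
      g <- glance(fit)
      tibble::tibble(pair_id = pair_id, truth = truth, weight = weight,
                     verdict = g$direction,
                     p_forward = g$mean_p_forward,
                     p_backward = g$mean_p_backward,
                     correct = g$direction == truth)
    },
    records$pair_id, records$truth, records$weight, records$data,
    seq_len(nrow(records)))
  per_pair <- dplyr::bind_rows(per_pair)
  structure(
    list(per_pair = per_pair,
         unweighted_accuracy = mean(per_pair$correct),
         weighted_accuracy = sum(per_pair$weight * per_pair$correct) /
           sum(per_pair$weight),
         n_pairs_used = nrow(per_pair),
         excluded_ids = attr(records, "excluded_ids") %||% character(0)),
    class = "liv_benchmark"
  )
}

#' @export
print.liv_benchmark <- function(x, ...) {
  cat(sprintf("Cause-effect-pairs benchmark: %d pairs used (%d excluded)\n",
              x$n_pairs_used, length(x$excluded_ids)))
  cat(sprintf("  unweighted accuracy: %.3f\n", x$unweighted_accuracy))
  cat(sprintf("  weighted accuracy:   %.3f\n", x$weighted_accuracy))
  invisible(x)
}

#' @method tidy liv_benchmark
#' @export
tidy.liv_benchmark <- function(x, ...) x$per_pair

#' @method glance liv_benchmark
#' @export
glance.liv_benchmark <- function(x, ...) {
  tibble::tibble(unweighted_accuracy = x$unweighted_accuracy,
                 weighted_accuracy = x$weighted_accuracy,
                 n_pairs_used = x$n_pairs_used,
                 n_excluded = length(x$excluded_ids))
}

#' Per-pair p-value differences for a benchmark run
#'
#' Bar chart of `p_forward - p_backward` per pair: positive bars favor
#' X -> Y.
#'
#' @param object A `liv_benchmark`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot liv_benchmark
#' @export
autoplot.liv_benchmark <- function(object, ...) {
  df <- object$per_pair |>
    dplyr::mutate(p_diff = .data$p_forward - .data$p_backward)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_id, y = .data$p_diff,
                                   fill = .data$correct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "p(forward) - p(backward)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Write a JSON summary of a benchmark run
#'
#' @param result A `liv_benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_summary <- function(result, path) {
  jsonlite::write_json(
    list(unweighted_accuracy = result$unweighted_accuracy,
         weighted_accuracy = result$weighted_accuracy,
         n_pairs_used = result$n_pairs_used,
         excluded_ids = as.list(result$excluded_ids),
         per_pair = result$per_pair),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Write a synthetic cause-effect-pairs benchmark
#'
#' Generates a labelled benchmark directory from the shipped trimodal
#' linear-Gaussian chain model: half the pairs are simulated as X -> Y,
#' half as Y -> X, each written in the two-column pair-file dialect
#' together with a metadata table (`pairmeta.txt`: id, truth, weight).
#' Weights alternate between 1 and 2 so weighted and unweighted accuracy
#' differ. The data are synthetic stand-ins for the real benchmark, useful
#' for self-contained tests of the full pipeline.
#'
#' @param dir_path Output directory (created if missing).
#' @param n_pairs Number of pairs (even; default 20).
#' @param n Observations per pair.
#' @param seed Integer master seed.
#' @param config Template [continuous_scm_config()]; its `structure`, `n`
#'   and `seed` are overridden per pair.
#' @return The metadata path, invisibly.
#' @export
write_synthetic_benchmark <- function(dir_path, n_pairs = 20L, n = 1000L,
                                      seed = 1L, config = continuous_scm_config()) {
  stopifnot(n_pairs >= 2L, n_pairs %% 2L == 0L)
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  meta <- purrr::map(seq_len(n_pairs), function(i) {
    cfg <- config
    cfg$structure <- if (i <= n_pairs / 2L) "chain_x_to_y" else "chain_y_to_x"
    cfg$n <- as.integer(n)
    cfg$seed <- derive_seed(seed, "pair", i)
    sim <- simulate_continuous(cfg)
    write_pair_file(sim[, c("x", "y")],
                    file.path(dir_path, paste0(pair_id_of(i), ".txt")))
    tibble::tibble(id = pair_id_of(i),
                   truth = if (cfg$structure == "chain_x_to_y") "x->y" else "y->x",
                   weight = 1 + (i %% 2L))
  })
  meta_path <- file.path(dir_path, "pairmeta.txt")
  utils::write.table(dplyr::bind_rows(meta), meta_path, row.names = FALSE,
                     quote = FALSE)
  invisible(meta_path)
}
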