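# Ranking of fusion candidates under one or more metrics, with optional
# rank agreement (Kendall tau, Spearman rho) against a reference ordering —
# the protocol used to compare objective metrics with a subjective rank.

#' Rank fusion candidates under one or more metrics
#'
#' Scores every fused candidate with each requested metric and assigns
#' 1-based ranks, rank 1 being the largest metric value (best). Ties are
#' broken deterministically by input order and flagged in the `tied`
#' column. If a reference ordering is supplied, Kendall's tau and
#' Spearman's rho between the metric ranking and the reference are
#' reported.
#'
#' @param a,b Source images.
#' @param fused A [fusion_set()] or named list of at least two fused
#'   images with unique labels.
#' @param metrics Character vector of metric names (see
#'   [fusion_metric()]).
#' @param reference_rank Optional character vector of labels ordered best
#'   to worst (e.g. a subjective rank).
#' @param alpha Arimoto order (default 1.5).
#' @param q Tsallis order (default 1.85).
#' @param bins Histogram bins (default 256).
#' @return Named list of `ranking_report` objects, one per metric: a data
#'   frame `rows` (label, value, rank, tied) plus `kendall_tau` and
#'   `spearman_rho` (NA without a reference).
#' @export
rank_fusions <- function(a, b, fused,
                         metrics = c("arimoto", "mi", "nmi", "tsallis",
                                     "petrovic"),
                         reference_rank = NULL, alpha = 1.5, q = 1.85,
                         bins = 256L) {
  fl <- fused_list(fused)
  if (length(fl) < 2L) stop("need at least two fused candidates")
  labels <- names(fl)
  if (!is.null(reference_rank)) {
    if (!setequal(reference_rank, labels)) {
      stop("reference_rank must be a permutation of the candidate labels")
    }
  }
  reports <- lapply(metrics, function(m) {
    vals <- vapply(fl, function(img) {
      fusion_metric(a, b, img, metric = m, alpha = alpha, q = q,
                    bins = bins)$value
    }, numeric(1))
    # rank 1 = largest; ties broken by input order ("first")
    rk <- rank(-vals, ties.method = "first")
    tied <- duplicated(vals) | duplicated(vals, fromLast = TRUE)
    rows <- data.frame(label = labels, value = unname(vals),
                       rank = as.integer(rk), tied = tied,
                       stringsAsFactors = FALSE)
    tau <- rho <- NA_real_
    if (!is.null(reference_rank)) {
      ref_pos <- match(labels, reference_rank)
      tau <- stats::cor(rk, ref_pos, method = "kendall")
      rho <- stats::cor(rk, ref_pos, method = "spearman")
    }
    structure(list(metric = m, rows = rows,
                   reference_rank = reference_rank,
                   kendall_tau = tau, spearman_rho = rho),
              class = "ranking_report")
  })
  names(reports) <- metrics
  reports
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("Ranking under metric '%s'\n", x$metric))
  ord <- order(x$rows$rank)
  print(x$rows[ord, ], row.names = FALSE)
  if (!is.na(x$kendall_tau)) {
    cat(sprintf("Kendall tau = %.4f, Spearman rho = %.4f vs reference\n",
                x$kendall_tau, x$spearman_rho))
  }
  invisible(x)
}

#' Write ranking reports to CSV or JSON
#'
#' The JSON round-trips: values are written at full precision.
#'
#' @param reports Output of [rank_fusions()].
#' @param path Output file; format chosen by extension (`.csv`, `.json`).
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(reports, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- do.call(rbind, lapply(reports, function(r) {
      cbind(metric = r$metric, r$rows,
            kendall_tau = r$kendall_tau, spearman_rho = r$spearman_rho)
    }))
    utils::write.csv(tab, path, row.names = FALSE)
  } else if (ext == "json") {
    payload <- lapply(reports, function(r) {
      list(metric = r$metric, rows = r$rows,
           kendall_tau = r$kendall_tau, spearman_rho = r$spearman_rho)
    })
    # I(17) significant digits: doubles survive the round trip bit-for-bit
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         na = "null")
  } else {
    stop("unsupported report format")
  }
  invisible(path)
}

#' Read a key = value configuration file
#'
#' A minimal TOML-style reader for tool defaults: one `key = value` pair
#' per line, `#` comments, numeric values parsed as numbers.
#'
#' @param path Configuration file.
#' @return Named list of values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
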