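#' Read a multivariate time series from CSV
#'
#' One row per sampling occasion, one numeric column per variable; the
#' columns `t`, `day`, `beep` and `phase` are recognized by name as
#' occasion metadata and ground-truth labels. A `t` column is added
#' (1..n) when absent.
#'
#' @param path Path to a CSV file with a header row.
#' @return A series tibble.
#' @export
read_timeseries_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(data) == 0) stop("empty series file: ", path, call. = FALSE)
  vars <- setdiff(names(data), RESERVED_COLS)
  bad <- vars[!vapply(data[vars], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric variable columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"t" %in% names(data)) data$t <- seq_len(nrow(data))
  dplyr::relocate(data, "t")
}

# Plain-list views of result objects for serialization.
result_list <- function(x) UseMethod("result_list")

#' @export
result_list.kcp_ar <- function(x) {
  list(
    type = "kcp_ar",
    p_value = x$p_value, p_value_plain = x$p_value_plain,
    statistic = x$statistic, selected_k = x$selected_k,
    change_points = x$change_points,
    boundaries_windows = x$boundaries,
    rmin = as.list(x$rmin),
    grid = x$grid,
    phase_autocorrelations = x$phase_autocorrelations,
    config = x$config
  )
}

#' @export
result_list.rsar <- function(x) {
  list(
    type = "rsar",
    regimes = x$R, loglik = x$loglik, aic = x$aic, bic = x$bic,
    n_params = x$n_params,
    phi = as.data.frame(x$phi),
    alpha = as.data.frame(x$alpha),
    sigma = lapply(seq_len(x$R), function(r) as.data.frame(x$sigma[, , r])),
    trans = as.data.frame(x$trans),
    assignments = x$assignments,
    converged = x$converged,
    flags = x$flags, config = x$config
  )
}

#' @export
result_list.rsar_selection <- function(x) {
  list(
    type = "rsar_selection",
    table = x$table, r_aic = x$r_aic, r_bic = x$r_bic,
    best_aic = result_list(x$best_aic), best_bic = result_list(x$best_bic)
  )
}

#' @export
result_list.data.frame <- function(x) x

#' @export
result_list.list <- function(x) x

#' Serialize an analysis result to JSON
#'
#' Writes a schema-versioned JSON document for a [kcp_ar()] result, a
#' fitted [fit_rsar()] model, a [select_regimes()] bundle, or any data
#' frame (e.g. a study table), including the configuration echo needed to
#' reproduce the run. Numbers are written at full precision.
#'
#' @param x The result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  payload <- list(schema = "autoshift/1", result = result_list(x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
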