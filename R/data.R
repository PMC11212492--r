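#' Assemble long-format clustered data
#'
#' Validates a long-format data frame (one row per observation) and
#' standardises it for model fitting: responses become interval bounds
#' `.lower`/`.upper` with an `.exact` flag (exact observations have equal
#' bounds), clusters are regrouped contiguously in order of first
#' appearance, and the named covariate / time / stratum columns are
#' checked. Infinite bounds encode right- (`upper = Inf`) or left-
#' (`lower = -Inf`) censoring.
#'
#' @param data A data frame.
#' @param cluster Name of the cluster identifier column.
#' @param response Name of the exact-response column, or `NULL` when
#'   `lower`/`upper` are given.
#' @param lower,upper Names of the bound columns for censored data.
#' @param covariates Character vector of fixed-effect column names (may be
#'   empty).
#' @param time Optional name of the observation-time column (activates the
#'   random intercept + slope design).
#' @param strata Optional name of a stratum column.
#' @return A tibble of class `clustered_df` with columns `.cluster`,
#'   `.lower`, `.upper`, `.exact`, optionally `.time` and `.stratum`, and
#'   the covariate columns; the schema is stored in attribute `"schema"`.
#' @examples
#' df <- data.frame(id = c(1, 1, 2), y = c(0.3, 1.2, 2), x = c(0, 1, 0))
#' cd <- clustered_data(df, cluster = "id", response = "y", covariates = "x")
#' attr(cd, "schema")$n_per_cluster
#' @export
clustered_data <- function(data, cluster, response = NULL, lower = NULL,
                           upper = NULL, covariates = character(),
                           time = NULL, strata = NULL) {
  data <- as.data.frame(data)
  need <- c(
    cluster, response, lower, upper, covariates, time, strata
  )
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("column(s) not found in `data`: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(response) && (is.null(lower) || is.null(upper))) {
    stop("give either `response` or both `lower` and `upper`.",
      call. = FALSE
    )
  }
  if (!is.null(response)) {
    lo <- as.numeric(data[[response]])
    up <- lo
    if (any(!is.finite(lo))) {
      stop("non-finite values in response column `", response, "` at row(s) ",
        paste(utils::head(which(!is.finite(lo)), 5L), collapse = ", "),
        call. = FALSE
      )
    }
  } else {
    lo <- as.numeric(data[[lower]])
    up <- as.numeric(data[[upper]])
    lo[is.na(lo)] <- -Inf
    up[is.na(up)] <- Inf
    bad <- which(lo > up)
    if (length(bad)) {
      stop("lower > upper at row(s) ",
        paste(utils::head(bad, 5L), collapse = ", "),
        call. = FALSE
      )
    }
  }
  for (v in covariates) {
    if (!is.numeric(data[[v]])) {
      stop("covariate `", v, "` must be numeric.", call. = FALSE)
    }
  }
  cl <- data[[cluster]]
  ord <- order(match(cl, unique(cl))) # stable regrouping
  out <- tibble::tibble(
    .cluster = factor(cl, levels = unique(cl))[ord],
    .lower = lo[ord], .upper = up[ord],
    .exact = (lo == up)[ord]
  )
  if (!is.null(time)) out$.time <- as.numeric(data[[time]])[ord]
  if (!is.null(strata)) {
    out$.stratum <- factor(data[[strata]])[ord]
  }
  for (v in covariates) out[[v]] <- as.numeric(data[[v]])[ord]
  schema <- list(
    cluster = cluster, response = response, lower = lower, upper = upper,
    covariates = covariates, time = time, strata = strata,
    n_per_cluster = as.integer(table(out$.cluster))
  )
  structure(out,
    schema = schema,
    class = c("clustered_df", class(out))
  )
}

#' Read a long-format clustered data table from delimited text
#'
#' Reads a comma-separated file with a header row and passes it through
#' [clustered_data()]. Empty fields and the sentinels `Inf` / `-Inf` in the
#' bound columns encode infinite censoring bounds.
#'
#' @inheritParams clustered_data
#' @param path Path to a CSV file.
#' @return A `clustered_df` tibble, see [clustered_data()].
#' @export
read_long_table <- function(path, cluster, response = NULL, lower = NULL,
                            upper = NULL, covariates = character(),
                            time = NULL, strata = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c(lower, upper)) {
    if (is.character(raw[[v]])) {
      x <- trimws(raw[[v]])
      x[x == ""] <- NA
      raw[[v]] <- as.numeric(x) # "Inf"/"-Inf" parse to infinities
    }
  }
  clustered_data(raw,
    cluster = cluster, response = response, lower = lower,
    upper = upper, covariates = covariates, time = time, strata = strata
  )
}

#' Write a clustered data table as delimited text
#'
#' Round-trip companion to [read_long_table()]: writes the standardised
#' columns as CSV with `Inf`/`-Inf` sentinels preserved.
#'
#' @param data A `clustered_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
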