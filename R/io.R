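#' Read an aggregate table of cell counts
#'
#' Reads a delimited text file (comma or tab, auto-detected from the
#' header line) with one row per design cell: one or two factor columns
#' plus success and size columns. Validates counts and, for two factors,
#' completeness of the grid.
#'
#' @param path file path.
#' @param factors character vector of factor column names (length 1
#'   or 2).
#' @param s,n names of the success-count and cell-size columns.
#' @return A data frame of validated cells (factor columns, `s`, `n`)
#'   with attribute `"design"` (`"oneway"` or `"twoway"`).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("group,s,n", "a,10,30", "b,14,22"), tf)
#' read_anopa_aggregate(tf, factors = "group")
#' @export
read_anopa_aggregate <- function(path, factors, s = "s", n = "n") {
  d <- read_delimited(path)
  need <- c(factors, s, n)
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(factors) < 1 || length(factors) > 2) {
    stop("'factors' must name 1 or 2 columns", call. = FALSE)
  }
  sv <- d[[s]]; nv <- d[[n]]
  for (i in seq_len(nrow(d))) {
    ok <- tryCatch({ check_counts(sv[i], nv[i]); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      stop("row ", i, ": ", conditionMessage(ok), call. = FALSE)
    }
  }
  key <- do.call(paste, c(d[factors], sep = ":"))
  if (anyDuplicated(key)) {
    stop("duplicate cell label(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (length(factors) == 2) {
    l1 <- unique(d[[factors[1]]]); l2 <- unique(d[[factors[2]]])
    full <- paste(rep(l1, each = length(l2)), rep(l2, length(l1)), sep = ":")
    absent <- setdiff(full, key)
    if (length(absent)) {
      stop("incomplete factorial grid; missing cells: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
  }
  out <- d[c(factors, s, n)]
  names(out) <- c(factors, "s", "n")
  attr(out, "design") <- if (length(factors) == 2) "twoway" else "oneway"
  out
}

#' Read raw binary data, stacked or wide
#'
#' Stacked layout: one row per observation with factor column(s) and a
#' single 0/1 outcome column — for between-subject designs. Wide
#' layout: one row per participant with `k` 0/1 measurement columns —
#' for repeated-measures designs.
#'
#' @param path file path.
#' @param outcome name of the 0/1 outcome column (stacked layout), or
#'   `NULL`.
#' @param factors factor column names (stacked layout).
#' @param measurements measurement column names (wide layout), or
#'   `NULL` to use every column.
#' @return Stacked: a data frame of factors plus `y`. Wide: a 0/1
#'   matrix with one column per measurement.
#' @export
read_anopa_long <- function(path, outcome = NULL, factors = NULL,
                            measurements = NULL) {
  d <- read_delimited(path)
  if (!is.null(outcome)) {
    need <- c(factors, outcome)
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    y <- d[[outcome]]
    bad <- which(!y %in% c(0, 1))
    if (length(bad)) {
      stop("non-binary outcome value(s) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    out <- d[factors]
    out$y <- y
    return(out)
  }
  if (is.null(measurements)) measurements <- names(d)
  miss <- setdiff(measurements, names(d))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(d[measurements])
  if (anyNA(m)) stop("missing values in measurement columns", call. = FALSE)
  bad <- which(!m %in% c(0, 1))
  if (length(bad)) {
    stop("non-binary measurement value(s) found", call. = FALSE)
  }
  m
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  if (nrow(d) == 0) stop("no data rows in ", path, call. = FALSE)
  d
}

#' Write analysis results to disk
#'
#' Serializes the test table (and cells) of a fit. `"tsv"` writes the
#' numeric table at full precision; `"json"` writes every component
#' (round-trips to identical values); `"pretty"` writes the printed
#' display with 4-decimal rounding.
#'
#' @param fit an `"anopa"` object.
#' @param path output file path.
#' @param format `"tsv"`, `"json"`, or `"pretty"`.
#' @return `path`, invisibly.
#' @export
write_anopa <- function(fit, path, format = c("tsv", "json", "pretty")) {
  format <- match.arg(format)
  if (!inherits(fit, "anopa")) stop("'fit' must be an anopa object", call. = FALSE)
  tab <- fit$table
  err <- data.frame(effect = "Error", SS = NA, df = Inf, MS = fit$MSe,
                    F = NA, g = NA, p.value = NA, correction = NA,
                    F.corrected = NA, p.corrected = NA)
  full <- rbind(tab, err)
  switch(format,
    tsv = {
      out <- full
      out$df <- ifelse(is.infinite(out$df), "inf", as.character(out$df))
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    json = {
      payload <- list(design = fit$design, cells = fit$cells,
                      table = tab, MSe = fit$MSe, N = fit$N,
                      alpha1 = fit$alpha1)
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
    },
    pretty = writeLines(utils::capture.output(print(fit)), path))
  invisible(path)
}
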