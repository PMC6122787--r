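#' Read a participant table with a column-role configuration
#'
#' The table is CSV or TSV (sniffed from the extension) with ISO-8601
#' dates.  The JSON config declares column roles, e.g.
#' `{"date": "assess_date", "outcome": "cognition",
#'   "covariates": ["age_years","sex"], "cohort": "cohort"}`.
#'
#' @param path table path (`.csv` or `.tsv`/`.txt`).
#' @param config_path optional JSON config path.
#' @return list with `data` and `roles` (NULL roles when no config given).
#' @export
read_cohort_table <- function(path, config_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, as.is = TRUE,
                         check.names = FALSE)
  roles <- NULL
  if (!is.null(config_path)) {
    roles <- jsonlite::read_json(config_path, simplifyVector = TRUE)
    declared <- unlist(roles[c("date", "outcome", "covariates", "group",
                               "cohort", "id")], use.names = FALSE)
    missing_cols <- setdiff(declared, names(d))
    if (length(missing_cols))
      stop("config declares missing column(s): ",
           paste(missing_cols, collapse = ", "))
    if (!is.null(roles$date)) d[[roles$date]] <- as.Date(d[[roles$date]])
  }
  list(data = d, roles = roles)
}

#' Write a fit report as TSV and/or JSON
#'
#' @param report data frame (e.g. rows of [fit_report_row()], a
#'   [confounder_sweep()] table, or a module selection report).
#' @param tsv,json output paths (either may be NULL).
#' @return invisibly, the report.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  invisible(report)
}

#' Write a simulated dataset and its ground truth to a directory
#'
#' Emits the data files in the formats the analysis functions read, plus
#' `truth.json`.
#'
#' @param sim output of [generate_cohort()], [generate_csf()],
#'   [generate_expression()], or [generate_tfbs()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wt <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(sim$data)) files <- c(files, wt(sim$data, "data.tsv"))
  if (!is.null(sim$mat)) {
    p <- file.path(dir, "expression.tsv")
    utils::write.table(data.frame(gene = rownames(sim$mat), sim$mat,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  if (!is.null(sim$modules)) files <- c(files, wt(sim$modules, "modules.tsv"))
  if (!is.null(sim$meta)) files <- c(files, wt(sim$meta, "meta.tsv"))
  if (!is.null(sim$genes)) {
    g <- sim$genes
    bed <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand)
    p <- file.path(dir, "genes.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, p)
  }
  if (!is.null(sim$tfbs)) {
    b <- sim$tfbs
    bed <- data.frame(b$chrom, b$start, b$end, b$tf_name)
    p <- file.path(dir, "tfbs.bed")
    utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, p)
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(c(files, tp))
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column = gene identifiers, remaining columns = samples.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", as.is = TRUE,
                         check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}
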